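strain_a,strain_b,chi2,I,SE_I,I1,SE_I1,I2,SE_I2,sig_chi2,sig_I,sig_I1,sig_I2
BAJ,GUR,4.38,0.19,0.11,0.26,0.11,0.13,0.11,0,0,1,0
BAJ,OAX,14.55,0.41,0.10,0.33,0.10,0.50,0.10,1,1,1,1
BAJ,HTL,16.68,0.49,0.11,0.39,0.12,0.63,0.10,1,1,1,1
BAJ,TEH,6.48,0.27,0.11,0.19,0.11,0.35,0.11,0,1,0,1
BAJ,SON,10.67,0.37,0.11,0.28,0.11,0.46,0.10,0,1,1,1
GUR,OAX,2.8,-0.01,0.11,0.00,0.11,-0.03,0.11,0,0,0,0
GUR,TEH,3.44,-0.14,0.12,-0.30,0.11,0.03,0.12,0,0,1,0
GUR,HTL,5.0,-0.27,0.12,-0.35,0.12,-0.19,0.12,0,1,1,0
GUR,SON,0.76,-0.10,0.12,-0.09,0.12,-0.12,0.12,0,0,0,0
OAX,TEH,2.66,-0.19,0.12,-0.31,0.11,-0.08,0.12,0,0,1,0
OAX,HTL,2.75,-0.19,0.12,-0.27,0.12,-0.12,0.12,0,0,1,0
OAX,SON,4.18,-0.24,0.12,-0.29,0.12,-0.20,0.12,0,1,1,0
TEH,HTL,3.12,-0.16,0.12,0.00,0.13,-0.31,0.12,0,0,0,1
TEH,SON,5.65,-0.24,0.11,-0.30,0.11,-0.20,0.11,0,1,1,0
HTL,SON,1.0,-0.08,0.13,0,0.13,-0.16,0.13,0,0,0,0
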