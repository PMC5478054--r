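---
title: "Measuring reproductive isolation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reproductive isolation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reproiso)
```

This vignette explains what `reproiso` computes, the assumptions behind
each statistic, where the design was genuinely open and which choice we
made, and what the synthetic-data checks do and do not demonstrate about
field data.

## Premating isolation from multiple-choice trials

A multiple-choice trial confines equal numbers of virgin males and
females of two strains in one chamber and scores every mating by class:
`n11` (strain-A female × A male), `n12` (A × B), `n21` (B × A), `n22`
(B × B). All statistics condition on the observed total `n`: nothing is
inferred about mating propensity per se, only about the distribution of
matings across classes.

The joint isolation index

$$I = \frac{n_{11} + n_{22} - n_{12} - n_{21}}{n}$$

is 0 under random mating, 1 under complete assortment, and negative when
heterotypic matings are in excess (disassortative mating, common among
mainland strain pairs in these flies). The sex-specific indices
$I_1 = (n_{11}-n_{12})/(n_{11}+n_{12})$ and
$I_2 = (n_{22}-n_{21})/(n_{22}+n_{21})$ ask the same question
separately of each strain's females; each is undefined (returned as
`NA`, not an error) when its females mated with no one.

**Standard error.** All three indices use

$$\mathrm{SE} = \sqrt{\frac{1 - I^2}{n}}$$

with the *pair's total* `n`, not the index-specific denominator. This is
the convention of the classical choice-test literature and the only
reading that reproduces published standard errors (for example an
$I_2 = 0.63$ reported with SE 0.10 out of 63 total matings:
$\sqrt{(1-0.63^2)/63} = 0.098$, whereas using the 27 matings of that
strain's females would give 0.15). Under the conditioned-multinomial
model below, the formula is the delta-method SE of $I$ at $n$
multinomial draws, and simulation confirms its calibration (within 15%
of the empirical SD at $n = 80$; see the test suite).

**Significance.** An index is flagged when $|I| \ge 2\,\mathrm{SE}$,
evaluated on unrounded values; the comparison uses $\ge$, not $>$, so a
printed index exactly double its printed SE is significant. The
random-mating test is a Pearson chi-square of the four counts against
equal expectation `n/4` (df = 3, no continuity correction). Published
tables in this literature do not always star a nominally significant
chi-square, so the package prints p-values and leaves the alpha to the
caller rather than hard-coding a criterion.

## Postzygotic isolation from reciprocal crosses

Replicates of a directed cross are pooled before testing, as the source
assays do; the sex-ratio test is then a single Pearson chi-square of
pooled daughter/son counts against 1:1 (df = 1, uncorrected — the
uncorrected form is what reproduces published values where they are
internally consistent).

Sperm motility is scored per dissected F1 male: one moving sperm counts
as motile. With dissection counts of a few tens per cross, the motile
fraction gets an exact Clopper–Pearson interval rather than a Wald
interval (which collapses badly at fractions of 0 or 1, exactly the
biologically decisive cases).

**Sterility categories.** The source assays report qualitative regimes
— complete sterility, substantially reduced motility (a quarter to three
quarters of sons non-motile), and full motility. We map them to
`sterile` (zero motile among a nonzero dissection), `fertile` (lower 95%
bound of the motile fraction ≥ 0.85), and `reduced` (between). The
cutoff 0.85 is chosen to sit *below* the exact lower bound of a fully
motile sample at the assay's dissection scale — 0.877 at 28/28, 0.900 at
35/35, 0.949 at 70/70 — so that complete motility is always called
fertile even at the smallest dissections, while a fraction in the
reduced regime (≤ 0.76) cannot reach it at these sample sizes. A cutoff
of 0.9 would misclassify a fully motile 35-male dissection, which occurs
in the shipped fixture.

## Sequence divergence and haplotype networks

Distances are uncorrected p-distances: percent of differing sites among
*comparable* sites, where a site is comparable only if both sequences
carry an unambiguous base. We use pairwise deletion rather than complete
deletion: it preserves per-pair information, reproduces full-length
denominators (e.g. 1,159 bp of concatenated COI+COII) when data are
complete, and makes the zero-distance criterion for haplotype collapsing
consistent with the distance itself. IUPAC ambiguity codes other than
`N` are remapped to `N` with a warning — collapsing to "missing" is the
conservative reading when no ambiguity policy is stated. No
model-corrected distances (JC, K2P) are offered; at the within-complex
divergences these tools target (≤ ~2%) the correction is smaller than
the sampling noise, and tree inference is out of scope.

Group-averaged divergence is the arithmetic mean of all inter-group
pairwise percents, so groups represented by a single sequence are
handled identically to larger ones.

The haplotype network is a minimum spanning tree over collapsed
haplotypes, with edge weights equal to the number of differing
comparable sites (rendered as tick marks, one per substitution).
Candidate edges are sorted by `(steps, id, id)` before Kruskal's
algorithm, making the construction deterministic; across reorderings of
the input, the multiset of edge weights (a property shared by all MSTs)
and the total weight are invariant, and the tests verify optimality
against exhaustive spanning-tree enumeration. Median (unsampled)
intermediate haplotypes are not inferred. The statistical-parsimony 95%
connection limit is a user parameter applied as a post-hoc edge filter,
default unlimited: the probability-of-parsimony computation behind TCS's
limit is external machinery, and in the fully connected networks these
data produce the limit never binds.

**Haplotype collapsing with missing data** is not transitive: with
pairwise deletion, A≈B and B≈C do not imply A≈C when `N`s fall on
different sites. We resolve this greedily — records join the first
existing haplotype they match, scanning in input order — and represent
each haplotype by its member with the fewest `N`s (ties by id). With
complete data the result is order-independent; with heavy missingness
the grouping can depend on input order, a known limitation shared by
most collapsing tools.

## The synthetic-data generators

The generators exist so that every estimator can be checked against
known truth, at the scales of the motivating assays:

- **Mating trials** are fixed-total multinomials over the four classes
  (probabilities `p11, p12, p21, p22`), because the statistics condition
  on `n`; latency and courtship dynamics are deliberately absent.
  Defaults: `n = 80` matings per trial, the observed per-pair scale
  (59–83). Under this model $E[I] = p_{11}+p_{22}-p_{12}-p_{21}$, which
  the recovery tests exploit.
- **Crosses** draw daughters as binomial(`n_offspring`, `prop_female`)
  and non-motile sons as binomial(`n_dissected`, `sterility_p`).
  Defaults `n_offspring = 400` (several hundred progeny per cross) and
  `n_dissected = 50` (dissections ranged 28–70).
- **Alignments** place a fixed number of substitutions per tree branch
  at sites drawn without replacement from a shared pool (an
  infinite-sites assumption, safe at a few tens of changes over ~1,000
  bp: collision probability is negligible and, by construction, zero).
  Realised Hamming distances therefore equal path sums exactly, making
  distance and network recovery exact rather than approximate. Default
  length 1,159 bp, the concatenated COI+COII scale; within-group
  polymorphism defaults to 0 and can be requested explicitly.

All generators are reproducible from their integer seed alone and
restore the caller's RNG state.

**What passing these checks shows — and what it does not.** The
simulations validate the estimators *under their own model*: multinomial
counts, independent binomials, infinite sites. Real trials add
observation loss, female remating, chamber effects and replicate
heterogeneity; real sequences add rate variation, multiple hits and
recombination-free but selection-shaped mtDNA. Agreement with the
generators is therefore a correctness check on the arithmetic and its
sampling theory, not a demonstration that the biological assumptions
hold in any particular dataset.

## Numerical and reporting choices

- Internal values are full precision; report rendering rounds half away
  from zero (0.125 → 0.13), the convention of the printed tables, with 2
  decimals by default.
- A recomputed value "matches" a printed one when it lies within one
  unit in the printed value's last decimal. Published tables mix true
  rounding with truncation (0.625 printed as 0.62; 14.5556 as 14.55),
  and the one-ULP band accepts both while catching every genuine
  inconsistency.
- Printed-vs-recomputed disagreements are *warnings, never corrections*:
  the shipped fixture transcribes the source tables as printed,
  including their known misprints (a transposed pair of sex-specific
  indices, two chi-squares irreproducible from their own counts, two
  totals that disagree with their counts, and one cross chi-square), and
  the pipeline reports each one next to its recomputed value.
- Degenerate inputs are values, not crashes, wherever the statistic has
  a defensible reading (`NA` sex-specific index, `unknown` motility
  category); they are errors where it does not (zero total matings,
  zero offspring, no comparable sites between groups).
- Problem sizes in the test suite (enumeration of all count vectors with
  `n ≤ 12`; spanning-tree enumeration at 6 haplotypes; 200 simulation
  replicates at `n = 80–81`; 400 seeds for the type-I-error check) were
  chosen as the smallest scales at which each property is decisively
  checked.

## Known limitations

- No latency/courtship modelling, no Bayesian estimation of isolation,
  no backcross genetics.
- Distances are uncorrected only; no codon partitioning or tree
  inference.
- The connection-limit filter prunes the MST rather than recomputing a
  parsimony-probability network; for data where the limit binds, a
  dedicated TCS implementation may yield different (multi-edge) networks.
- Haplotype collapsing under heavy missing data is order-dependent (see
  above).
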