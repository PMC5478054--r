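test_that("generators are reproducible from seed alone", {
  m <- mating_model(0.4, 0.1, 0.1, 0.4, n_matings = 100, replicates = 3,
                    seed = 99)
  expect_equal(as.data.frame(simulate_mating_trials(m)),
               as.data.frame(simulate_mating_trials(m)))
  m2 <- mating_model(0.4, 0.1, 0.1, 0.4, n_matings = 100, replicates = 3,
                     seed = 100)
  expect_false(identical(simulate_mating_trials(m)$n11,
                         simulate_mating_trials(m2)$n11))

  cm <- cross_model(seed = 5)
  expect_equal(as.data.frame(simulate_cross(cm)),
               as.data.frame(simulate_cross(cm)))

  sm <- sequence_model(c(A = 2, B = 2), length = 200, seed = 7)
  expect_equal(as.data.frame(simulate_alignment(sm)),
               as.data.frame(simulate_alignment(sm)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_mating_trials(mating_model(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("model constructors validate their parameters", {
  expect_error(mating_model(0.5, 0.5, 0.5, 0.5),
               class = "reproiso_validation_error")
  expect_error(sequence_model(c(A = 1, B = 1), length = 10,
                              star_substitutions = 8),
               class = "reproiso_validation_error")
  expect_error(sequence_model(c(A = 1), tree = data.frame(
    from = "ancestor", to = "B", substitutions = 1), length = 100),
    class = "reproiso_validation_error")
})

test_that("simulated trials recover the model's expected joint index", {
  # null model: with n = 10,000 the index should sit within 0.05 of zero
  null <- simulate_mating_trials(mating_model(n_matings = 10000, seed = 21))
  expect_lt(abs(joint_isolation_index(
    as.numeric(null[1, c("n11", "n12", "n21", "n22")]))), 0.05)

  # isolation model: E[I] = p11 + p22 - p12 - p21 = 0.6, check within 3 SE
  iso <- simulate_mating_trials(
    mating_model(0.4, 0.1, 0.1, 0.4, n_matings = 10000, seed = 22))
  I <- joint_isolation_index(as.numeric(iso[1, c("n11", "n12", "n21", "n22")]))
  expect_lt(abs(I - 0.6), 3 * sqrt((1 - 0.6^2) / 10000))
})

test_that("simulated crosses honour sterility extremes and sex-ratio null", {
  fully <- simulate_cross(cross_model(sterility_p = 0, n_dissected = 40,
                                      seed = 4))
  expect_equal(fully$males_motile, 40L)
  expect_equal(analyze_crosses(fully)$category, "fertile")

  none <- simulate_cross(cross_model(sterility_p = 1, n_dissected = 40,
                                     seed = 4))
  expect_equal(none$males_motile, 0L)
  expect_equal(analyze_crosses(none)$category, "sterile")

  # type-I error of the sex-ratio test near the nominal 5% under the null
  rejections <- vapply(1:400, function(s) {
    r <- simulate_cross(cross_model(prop_female = 0.5, n_offspring = 400,
                                    seed = 10000 + s))
    sex_ratio_chi2(r$females, r$males)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("simulated alignments realise the requested divergence structure", {
  # zero substitutions: every record is the ancestral haplotype
  flat <- simulate_alignment(sequence_model(c(A = 3, B = 3),
                                            star_substitutions = 0,
                                            length = 300, seed = 9))
  expect_equal(nrow(collapse_haplotypes(flat)), 1)

  # two groups two substitutions apart over 1159 bp: the published scale
  two <- simulate_alignment(sequence_model(
    c(SON = 2, LBO = 2),
    tree = data.frame(from = c("ancestor", "ancestor"),
                      to = c("SON", "LBO"),
                      substitutions = c(0L, 2L)),
    length = 1159, seed = 10))
  dm <- group_divergence_matrix(two)
  expect_equal(dm$percent["SON", "LBO"], 200 / 1159)
  expect_equal(round_half_away(dm$percent["SON", "LBO"], 2), 0.17)

  # star tree with disjoint mutated sites: network recovers the star exactly
  star <- simulate_alignment(sequence_model(
    c(HUB = 1, X = 1, Y = 1, Z = 1),
    tree = data.frame(from = "ancestor", to = c("HUB", "X", "Y", "Z"),
                      substitutions = c(0L, 3L, 5L, 7L)),
    length = 500, seed = 11))
  net <- build_network(collapse_haplotypes(star))
  hub_id <- net$nodes$id[vapply(net$nodes$members,
                                function(m) "HUB_01" %in% m, NA)]
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$from == hub_id | net$edges$to == hub_id))
  expect_setequal(net$edges$steps, c(3L, 5L, 7L))
})

test_that("within-group polymorphism stays on private disjoint sites", {
  aln <- simulate_alignment(sequence_model(c(A = 3, B = 3),
                                           star_substitutions = 4,
                                           length = 400,
                                           within_substitutions = 2,
                                           seed = 13))
  haps <- collapse_haplotypes(aln)
  expect_equal(nrow(haps), 6)   # every individual private
  dm <- group_divergence_matrix(aln)
  # between-group distance: path (4+4) plus two private loads of 2 each
  expect_equal(dm$percent["A", "B"], 100 * 12 / 400)
})
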