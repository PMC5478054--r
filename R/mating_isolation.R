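#' Joint isolation index from multiple-choice mating counts
#'
#' The joint isolation index for a pair of strains is the excess of
#' homotypic over heterotypic matings as a fraction of all matings:
#'
#' \deqn{I = (n_{11} + n_{22} - n_{12} - n_{21}) / n}
#'
#' where `n11` and `n22` count matings within strain A and strain B, `n12`
#' and `n21` the two heterotypic classes, and `n` their total. `I = 0`
#' under random mating, `1` under complete isolation, and negative values
#' indicate disassortative mating.
#'
#' @param counts numeric vector `c(n11, n12, n21, n22)` of non-negative
#'   mating counts.
#' @return the index, a number in `[-1, 1]`.
#' @export
#' @examples
#' joint_isolation_index(c(30, 15, 9, 27))   # 0.4074
joint_isolation_index <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n == 0)
    abort("isolation index undefined for zero matings",
          "reproiso_undefined_statistic")
  (counts[1] + counts[4] - counts[2] - counts[3]) / n
}

#' Sex-specific (per-strain female) isolation indices
#'
#' `I1 = (n11 - n12) / (n11 + n12)` measures isolation among strain-A
#' females (own-strain versus other-strain matings); `I2 = (n22 - n21) /
#' (n22 + n21)` does the same for strain-B females. An index is undefined
#' (`NA`) when its denominator is zero -- that strain's females mated with
#' no one -- which is a value, not an error.
#'
#' @inheritParams joint_isolation_index
#' @return named numeric vector `c(I1 = ..., I2 = ...)`, each in `[-1, 1]`
#'   or `NA`.
#' @export
#' @examples
#' sex_specific_indices(c(30, 15, 9, 27))   # 0.3333, 0.5000
sex_specific_indices <- function(counts) {
  counts <- check_counts(counts)
  d1 <- counts[1] + counts[2]
  d2 <- counts[4] + counts[3]
  c(I1 = if (d1 > 0) (counts[1] - counts[2]) / d1 else NA_real_,
    I2 = if (d2 > 0) (counts[4] - counts[3]) / d2 else NA_real_)
}

#' Standard error of an isolation index
#'
#' \deqn{SE = \sqrt{(1 - I^2)/n}}
#'
#' with `n` the pair's total mating count. The same formula, always with
#' the total `n`, applies to the joint and both sex-specific indices; this
#' is the convention of the choice-test literature and what published
#' standard errors reproduce. The SE is largest (`1/sqrt(n)`) at `I = 0`
#' and shrinks to 0 as `|I|` approaches 1.
#'
#' @param index an isolation index in `[-1, 1]`.
#' @param n total number of matings (> 0).
#' @return the standard error.
#' @export
isolation_se <- function(index, n) {
  if (is.na(index)) return(NA_real_)
  stopifnot(abs(index) <= 1)
  if (n <= 0)
    abort("standard error undefined for n = 0", "reproiso_undefined_statistic")
  sqrt((1 - index^2) / n)
}

#' Chi-square test of random mating in a multiple-choice trial
#'
#' Tests the four mating-class counts against the 1:1:1:1 expectation of
#' random mating (each class expected `n/4`): Pearson chi-square, 3 degrees
#' of freedom, no continuity correction.
#'
#' @inheritParams joint_isolation_index
#' @return list with `chi2`, `df` (always 3) and `p` (upper tail).
#' @export
#' @examples
#' random_mating_chi2(c(30, 15, 9, 27))   # chi2 = 14.556
random_mating_chi2 <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) == 0)
    abort("chi-square undefined for zero matings",
          "reproiso_undefined_statistic")
  ct <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / 4, 4), correct = FALSE))
  list(chi2 = unname(ct$statistic), df = 3L, p = unname(ct$p.value))
}

#' Full isolation analysis for one strain pair
#'
#' Computes the joint and sex-specific isolation indices, their standard
#' errors (all with the pair's total `n`), the random-mating chi-square,
#' and significance flags. An index is called significant when its absolute
#' value is at least twice its standard error, evaluated on unrounded
#' values (so a printed index exactly double its printed SE is
#' significant).
#'
#' @inheritParams joint_isolation_index
#' @param strain_a,strain_b strain labels (female strain first by
#'   convention of the counts).
#' @return one-row data frame (class `isolation_result`) with columns
#'   `strain_a, strain_b, n, chi2, df, p_value, I, SE_I, I1, SE_I1, I2,
#'   SE_I2, significant_I, significant_I1, significant_I2`.
#' @export
analyze_pair <- function(counts, strain_a = "A", strain_b = "B") {
  counts <- check_counts(counts)
  n <- sum(counts)
  I <- joint_isolation_index(counts)
  ss <- sex_specific_indices(counts)
  chi <- random_mating_chi2(counts)
  se_I <- isolation_se(I, n)
  se_1 <- isolation_se(ss[["I1"]], n)
  se_2 <- isolation_se(ss[["I2"]], n)
  sig <- function(x, se) !is.na(x) && !is.na(se) && abs(x) >= 2 * se
  structure(
    data.frame(strain_a = strain_a, strain_b = strain_b, n = n,
               chi2 = chi$chi2, df = chi$df, p_value = chi$p,
               I = I, SE_I = se_I,
               I1 = ss[["I1"]], SE_I1 = se_1,
               I2 = ss[["I2"]], SE_I2 = se_2,
               significant_I = sig(I, se_I),
               significant_I1 = sig(ss[["I1"]], se_1),
               significant_I2 = sig(ss[["I2"]], se_2),
               stringsAsFactors = FALSE),
    class = c("isolation_result", "data.frame"))
}

#' Isolation analysis for every pair in a mating-trial table
#'
#' @param trials a `mating_trials` table from [read_mating_trials()] or
#'   [simulate_mating_trials()].
#' @return data frame with one [analyze_pair()] row per input row, in
#'   input order.
#' @export
analyze_trials <- function(trials) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    analyze_pair(as.numeric(trials[i, c("n11", "n12", "n21", "n22")]),
                 strain_a = trials$strain_a[i],
                 strain_b = trials$strain_b[i])
  })
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    analyze_pair(c(1, 0, 0, 0))[0, ]
  structure(out, class = c("isolation_result", "data.frame"))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 4 || !is_count(counts))
    abort("counts must be four non-negative integers c(n11, n12, n21, n22)",
          "reproiso_validation_error")
  counts
}
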