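#' Mating-trial generative model
#'
#' The generator conditions on the total number of matings per trial, as
#' the choice-test statistics themselves do: each replicate draws the four
#' class counts `(n11, n12, n21, n22)` from a multinomial with the given
#' propensity vector. Under this model the expected joint isolation index
#' is `p11 + p22 - p12 - p21`.
#'
#' @param p11,p12,p21,p22 mating-class probabilities, non-negative and
#'   summing to 1 (within 1e-12).
#' @param n_matings total matings per replicate.
#' @param replicates number of independent trials.
#' @param seed integer RNG seed.
#' @return a validated `mating_model` list.
#' @export
mating_model <- function(p11 = 0.25, p12 = 0.25, p21 = 0.25, p22 = 0.25,
                         n_matings = 80, replicates = 1, seed = 1) {
  p <- c(p11, p12, p21, p22)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    abort("mating-class probabilities must be non-negative and sum to 1",
          "reproiso_validation_error")
  stopifnot(is_count(n_matings), n_matings > 0,
            is_count(replicates), replicates >= 1)
  structure(list(p = p, n_matings = as.integer(n_matings),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "mating_model")
}

#' Simulate multiple-choice mating trials
#'
#' Each replicate becomes one row of a `mating_trials` table, with strain
#' labels `A<r>` / `B<r>` so replicate pairs stay distinct. Deterministic
#' given the model's seed.
#'
#' @param model a [mating_model()].
#' @return a `mating_trials` table with `replicates` rows.
#' @export
simulate_mating_trials <- function(model) {
  stopifnot(inherits(model, "mating_model"))
  with_seed(model$seed, {
    draws <- stats::rmultinom(model$replicates, model$n_matings, model$p)
    as_mating_trials(data.frame(
      strain_a = paste0("A", seq_len(model$replicates)),
      strain_b = paste0("B", seq_len(model$replicates)),
      n11 = draws[1, ], n12 = draws[2, ], n21 = draws[3, ], n22 = draws[4, ],
      stringsAsFactors = FALSE))
  })
}

#' Reciprocal-cross generative model
#'
#' Offspring sex is binomial with probability `prop_female` of a daughter
#' (0.5 = no distortion); each dissected F1 male independently lacks
#' motile sperm with probability `sterility_p`.
#'
#' @param prop_female probability an offspring is female.
#' @param sterility_p probability a dissected male has no motile sperm.
#' @param n_offspring total offspring counted.
#' @param n_dissected males dissected for motility (dissections at the
#'   assay's usual scale are a few tens of males).
#' @param seed integer RNG seed.
#' @return a validated `cross_model` list.
#' @export
cross_model <- function(prop_female = 0.5, sterility_p = 0,
                        n_offspring = 400, n_dissected = 50, seed = 1) {
  stopifnot(prop_female >= 0, prop_female <= 1,
            sterility_p >= 0, sterility_p <= 1,
            is_count(n_offspring), is_count(n_dissected))
  structure(list(prop_female = prop_female, sterility_p = sterility_p,
                 n_offspring = as.integer(n_offspring),
                 n_dissected = as.integer(n_dissected),
                 seed = as.integer(seed)),
            class = "cross_model")
}

#' Simulate one directed cross
#'
#' @param model a [cross_model()].
#' @param mother,father strain labels for the simulated cross.
#' @return a one-row `cross_table`.
#' @export
simulate_cross <- function(model, mother = "A", father = "B") {
  stopifnot(inherits(model, "cross_model"))
  with_seed(model$seed, {
    females <- stats::rbinom(1, model$n_offspring, model$prop_female)
    motile <- stats::rbinom(1, model$n_dissected, 1 - model$sterility_p)
    as_cross_table(data.frame(
      mother = mother, father = father, replicates = 1L,
      females = females, males = model$n_offspring - females,
      males_dissected = model$n_dissected, males_motile = motile,
      stringsAsFactors = FALSE))
  })
}

#' Sequence-divergence generative model
#'
#' Groups of individuals diverge on a rooted tree whose branches each
#' carry a fixed number of substitutions. Substitution sites are drawn
#' without replacement from a shared pool across all branches (an
#' infinite-sites assumption, reasonable at the per-branch counts of a
#' few to a few tens of changes over ~1000 bp), so the realised Hamming
#' distance between any two groups equals the sum of substitutions on the
#' path between them -- which makes distance and network recovery exact
#' and testable.
#'
#' @param groups named integer vector: individuals per group label.
#' @param tree data frame with columns `from`, `to`, `substitutions`;
#'   `from = "ancestor"` denotes the root. Default: a star with every
#'   group hanging off the ancestor by the counts in `star_substitutions`.
#' @param star_substitutions per-group branch lengths used when `tree` is
#'   not given (recycled).
#' @param length alignment columns (default 1159, the concatenated
#'   COI+COII scale).
#' @param within_substitutions substitutions applied independently to each
#'   individual on top of its group consensus (default 0: clonal groups).
#' @param seed integer RNG seed.
#' @return a validated `sequence_model` list.
#' @export
sequence_model <- function(groups, tree = NULL, star_substitutions = 2,
                           length = 1159, within_substitutions = 0,
                           seed = 1) {
  stopifnot(is_count(groups), length(groups) >= 1, !is.null(names(groups)))
  if (is.null(tree))
    tree <- data.frame(from = "ancestor", to = names(groups),
                       substitutions = rep_len(star_substitutions,
                                               length(groups)),
                       stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "substitutions") %in% names(tree)),
            is_count(tree$substitutions), is_count(length),
            is_count(within_substitutions))
  total <- sum(tree$substitutions) +
    within_substitutions * sum(groups)
  if (total > length)
    abort(sprintf("requested %d substitutions exceed alignment length %d",
                  total, length), "reproiso_validation_error")
  miss <- setdiff(names(groups), tree$to)
  if (length(miss))
    abort(sprintf("tree has no branch leading to group(s): %s",
                  paste(miss, collapse = ", ")), "reproiso_validation_error")
  structure(list(groups = groups, tree = tree, length = as.integer(length),
                 within_substitutions = as.integer(within_substitutions),
                 seed = as.integer(seed)),
            class = "sequence_model")
}

#' Simulate an aligned sequence set with known divergence
#'
#' Draws a random ancestral sequence, mutates it along each tree branch at
#' sites sampled without replacement from a shared pool, assigns each
#' group the consensus at the end of its root-to-group path, and copies it
#' to the group's individuals (optionally adding private substitutions,
#' also at pool sites). Deterministic given the model's seed.
#'
#' @param model a [sequence_model()].
#' @return an `alignment_set` with ids `<group>_<i>`.
#' @export
simulate_alignment <- function(model) {
  stopifnot(inherits(model, "sequence_model"))
  bases <- c("A", "C", "G", "T")
  with_seed(model$seed, {
    anc <- sample(bases, model$length, replace = TRUE)
    pool <- sample.int(model$length)   # shuffled site pool, consumed in order
    take <- function(k) {
      if (k == 0) return(integer(0))
      s <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      s
    }
    mutate <- function(seq, sites) {
      for (s in sites) seq[s] <- sample(setdiff(bases, seq[s]), 1)
      seq
    }
    edge_sites <- lapply(model$tree$substitutions, take)
    # consensus per node, walking from the root
    consensus <- list(ancestor = anc)
    remaining <- seq_len(nrow(model$tree))
    while (length(remaining)) {
      ready <- remaining[model$tree$from[remaining] %in% names(consensus)]
      if (!length(ready))
        abort("tree is not connected to the ancestor",
              "reproiso_validation_error")
      for (e in ready)
        consensus[[model$tree$to[e]]] <-
          mutate(consensus[[model$tree$from[e]]], edge_sites[[e]])
      remaining <- setdiff(remaining, ready)
    }
    ids <- groups <- seqs <- character(0)
    for (g in names(model$groups)) {
      for (i in seq_len(model$groups[[g]])) {
        s <- consensus[[g]]
        if (model$within_substitutions > 0)
          s <- mutate(s, take(model$within_substitutions))
        ids <- c(ids, sprintf("%s_%02d", g, i))
        groups <- c(groups, g)
        seqs <- c(seqs, paste(s, collapse = ""))
      }
    }
    as_alignment_set(ids, seqs, groups = groups)
  })
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
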