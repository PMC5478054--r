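# Shared fixture helpers. The strain-pair and cross fixtures ship with the
# package; everything else is generated in code.

table3_trials <- function() {
  suppressWarnings(
    read_mating_trials(reproiso_example("mating_trials_table3.csv")))
}

table3_published <- function() {
  utils::read.csv(reproiso_example("table3_published.csv"),
                  colClasses = "character")
}

table2a_crosses <- function() {
  read_cross_records(reproiso_example("crosses_table2a.csv"))
}

table2a_published <- function() {
  utils::read.csv(reproiso_example("table2a_published.csv"),
                  colClasses = "character")
}

# Rows of the printed strain-pair table whose counts reproduce every printed
# statistic; the other three carry documented printing inconsistencies.
INCONSISTENT_PAIRS <- c("OAX.TEH", "OAX.SON", "TEH.SON")

pair_key <- function(a, b) paste(a, b, sep = ".")

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# All compositions of n into 4 non-negative parts (mating-class count vectors).
compositions4 <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b))
    out[[length(out) + 1]] <- c(a, b, c, n - a - b - c)
  out
}

# Minimum spanning-tree weight by exhaustive enumeration of edge subsets.
brute_force_mst_weight <- function(dist_mat) {
  k <- nrow(dist_mat)
  if (k == 1) return(0)
  edges <- t(utils::combn(k, 2))
  w <- dist_mat[edges]
  best <- Inf
  for (sel in utils::combn(nrow(edges), k - 1, simplify = FALSE)) {
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}
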