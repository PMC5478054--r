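#' Uncorrected pairwise p-distance between two aligned sequences
#'
#' Percent of differing sites among the comparable sites, with no
#' substitution-model correction. A site is comparable only when both
#' sequences carry an unambiguous base (`A`, `C`, `G` or `T`); `N` and
#' gaps are dropped site-by-site (pairwise deletion), so each pair keeps
#' all information it has.
#'
#' @param a,b aligned sequences of equal length (character strings over
#'   `A,C,G,T,N,-`).
#' @return list with `percent` (100 x mismatches / comparable sites; `NA`
#'   if no site is comparable) and `comparable_sites`.
#' @export
#' @examples
#' pairwise_p_distance("AAAA", "AAAT")   # 25% over 4 sites
#' pairwise_p_distance("AANA", "AATA")   # 0% over 3 sites
pairwise_p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    abort(sprintf("sequences differ in length (%d vs %d)", nchar(a), nchar(b)),
          "reproiso_alignment_error")
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  comp <- va %in% bases & vb %in% bases
  ncomp <- sum(comp)
  pct <- if (ncomp == 0) NA_real_ else 100 * sum(va[comp] != vb[comp]) / ncomp
  list(percent = pct, comparable_sites = ncomp)
}

#' Group-averaged percent divergence matrix
#'
#' Average uncorrected p-distance between every pair of groups in an
#' alignment: each between-group cell is the arithmetic mean of all
#' inter-group pairwise percent distances (so single-member groups are
#' fine); the diagonal is zero by definition.
#'
#' @param aln an `alignment_set` in which every record has a group label.
#' @return a `divergence_matrix`: list with `labels` (group order of first
#'   appearance), `percent` (symmetric matrix, zero diagonal), and
#'   `comparable_sites` (matrix of the mean comparable-site count per
#'   cell).
#' @export
group_divergence_matrix <- function(aln) {
  groups <- unique(aln$group)
  k <- length(groups)
  pct <- matrix(0, k, k, dimnames = list(groups, groups))
  ncomp <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ai <- aln$sequence[aln$group == groups[i]]
    aj <- aln$sequence[aln$group == groups[j]]
    dists <- comps <- numeric(0)
    for (x in ai) for (y in aj) {
      d <- pairwise_p_distance(x, y)
      if (is.na(d$percent))
        abort(sprintf("no comparable sites between groups %s and %s",
                      groups[i], groups[j]), "reproiso_undefined_statistic")
      dists <- c(dists, d$percent)
      comps <- c(comps, d$comparable_sites)
    }
    pct[i, j] <- pct[j, i] <- mean(dists)
    ncomp[i, j] <- ncomp[j, i] <- mean(comps)
  }
  structure(list(labels = groups, percent = pct, comparable_sites = ncomp),
            class = "divergence_matrix")
}

#' Collapse aligned records into haplotypes
#'
#' Records whose sequences show zero mismatches across their comparable
#' sites (pairwise deletion of `N` and gaps, as in
#' [pairwise_p_distance()]) are merged into one haplotype. Records are
#' scanned in input order and joined to the first haplotype they match.
#' Each haplotype is represented by the member sequence with the fewest
#' `N` characters (ties broken by lexicographic id) and labelled `H1`,
#' `H2`, ... in order of first appearance.
#'
#' @param aln an `alignment_set`.
#' @return data frame (class `haplotype_set`) with columns `id`,
#'   `sequence` (the representative), `members` (list column of record
#'   ids), `frequency`.
#' @export
collapse_haplotypes <- function(aln) {
  reps <- character(0)       # representative sequence per haplotype
  members <- list()
  for (i in seq_len(nrow(aln))) {
    s <- aln$sequence[i]
    hit <- 0L
    for (h in seq_along(reps)) {
      d <- pairwise_p_distance(s, reps[h])
      if (!is.na(d$percent) && d$percent == 0) { hit <- h; break }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      members <- c(members, list(aln$id[i]))
    } else {
      members[[hit]] <- c(members[[hit]], aln$id[i])
    }
  }
  n_count <- function(x) lengths(regmatches(x, gregexpr("N", x, fixed = TRUE)))
  rep_seq <- vapply(seq_along(reps), function(h) {
    ids <- members[[h]]
    seqs <- aln$sequence[match(ids, aln$id)]
    ord <- order(n_count(seqs), ids)
    seqs[ord[1]]
  }, character(1))
  structure(
    data.frame(id = paste0("H", seq_along(reps)),
               sequence = rep_seq,
               frequency = lengths(members),
               stringsAsFactors = FALSE,
               members = I(members)),
    class = c("haplotype_set", "data.frame"))
}

#' Build a haplotype network by minimum spanning tree
#'
#' Connects haplotypes with edges weighted by the number of differing
#' comparable sites, keeping a minimum spanning tree -- the
#' parsimony-style network in which each edge's step count is the number
#' of single-nucleotide substitutions separating its endpoints (one tick
#' mark per step in the usual rendering). Edge candidates are sorted by
#' `(steps, id_a, id_b)` before Kruskal's algorithm, so the result is
#' deterministic regardless of input order. If `connection_limit` is set,
#' edges with more steps are removed afterwards, which may split the
#' network into disconnected components (the statistical-parsimony
#' connection limit; by default no limit is applied).
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param connection_limit optional maximum steps per retained edge.
#' @return a `haplotype_network`: list with `nodes` (the input haplotype
#'   set), `edges` (data frame `from, to, steps`), and
#'   `connection_limit`.
#' @export
build_network <- function(haps, connection_limit = NULL) {
  k <- nrow(haps)
  if (k < 1)
    abort("need at least one haplotype", "reproiso_validation_error")
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (k > 1) {
    cand <- t(utils::combn(k, 2))
    steps <- apply(cand, 1, function(ij) {
      d <- pairwise_p_distance(haps$sequence[ij[1]], haps$sequence[ij[2]])
      as.integer(round(d$percent / 100 * d$comparable_sites))
    })
    cand <- data.frame(i = cand[, 1], j = cand[, 2], steps = steps)
    cand <- cand[order(cand$steps, haps$id[cand$i], haps$id[cand$j]), ]
    # Kruskal with union-find; deterministic given the sort above
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(nrow(cand))
    for (e in seq_len(nrow(cand))) {
      ri <- find(cand$i[e]); rj <- find(cand$j[e])
      if (ri != rj) { parent[ri] <- rj; keep[e] <- TRUE }
    }
    cand <- cand[keep, , drop = FALSE]
    if (!is.null(connection_limit))
      cand <- cand[cand$steps <= connection_limit, , drop = FALSE]
    edges <- data.frame(from = haps$id[cand$i], to = haps$id[cand$j],
                        steps = cand$steps, stringsAsFactors = FALSE,
                        row.names = NULL)
  }
  structure(list(nodes = haps, edges = edges,
                 connection_limit = connection_limit),
            class = "haplotype_network")
}

#' Write a divergence matrix as CSV
#'
#' Lower-triangle-symmetric square matrix of percents, rounded for
#' display; row and column names are the group labels.
#'
#' @param dm a `divergence_matrix`.
#' @param path output CSV path.
#' @param digits decimals for the percents (default 2).
#' @return `path`, invisibly.
#' @export
write_divergence_csv <- function(dm, path, digits = 2) {
  m <- round_half_away(dm$percent, digits)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a haplotype network as an edge list (TSV)
#'
#' Columns `from`, `to`, `steps`, plus a node table appended as comment
#' lines (`# node<TAB>frequency<TAB>members`) so viewers and scripts can
#' size nodes by haplotype frequency.
#'
#' @param net a `haplotype_network`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(net$edges, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  for (i in seq_len(nrow(net$nodes)))
    cat(sprintf("# %s\t%d\t%s\n", net$nodes$id[i], net$nodes$frequency[i],
                paste(net$nodes$members[[i]], collapse = ",")), file = con)
  invisible(path)
}
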