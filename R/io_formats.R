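#' Read a multiple-choice mating-trial table
#'
#' Parses a CSV of mating counts from multiple-choice tests, one row per
#' strain pair. The four counts follow the convention of the choice-test
#' literature: `n11` = females of strain A with males of strain A, `n12` =
#' females of A with males of B, `n21` = females of B with males of A,
#' `n22` = females of B with males of B. The first-named strain is always
#' the female's strain.
#'
#' The total number of matings `n` is always recomputed as
#' `n11 + n12 + n21 + n22`. If the file carries a transcribed total in an
#' `n_reported` column that disagrees with the sum, the row is kept and a
#' data-quality warning is raised; published tables occasionally print a
#' total inconsistent with their own counts, and silent correction would
#' hide that.
#'
#' @param path path to a comma-separated file with header columns
#'   `strain_a,strain_b,n11,n12,n21,n22` and optionally `n_reported`.
#' @return a `mating_trials` data frame with the columns above plus `n`
#'   (the recomputed total).
#' @seealso [analyze_trials()], [simulate_mating_trials()]
#' @export
read_mating_trials <- function(path) {
  df <- read_strict_csv(path, required = c("strain_a", "strain_b",
                                           "n11", "n12", "n21", "n22"))
  if (!"n_reported" %in% names(df))
    df$n_reported <- rep(NA_integer_, nrow(df))
  as_mating_trials(df)
}

#' Construct and validate a mating-trial table
#'
#' @param df data frame with columns `strain_a,strain_b,n11,n12,n21,n22`
#'   and optionally `n_reported`.
#' @return the validated table, classed `mating_trials`, with recomputed `n`.
#' @export
as_mating_trials <- function(df) {
  counts <- c("n11", "n12", "n21", "n22")
  for (col in counts) {
    v <- df[[col]]
    if (!is_count(v))
      abort(sprintf("column '%s' must hold non-negative integers", col),
            "reproiso_parse_error")
    df[[col]] <- as.integer(v)
  }
  df$strain_a <- as.character(df$strain_a)
  df$strain_b <- as.character(df$strain_b)
  if (any(df$strain_a == df$strain_b)) {
    bad <- which(df$strain_a == df$strain_b)[1]
    abort(sprintf("row %d pairs strain '%s' with itself", bad, df$strain_a[bad]),
          "reproiso_validation_error")
  }
  key <- apply(cbind(df$strain_a, df$strain_b), 1,
               function(x) paste(sort(x), collapse = "\r"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicate strain pair: %s",
                  paste(strsplit(dup, "\r")[[1]], collapse = " x ")),
          "reproiso_validation_error")
  }
  df$n <- df$n11 + df$n12 + df$n21 + df$n22
  if (!"n_reported" %in% names(df))
    df$n_reported <- rep(NA_integer_, nrow(df))
  mismatch <- !is.na(df$n_reported) & df$n_reported != df$n
  if (any(mismatch)) {
    rows <- df[mismatch, , drop = FALSE]
    warning(sprintf(
      "reported N differs from sum of counts for pair(s): %s",
      paste(sprintf("%s x %s (reported %d, counts sum to %d)",
                    rows$strain_a, rows$strain_b, rows$n_reported, rows$n),
            collapse = "; ")), call. = FALSE)
  }
  structure(df[c("strain_a", "strain_b", "n11", "n12", "n21", "n22",
                 "n", "n_reported")],
            class = c("mating_trials", "data.frame"))
}

#' Write a mating-trial table to CSV
#'
#' Inverse of [read_mating_trials()]: reading the written file reproduces
#' the counts exactly.
#'
#' @param trials a `mating_trials` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mating_trials <- function(trials, path) {
  out <- trials[c("strain_a", "strain_b", "n11", "n12", "n21", "n22",
                  "n_reported")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read reciprocal-cross offspring and sperm-motility records
#'
#' Each row of the CSV describes one directed cross (mother strain by
#' father strain): pooled offspring counts by sex across replicates, the
#' number of F1 males dissected, and how many of those had at least one
#' motile sperm. A male is scored motile if even a single moving sperm is
#' seen; zero motile males among a nonzero dissection count is the
#' operational definition of hybrid male sterility.
#'
#' @param path CSV with header
#'   `mother,father,replicates,females,males,males_dissected,males_motile`.
#' @return a `cross_table` data frame.
#' @seealso [analyze_crosses()], [simulate_cross()]
#' @export
read_cross_records <- function(path) {
  df <- read_strict_csv(path, required = c("mother", "father", "replicates",
                                           "females", "males",
                                           "males_dissected", "males_motile"))
  as_cross_table(df)
}

#' Construct and validate a cross-record table
#'
#' @param df data frame with the columns of [read_cross_records()].
#' @return the validated table, classed `cross_table`.
#' @export
as_cross_table <- function(df) {
  for (col in c("replicates", "females", "males",
                "males_dissected", "males_motile")) {
    if (!is_count(df[[col]]))
      abort(sprintf("column '%s' must hold non-negative integers", col),
            "reproiso_parse_error")
    df[[col]] <- as.integer(df[[col]])
  }
  if (any(df$replicates < 1))
    abort("each cross needs at least one replicate", "reproiso_validation_error")
  bad <- df$males_motile > df$males_dissected
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("row %d (%s x %s): males_motile (%d) exceeds males_dissected (%d)",
                  i, df$mother[i], df$father[i],
                  df$males_motile[i], df$males_dissected[i]),
          "reproiso_validation_error")
  }
  df$mother <- as.character(df$mother)
  df$father <- as.character(df$father)
  structure(df[c("mother", "father", "replicates", "females", "males",
                 "males_dissected", "males_motile")],
            class = c("cross_table", "data.frame"))
}

#' Write cross records to CSV
#'
#' @param crosses a `cross_table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cross_records <- function(crosses, path) {
  utils::write.csv(as.data.frame(crosses), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Strict CSV reader: comma-separated, header required, decimal point only.
# Tab-separated input is rejected outright rather than silently split on
# the wrong delimiter.
read_strict_csv <- function(path, required) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "reproiso_io_error")
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) && grepl("\t", header, fixed = TRUE))
    abort(sprintf("%s appears tab-separated; inputs must be comma-separated",
                  path), "reproiso_parse_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        strip.white = TRUE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(sprintf("%s lacks required column(s): %s", path,
                  paste(missing, collapse = ", ")), "reproiso_parse_error")
  numeric_cols <- setdiff(names(df), c("strain_a", "strain_b",
                                       "mother", "father"))
  for (col in numeric_cols) {
    v <- df[[col]]
    blank <- is.na(v) | v == ""
    ok <- blank | grepl("^-?[0-9]+$", v)
    if (!all(ok))
      abort(sprintf("%s: non-integer value '%s' in column '%s' (row %d)",
                    path, v[!ok][1], col, which(!ok)[1]),
            "reproiso_parse_error")
    v[blank] <- NA
    df[[col]] <- as.integer(v)
  }
  df
}

#' Read an aligned FASTA file into an alignment set
#'
#' All records must have identical length (the input is expected to be a
#' pre-computed alignment, e.g. concatenated COI+COII). Sequences are
#' uppercased; `U` is remapped to `T`; IUPAC ambiguity codes other than `N`
#' are remapped to `N` with a warning (treated as missing, the conservative
#' choice when no ambiguity policy is given); any other character is a
#' format error. Gaps (`-`) are kept and excluded later by pairwise
#' deletion.
#'
#' Each record is assigned a group label (a strain or population) used for
#' group-averaged divergence. If `group_map` is supplied it maps record ids
#' to groups; otherwise the token before the first underscore of the id is
#' used (so `BAJ_01` belongs to group `BAJ`).
#'
#' @param path FASTA file.
#' @param group_map optional named character vector mapping record id to
#'   group label.
#' @return an `alignment_set`: data frame with columns `id`, `group`,
#'   `sequence`, and attribute `length` (alignment columns).
#' @seealso [group_divergence_matrix()], [collapse_haplotypes()]
#' @export
read_fasta_alignment <- function(path, group_map = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "reproiso_io_error")
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  names(seqs) <- NULL
  as_alignment_set(ids, seqs, group_map = group_map)
}

#' Construct and validate an alignment set
#'
#' Applies the same character policy as [read_fasta_alignment()].
#'
#' @param ids character vector of unique record ids.
#' @param sequences character vector of aligned sequences, same length as
#'   `ids`.
#' @param groups optional character vector of group labels per record.
#' @param group_map optional named vector mapping id to group; ignored when
#'   `groups` is given.
#' @return an `alignment_set` data frame.
#' @export
as_alignment_set <- function(ids, sequences, groups = NULL, group_map = NULL) {
  if (length(ids) != length(sequences))
    abort("ids and sequences differ in length", "reproiso_validation_error")
  if (anyDuplicated(ids))
    abort(sprintf("duplicate record id: %s", ids[duplicated(ids)][1]),
          "reproiso_validation_error")
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  ambig <- "RYSWKMBDHV"
  has_ambig <- grepl(sprintf("[%s]", ambig), sequences)
  if (any(has_ambig)) {
    warning(sprintf(
      "IUPAC ambiguity codes remapped to N in record(s): %s",
      paste(ids[has_ambig], collapse = ", ")), call. = FALSE)
    sequences <- chartr(ambig, strrep("N", nchar(ambig)), sequences)
  }
  invalid <- grepl("[^ACGTN-]", sequences)
  if (any(invalid)) {
    i <- which(invalid)[1]
    ch <- regmatches(sequences[i], regexpr("[^ACGTN-]", sequences[i]))
    abort(sprintf("record '%s' contains invalid character '%s'", ids[i], ch),
          "reproiso_format_error")
  }
  len <- unique(nchar(sequences))
  if (length(len) > 1) {
    i <- which(nchar(sequences) != nchar(sequences)[1])[1]
    abort(sprintf("record '%s' has length %d; expected %d (not an alignment?)",
                  ids[i], nchar(sequences)[i], nchar(sequences)[1]),
          "reproiso_alignment_error")
  }
  if (is.null(groups)) {
    if (!is.null(group_map)) {
      miss <- setdiff(ids, names(group_map))
      if (length(miss))
        abort(sprintf("group_map lacks id(s): %s", paste(miss, collapse = ", ")),
              "reproiso_validation_error")
      groups <- unname(group_map[ids])
    } else {
      groups <- sub("_.*$", "", ids)
    }
  }
  structure(
    data.frame(id = as.character(ids), group = as.character(groups),
               sequence = sequences, stringsAsFactors = FALSE),
    length = if (length(len)) len else 0L,
    class = c("alignment_set", "data.frame"))
}

#' Alignment length (number of columns)
#'
#' @param aln an `alignment_set`.
#' @return integer column count.
#' @export
alignment_length <- function(aln) attr(aln, "length")

#' Read a key=value configuration file
#'
#' One `key=value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are returned as character and interpreted by
#' [run_pipeline()]. Recognised keys: `trials`, `crosses`, `alignment`,
#' `group_map` (two-column CSV id,group), `out_dir`, `seed`, `digits`.
#'
#' @param path configuration file.
#' @return named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "reproiso_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ok <- grepl("=", lines, fixed = TRUE)
  if (!all(ok))
    abort(sprintf("config line without '=': %s", lines[!ok][1]),
          "reproiso_parse_error")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}
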