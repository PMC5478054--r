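#' Path to a bundled example data file
#'
#' The package ships transcriptions of the published *Drosophila aldrichi*
#' result tables so every stage can be exercised and checked against the
#' printed values:
#'
#' * `mating_trials_table3.csv` -- multiple-choice mating counts for the
#'   15 strain pairs (Baja, Guerrero, Oaxaca, Huatulco, Tehuacan, Sonora);
#' * `table3_published.csv` -- the printed isolation statistics for those
#'   pairs (kept as printed strings so the printed precision is known);
#' * `crosses_table2a.csv` -- the six homotypic reciprocal crosses with
#'   offspring sex counts and sperm-motility dissections;
#' * `table2a_published.csv` -- the printed sex-ratio chi-squares.
#'
#' @param file file name, or `NULL` to list available files.
#' @return full path to the file.
#' @export
#' @examples
#' reproiso_example()
#' read_mating_trials(reproiso_example("mating_trials_table3.csv"))
reproiso_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "reproiso")))
  path <- system.file("extdata", file, package = "reproiso")
  if (path == "")
    abort(sprintf("no bundled file named '%s'", file), "reproiso_io_error")
  path
}

#' Compare recomputed statistics against a printed table
#'
#' A recomputed value is taken to match a printed one when it lies within
#' one unit in the printed value's last decimal place. That band accepts
#' both genuine rounding and the occasional truncation seen in published
#' tables (e.g. 0.625 printed as 0.62), while still catching every real
#' transcription or computation inconsistency.
#'
#' @param computed numeric vector of recomputed values.
#' @param printed character vector of values as printed (strings, so the
#'   number of printed decimals is preserved).
#' @return logical vector: does each computed value match its printed
#'   counterpart? `NA` printed entries give `NA`.
#' @export
matches_printed <- function(computed, printed) {
  printed <- as.character(printed)
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^-?[0-9]*\\.", "", printed)), 0L)
  tol <- 10^(-dec)
  out <- abs(computed - as.numeric(printed)) < tol
  out[is.na(printed) | printed == ""] <- NA
  out
}
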