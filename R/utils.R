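#' Round half away from zero
#'
#' Printed tables in the mating-test literature round 0.125 to 0.13 and
#' -0.125 to -0.13; base R's [round()] rounds half to even. This helper
#' reproduces the tabular convention for report output. Internal statistics
#' are always kept at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, matching the tables).
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_away(c(0.125, -0.125, 0.1852), 2)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a classed condition so callers/tests can distinguish
# validation failures from parse failures etc.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "reproiso_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}
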