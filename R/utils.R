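#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_immunet <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Round half away from zero
#'
#' Rounding convention used for all reported percentages: ties go away from
#' zero (so 15.5 -> 16), unlike base [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep (0 for integer rounding).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used to score recovery of planted cluster structure. Returns 1 for
#' identical partitions (up to relabeling) and has expectation 0 for
#' independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type; `NA` allowed
#'   and treated as its own label).
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop_immunet("label vectors differ in length (%d vs %d)",
                 length(a), length(b))
  }
  a <- addNA(factor(a), ifany = TRUE)
  b <- addNA(factor(b), ifany = TRUE)
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(length(a))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
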