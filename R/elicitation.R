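#' Convert roulette-method chip allocations to a probability vector
#'
#' Experts allocate chips across bins (the "chips and bins" or histogram
#' method); the fraction of chips per bin is the elicited probability.
#'
#' @param chips Non-negative counts, one per bin.
#' @return Numeric probability vector of the same length, summing to 1.
#' @export
#' @examples
#' roulette_to_distribution(c(2, 18, 16, 4))
roulette_to_distribution <- function(chips) {
  chips <- as.numeric(chips)
  if (length(chips) == 0 || any(!is.finite(chips)) || any(chips < 0)) {
    abort_emibayes("elicitation", "chips must be non-negative finite counts")
  }
  total <- sum(chips)
  if (total <= 0) {
    abort_emibayes("elicitation",
                   "degenerate elicitation: all chip counts are zero")
  }
  p <- chips / total
  names(p) <- names(chips)
  p
}

#' Convert a per-100-subjects elicitation column to a level distribution
#'
#' The elicited answer tables record, for 100 subjects at a given true level,
#' how many would give each of the four answers; dividing by the total turns
#' a column into a conditional probability distribution.
#'
#' @param counts Four non-negative counts in absent..high (or least..most
#'   severe answer) order.
#' @return A level distribution.
#' @export
#' @examples
#' counts_to_distribution(c(0, 5, 15, 80))
counts_to_distribution <- function(counts) {
  if (length(counts) != 4L) {
    abort_emibayes("elicitation", "expected exactly 4 counts")
  }
  level_distribution(roulette_to_distribution(counts))
}
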