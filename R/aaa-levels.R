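#' Ordered severity levels
#'
#' All clinical quantities in the network — the immediate value of a factor
#' (IF), its cumulated value (CF) and its contextual severity (CS) — live on
#' the same ordered four-level domain: absent < low < medium < high.
#' Distributions over this domain are plain named numeric vectors in that
#' fixed order.
#'
#' @format Character vector of length 4.
#' @export
severity_levels <- c("absent", "low", "medium", "high")

# Tolerance used everywhere a stored distribution row must sum to one.
DIST_TOL <- 1e-9

#' Construct a distribution over the four severity levels
#'
#' @param p Numeric vector of four probabilities in absent..high order.
#' @param tol Normalisation tolerance.
#' @return Named numeric vector (a valid level distribution).
#' @export
level_distribution <- function(p, tol = DIST_TOL) {
  p <- as.numeric(p)
  if (length(p) != 4L) {
    abort_emibayes("validation", "a level distribution needs exactly 4 entries")
  }
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    abort_emibayes(
      "validation",
      sprintf("not a probability distribution: entries [%s] (sum %.12f)",
              paste(signif(p, 6), collapse = ", "), sum(p))
    )
  }
  p <- pmax(p, 0)
  names(p) <- severity_levels
  p
}

is_level_distribution <- function(p, tol = DIST_TOL) {
  is.numeric(p) && length(p) == 4L && all(is.finite(p)) &&
    all(p >= -tol) && abs(sum(p) - 1) <= tol
}

#' Point-mass distribution at one severity level
#'
#' @param level One of `severity_levels` or its 0-based index.
#' @export
point_mass <- function(level) {
  idx <- level_index(level)
  p <- numeric(4)
  p[idx] <- 1
  names(p) <- severity_levels
  p
}

# Accepts level names or 0-based codes; returns 1-based index.
level_index <- function(level) {
  if (is.character(level)) {
    idx <- match(level, severity_levels)
    if (anyNA(idx)) {
      abort_emibayes("parameter", sprintf("unknown severity level '%s'", level))
    }
    return(idx)
  }
  idx <- as.integer(level) + 1L
  if (anyNA(idx) || any(idx < 1L) || any(idx > 4L)) {
    abort_emibayes("parameter", "severity level code must be in 0..3")
  }
  idx
}

#' Expected-severity score of a level distribution
#'
#' Maps a distribution over absent..high to a scalar in \[0, 1\]:
#' the expected level index divided by 3. Used for the signed review exports,
#' where the immediate value is plotted positive and contextual severity
#' negative.
#'
#' @param p A level distribution.
#' @export
severity_score <- function(p) {
  sum(as.numeric(p) * 0:3) / 3
}

# CDF dominance over ordered levels: TRUE if x is stochastically <= y
# (x's CDF everywhere >= y's).
stochastically_leq <- function(x, y, tol = 1e-12) {
  all(cumsum(x)[1:3] >= cumsum(y)[1:3] - tol)
}
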