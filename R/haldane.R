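#' Haldane map function
#'
#' Convert a sex-averaged map distance in Haldane centiMorgans to a
#' recombination fraction, assuming no crossover interference:
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d Numeric vector of map distances in centiMorgans; must be
#'   non-negative.
#' @return Recombination fractions in \eqn{[0, 0.5)}.
#' @seealso [r_to_haldane_cm()] for the inverse.
#' @examples
#' haldane_cm_to_r(c(0, 10, 50))
#' @export
haldane_cm_to_r <- function(d) {
  if (!is.numeric(d) || anyNA(d)) stop("'d' must be numeric without NA")
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' Inverse Haldane map function
#'
#' Convert a recombination fraction to a Haldane map distance in
#' centiMorgans: \eqn{d = -50 \log(1 - 2r)}.
#'
#' @param r Numeric vector of recombination fractions in \eqn{[0, 0.5)}.
#' @return Map distances in centiMorgans.
#' @export
r_to_haldane_cm <- function(r) {
  if (!is.numeric(r) || anyNA(r)) stop("'r' must be numeric without NA")
  if (any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}
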