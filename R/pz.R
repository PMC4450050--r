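#' Convert two-sided p values to absolute Z scores
#'
#' The package uses the two-sided convention throughout: `|z| = qnorm(1 - p/2)`.
#' Signs of effects are never needed by any quantity computed here and are not
#' stored.
#'
#' @param p Numeric vector of p values in (0, 1]. Exact zeros are clamped to
#'   `1e-300` with a warning, since downstream estimators divide by quantities
#'   derived from p.
#' @return Non-negative numeric vector of |Z| values.
#' @seealso [z_to_p()]
#' @export
#' @examples
#' p_to_z(c(0.5, 0.01, 1))
p_to_z <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p values must be finite and in [0, 1]")
  }
  if (any(p == 0)) {
    warning("p values of exactly 0 clamped to 1e-300")
    p[p == 0] <- 1e-300
  }
  # lower.tail = FALSE keeps full precision for tiny p
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Convert absolute Z scores to two-sided p values
#'
#' Inverse of [p_to_z()]: `p = 2 * pnorm(-|z|)`.
#'
#' @param z Numeric vector of |Z| values (non-negative).
#' @return Numeric vector of two-sided p values in (0, 1].
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z) | z < 0)) stop("z values must be finite and >= 0")
  2 * stats::pnorm(z, lower.tail = FALSE)
}
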