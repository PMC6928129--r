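#' Normalized Hill activation function
#'
#' Sigmoid activation kernel of the logic-based ODE engine, rescaled so that
#' \eqn{f(0) = 0}, \eqn{f(EC_{50}) = 0.5} and \eqn{f(1) = 1}:
#' \deqn{f(x) = \frac{B x^n}{K^n + x^n}, \quad
#'       B = \frac{EC_{50}^n - 1}{2 EC_{50}^n - 1}, \quad K^n = B - 1.}
#' This is the activation convention used by the Netflux family of
#' logic-based network models.
#'
#' @param x numeric vector of normalized activities in \code{[0, 1]}.
#' @param hill_n Hill coefficient (> 0). Default 1.4.
#' @param ec50 half-maximal activation level, strictly between 0 and 1
#'   (and with \code{ec50^hill_n != 0.5}, where the rescaling is singular).
#'   Default 0.6.
#' @return numeric vector of activations in \code{[0, 1]}.
#' @examples
#' normalized_hill_activation(c(0, 0.6, 1))   # 0, 0.5, 1
#' @export
normalized_hill_activation <- function(x, hill_n = 1.4, ec50 = 0.6) {
  if (hill_n <= 0) stop("hill_n must be > 0")
  if (ec50 <= 0 || ec50 >= 1) stop("ec50 must lie strictly between 0 and 1")
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE))
    stop("activity x outside [0, 1]")
  x <- pmin(pmax(x, 0), 1)
  en <- ec50^hill_n
  if (abs(2 * en - 1) < 1e-12)
    stop("ec50^hill_n == 0.5 makes the normalized Hill rescaling singular")
  B <- (en - 1) / (2 * en - 1)
  Kn <- B - 1
  B * x^hill_n / (Kn + x^hill_n)
}

# inclusive-or fold: g1 + g2 - g1*g2, elementwise over a list of vectors
.or_fold <- function(gs) {
  out <- gs[[1L]]
  if (length(gs) > 1L)
    for (k in 2L:length(gs)) out <- out + gs[[k]] - out * gs[[k]]
  out
}
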