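#' Langevin function
#'
#' Equilibrium magnetization of a classical superparamagnetic moment,
#' `L(xi) = coth(xi) - 1/xi`, with the Taylor branch
#' `xi/3 - xi^3/45 + 2 xi^5/945` used for |xi| < 0.01, where the direct
#' expression loses precision to cancellation; the function is finite and odd
#' through zero. Vectorized.
#'
#' @param xi Dimensionless field argument `mu * B / (k_B * T)`; any finite
#'   numeric vector.
#' @return Values in (-1, 1), same shape as `xi`.
#' @examples
#' langevin(c(-1, 0, 1))
#' @export
langevin <- function(xi) {
  out <- xi
  small <- abs(xi) < 0.01
  x <- xi[small]
  out[small] <- x / 3 - x^3 / 45 + 2 * x^5 / 945
  x <- xi[!small]
  out[!small] <- 1 / tanh(x) - 1 / x
  out
}
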