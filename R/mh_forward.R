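#' Magnetization curve container
#'
#' Holds sampled pairs of applied field and iron-normalized magnetization.
#' Fields are stored as flux density B in tesla; magnetization in
#' Am^2/mol(Fe).
#'
#' @param field_t Applied field values in T, strictly increasing.
#' @param magnetization Molar magnetization in Am^2/mol(Fe), finite, same
#'   length as `field_t`.
#' @param temperature Measurement temperature in K.
#' @return An object of class `magnetization_curve`.
#' @export
magnetization_curve <- function(field_t, magnetization, temperature = 295) {
  stopifnot(length(field_t) == length(magnetization),
            all(is.finite(field_t)), all(is.finite(magnetization)),
            temperature > 0)
  if (length(field_t) > 1 && any(diff(field_t) <= 0))
    stop("field grid must be strictly increasing")
  structure(list(field_t = as.numeric(field_t),
                 magnetization = as.numeric(magnetization),
                 temperature = temperature),
            class = "magnetization_curve")
}

#' @export
print.magnetization_curve <- function(x, ...) {
  cat(sprintf("Magnetization curve: %d points, B in [%.3g, %.3g] T, T = %g K\n",
              length(x$field_t), min(x$field_t), max(x$field_t), x$temperature))
  invisible(x)
}

# Cached Gauss-Hermite rule (pracma); keyed by node count.
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

# Mean Langevin response of one lognormal mode at fields b (T):
# <L>(b) = (1/sqrt(pi)) sum_j w_j L(exp(m + sqrt(2) sigma x_j) * b / kT)
# with m = log(mean_mu) - sigma^2/2 (volume-weighted mean parameterization).
mode_mean_langevin <- function(b, mean_mu, sigma, temperature, constants, nodes) {
  kt <- constants$boltzmann * temperature
  if (sigma == 0) return(langevin(mean_mu * b / kt))
  gh <- gauss_hermite_rule(nodes)
  mu_j <- exp(log(mean_mu) - sigma^2 / 2 + sqrt(2) * sigma * gh$x)
  # outer over fields x nodes, weighted sum along nodes
  acc <- numeric(length(b))
  for (j in seq_along(mu_j)) {
    acc <- acc + gh$w[j] * langevin(mu_j[j] * b / kt)
  }
  acc / sqrt(pi)
}

#' Forward M(H) model of a bimodal lognormal moment distribution
#'
#' Computes the equilibrium molar magnetization of an ensemble of
#' non-interacting superparamagnetic moments,
#' `M(B) = M_S [(1 - beta) <L>_A + beta <L>_B]`, where `<L>_i` is the
#' Langevin function averaged over the volume-weighted lognormal moment
#' density of mode i. The lognormal averages are evaluated by Gauss-Hermite
#' quadrature in log-moment (default 61 nodes). The model is odd in B.
#'
#' @param dist A [moment_distribution()].
#' @param field_t Applied field values in T (any finite numeric vector; may be
#'   negative).
#' @param temperature Temperature in K; defaults to the distribution's.
#' @param constants A [material_constants()] object.
#' @param nodes Number of Gauss-Hermite quadrature nodes (odd recommended).
#' @return If `field_t` is strictly increasing, a [magnetization_curve()];
#'   otherwise a numeric vector of magnetizations (Am^2/mol(Fe)).
#' @examples
#' m <- mh_forward(reference_tracer(), c(0.001, 0.01, 0.1, 1, 5))
#' @export
mh_forward <- function(dist, field_t, temperature = dist$temperature,
                       constants = material_constants(), nodes = 61) {
  stopifnot(inherits(dist, "moment_distribution"), all(is.finite(field_t)),
            nodes >= 3)
  m <- dist$ms_molar *
    ((1 - dist$beta) * mode_mean_langevin(field_t, dist$mu1, dist$sigma1,
                                          temperature, constants, nodes) +
     dist$beta * mode_mean_langevin(field_t, dist$mu2, dist$sigma2,
                                    temperature, constants, nodes))
  increasing <- length(field_t) > 1 && all(diff(field_t) > 0)
  if (increasing) magnetization_curve(field_t, m, temperature) else m
}

#' Magnetometry field grid
#'
#' Standard quasi-static magnetometry sweeps sample the field
#' logarithmically so that both the low-field (large-moment) and high-field
#' (small-moment) response are resolved. Returns `n` points: H = 0 followed by
#' a geometric sequence from `b_min` to `b_max`.
#'
#' @param n Total number of field points (>= 3).
#' @param b_min,b_max Smallest nonzero and largest field in T.
#' @return Strictly increasing numeric vector of length `n`, starting at 0.
#' @export
mh_field_grid <- function(n = 50, b_min = 1e-4, b_max = 5) {
  stopifnot(n >= 3, b_min > 0, b_max > b_min)
  c(0, exp(seq(log(b_min), log(b_max), length.out = n - 1)))
}
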