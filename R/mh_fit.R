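#' Subtract a blank measurement from a raw magnetization curve
#'
#' Magnetometry of dispersions includes the sample holder and the diamagnetic
#' medium, which contribute an approximately linear-in-field background. The
#' blank curve is interpolated onto the raw field grid (linear, with linear
#' extrapolation of the dominant diamagnetic slope at the ends) and subtracted
#' pointwise; the result is optionally normalized per mole of iron.
#'
#' @param raw Raw sample [magnetization_curve()] (moment or magnetization
#'   units; see `iron_mol`).
#' @param blank Blank/background [magnetization_curve()] on the same units.
#' @param iron_mol Moles of iron in the sample; if given, the difference is
#'   divided by it to yield Am^2/mol(Fe). Default 1 (no renormalization).
#' @return A [magnetization_curve()] on the raw field grid.
#' @export
subtract_background <- function(raw, blank, iron_mol = 1) {
  stopifnot(inherits(raw, "magnetization_curve"),
            inherits(blank, "magnetization_curve"), iron_mol > 0)
  rng_r <- range(raw$field_t); rng_b <- range(blank$field_t)
  if (rng_b[1] > rng_r[1] + 1e-12 || rng_b[2] < rng_r[2] - 1e-12) {
    # tolerate modest extrapolation (<= 5% of blank span); otherwise reject
    span <- diff(rng_b)
    if (rng_b[1] - rng_r[1] > 0.05 * span || rng_r[2] - rng_b[2] > 0.05 * span)
      stop("blank field range does not cover the raw field range")
  }
  bg <- stats::approx(blank$field_t, blank$magnetization, xout = raw$field_t,
                      rule = 2)$y
  magnetization_curve(raw$field_t, (raw$magnetization - bg) / iron_mol,
                      raw$temperature)
}

#' Fit the bimodal lognormal moment model to an M(H) curve
#'
#' Weighted bounded least squares of [mh_forward()] against measured data in
#' the six free parameters (beta, mu1, mu2, sigma1, sigma2, M_S), with the two
#' mode moments log-parameterized for conditioning. Uses Levenberg-Marquardt
#' with box bounds. After convergence the modes are ordered so that
#' mu1 < mu2 (swapping labels and replacing beta by 1 - beta if needed), which
#' prevents label switching between runs.
#'
#' @param curve A [magnetization_curve()] to fit.
#' @param init A [moment_distribution()] giving the starting parameters.
#' @param weights Per-point weights (default uniform).
#' @param constants A [material_constants()] object.
#' @param nodes Quadrature nodes for the forward model.
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `mh_fit` with elements `distribution` (fitted
#'   [moment_distribution()]), `se` (approximate standard errors, NA where the
#'   Jacobian is degenerate), `residual_norm`, `iterations`, `converged`, and
#'   `derived` (d_v2 in nm, beta_mu2 in aAm^2).
#' @export
fit_mh <- function(curve, init = NULL, weights = NULL,
                   constants = material_constants(), nodes = 61,
                   max_iter = 200) {
  stopifnot(inherits(curve, "magnetization_curve"))
  npt <- length(curve$field_t)
  if (npt < 8 * 6 / 8)  # guard against clearly underdetermined input
    stop("need substantially more data points than the 6 free parameters")
  if (is.null(init)) init <- default_mh_init(curve, constants)
  if (is.null(weights)) weights <- rep(1, npt)
  stopifnot(length(weights) == npt, all(weights >= 0))

  aam2 <- 1e-18
  par0 <- c(beta = init$beta,
            lmu1 = log(init$mu1 / aam2), lmu2 = log(init$mu2 / aam2),
            sigma1 = init$sigma1, sigma2 = init$sigma2,
            ms = init$ms_molar)
  lower <- c(0, log(1e-3), log(1e-3), 0, 0, 1e-6)
  upper <- c(1, log(1e3), log(1e3), 1.5, 1.5, Inf)
  par0 <- pmin(pmax(par0, lower), upper)
  sw <- sqrt(weights)
  resid_fn <- function(p) {
    d <- moment_distribution(p[1], exp(p[2]) * aam2, exp(p[3]) * aam2,
                             p[4], p[5], p[6], curve$temperature)
    m <- mh_forward(d, curve$field_t, curve$temperature, constants, nodes)
    if (inherits(m, "magnetization_curve")) m <- m$magnetization
    sw * (m - curve$magnetization)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  p <- unname(unlist(fit$par))
  # enforce mu1 < mu2 mode labelling
  if (p[2] > p[3]) {
    p <- c(1 - p[1], p[3], p[2], p[5], p[4], p[6])
  }
  dist <- moment_distribution(p[1], exp(p[2]) * aam2, exp(p[3]) * aam2,
                              p[4], p[5], p[6], curve$temperature)
  converged <- fit$info %in% 1:4
  # delta-method standard errors on the internal parameterization
  se <- rep(NA_real_, 6)
  cov_try <- try(suppressWarnings(vcov(fit)), silent = TRUE)
  if (!inherits(cov_try, "try-error") && all(is.finite(diag(cov_try))))
    se <- sqrt(pmax(diag(cov_try), 0))
  names(se) <- c("beta", "log_mu1", "log_mu2", "sigma1", "sigma2", "ms_molar")
  structure(list(
    distribution = dist,
    se = se,
    residual_norm = sqrt(sum(fit$fvec^2)),
    iterations = fit$niter,
    converged = converged,
    info = fit$info,
    message = fit$message,
    derived = list(
      d_v2_nm = moment_to_diameter(dist$mu2, dist$ms_molar, constants),
      beta_mu2_aAm2 = dist$beta * dist$mu2 / aam2)),
    class = "mh_fit")
}

# Physically motivated default initialization: mode A at a 10 nm domain
# moment, mode B at the TEM-scale mean moment, even volume split.
default_mh_init <- function(curve, constants, tem_diameter_nm = 25) {
  ms0 <- max(abs(curve$magnetization)) * 1.05
  moment_distribution(beta = 0.5,
                      mu1 = diameter_to_moment(10, ms0, constants),
                      mu2 = diameter_to_moment(tem_diameter_nm, ms0, constants),
                      sigma1 = 0.2, sigma2 = 0.2,
                      ms_molar = ms0, temperature = curve$temperature)
}

#' @export
print.mh_fit <- function(x, ...) {
  d <- x$distribution
  cat("Bimodal lognormal M(H) fit",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  beta   = %.4f\n", d$beta))
  cat(sprintf("  mu1    = %.4g aAm^2, sigma1 = %.3f\n", d$mu1 * 1e18, d$sigma1))
  cat(sprintf("  mu2    = %.4g aAm^2, sigma2 = %.3f\n", d$mu2 * 1e18, d$sigma2))
  cat(sprintf("  M_S    = %.4g Am^2/mol(Fe)\n", d$ms_molar))
  cat(sprintf("  d_v2   = %.3g nm, beta*mu2 = %.3g aAm^2\n",
              x$derived$d_v2_nm, x$derived$beta_mu2_aAm2))
  cat(sprintf("  residual norm %.3g after %d iterations\n",
              x$residual_norm, x$iterations))
  invisible(x)
}

#' Summarize a fitted moment distribution against TEM sizing
#'
#' Derives the headline characterization numbers from a fit: the mode-B
#' equivalent volume diameter, the signal-weighted moment beta*mu2, the
#' percent by which the magnetic diameter is smaller than the TEM mean
#' diameter, the corresponding equivalent-volume difference, and the mode-B
#' volume share in percent.
#'
#' @param fit An `mh_fit` object (or a [moment_distribution()]).
#' @param tem_mean_diameter_nm Mean core diameter from TEM, nm.
#' @param constants A [material_constants()] object.
#' @return A list of class `mh_summary`.
#' @export
derive_summary <- function(fit, tem_mean_diameter_nm,
                           constants = material_constants()) {
  dist <- if (inherits(fit, "mh_fit")) fit$distribution else fit
  stopifnot(inherits(dist, "moment_distribution"), tem_mean_diameter_nm > 0)
  d_v2 <- moment_to_diameter(dist$mu2, dist$ms_molar, constants)
  structure(list(
    d_v2_nm = d_v2,
    beta_mu2_aAm2 = dist$beta * dist$mu2 * 1e18,
    mode_b_volume_percent = 100 * dist$beta,
    percent_smaller_than_tem = 100 * (1 - d_v2 / tem_mean_diameter_nm),
    volume_percent_difference = 100 * (1 - (d_v2 / tem_mean_diameter_nm)^3),
    tem_mean_diameter_nm = tem_mean_diameter_nm),
    class = "mh_summary")
}

#' @export
print.mh_summary <- function(x, ...) {
  cat("Moment-distribution summary\n")
  cat(sprintf("  d_v2              : %.3g nm\n", x$d_v2_nm))
  cat(sprintf("  beta*mu2          : %.3g aAm^2\n", x$beta_mu2_aAm2))
  cat(sprintf("  mode B volume     : %.1f%%\n", x$mode_b_volume_percent))
  cat(sprintf("  vs TEM (%.3g nm)  : %.0f%% smaller in diameter, %.0f%% in volume\n",
              x$tem_mean_diameter_nm, x$percent_smaller_than_tem,
              x$volume_percent_difference))
  invisible(x)
}

#' Write a fit report as a structured text table
#'
#' @param fit An `mh_fit` object.
#' @param path Output file path (CSV: key, value, uncertainty, unit).
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "mh_fit"))
  d <- fit$distribution
  df <- data.frame(
    key = c("beta", "mu1", "mu2", "sigma1", "sigma2", "ms_molar",
            "d_v2", "beta_mu2", "residual_norm", "converged"),
    value = c(d$beta, d$mu1 * 1e18, d$mu2 * 1e18, d$sigma1, d$sigma2,
              d$ms_molar, fit$derived$d_v2_nm, fit$derived$beta_mu2_aAm2,
              fit$residual_norm, as.numeric(fit$converged)),
    uncertainty = c(fit$se["beta"], NA, NA, fit$se["sigma1"], fit$se["sigma2"],
                    fit$se["ms_molar"], NA, NA, NA, NA),
    unit = c("", "aAm^2", "aAm^2", "", "", "Am^2/mol(Fe)", "nm", "aAm^2",
             "Am^2/mol(Fe)", ""))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
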