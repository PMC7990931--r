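#' Tissue--seawater oxygen isotope calibration model
#'
#' The linear relation between biogenic-apatite phosphate delta-18O and
#' ambient seawater delta-18O,
#' \deqn{\delta^{18}O_P = \beta_0 + \beta_1 \, \delta^{18}O_{marine},}
#' with parameter uncertainties and the analytical measurement error on the
#' tissue value. Defaults are the published interspecific cetacean
#' calibration (intercept 18.73 +/- 0.30 per mil, slope 0.81 +/- 0.23) and
#' the average replicate reproducibility of phosphate delta-18O analyses
#' (+/- 0.22 per mil).
#'
#' @param beta0_mean,beta0_sd Intercept mean and SD, per mil.
#' @param beta1_mean,beta1_sd Slope mean and SD (dimensionless).
#' @param meas_sd Measurement SD on delta-18O_P, per mil.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(beta0_mean = 18.73, beta0_sd = 0.30,
                              beta1_mean = 0.81, beta1_sd = 0.23,
                              meas_sd = 0.22) {
  if (beta1_mean == 0) {
    stop("invalid calibration: slope beta1_mean must be nonzero", call. = FALSE)
  }
  sds <- c(beta0_sd = beta0_sd, beta1_sd = beta1_sd, meas_sd = meas_sd)
  if (any(sds < 0)) {
    stop("invalid calibration: SDs must be non-negative (",
         paste(names(sds)[sds < 0], collapse = ", "), ")", call. = FALSE)
  }
  structure(list(beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 beta1_mean = beta1_mean, beta1_sd = beta1_sd,
                 meas_sd = meas_sd),
            class = "calibration_model")
}

stopifnot_calibration <- function(calib) {
  if (!inherits(calib, "calibration_model")) {
    calib <- do.call(calibration_model, as.list(calib))
  }
  if (calib$beta1_mean == 0) {
    stop("invalid calibration: slope beta1_mean must be nonzero", call. = FALSE)
  }
  calib
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration: d18O_P = %.2f (+/- %.2f) + %.2f (+/- %.2f) * d18O_marine; meas SD %.2f\n",
    x$beta0_mean, x$beta0_sd, x$beta1_mean, x$beta1_sd, x$meas_sd))
  invisible(x)
}

#' Invert the calibration to estimate source seawater delta-18O
#'
#' Algebraic rearrangement of the calibration line:
#' `(x - beta0) / beta1`, the point estimate of the seawater delta-18O that
#' produced a measured tissue value `x`.
#'
#' @param x Measured delta-18O_P, per mil VSMOW (vectorised).
#' @param calib A [calibration_model()].
#' @return Estimated delta-18O_marine, per mil VSMOW.
#' @export
invert_calibration <- function(x, calib = calibration_model()) {
  calib <- stopifnot_calibration(calib)
  (x - calib$beta0_mean) / calib$beta1_mean
}

#' Delta-method standard error of the seawater estimate
#'
#' First-order Taylor expansion of `(x - beta0) / beta1` with `x`, `beta0`
#' and `beta1` treated as independent:
#' \deqn{SE^2 = \frac{\sigma_x^2 + \sigma_{\beta_0}^2}{\beta_1^2}
#'   + \frac{(x - \beta_0)^2}{\beta_1^4}\,\sigma_{\beta_1}^2.}
#' The slope-uncertainty term grows with leverage, so the SE is
#' non-decreasing in `|x - beta0|`.
#'
#' @inheritParams invert_calibration
#' @return Propagated SE, per mil (vectorised).
#' @seealso [mc_oracle_se()] for a simulation-based check.
#' @export
propagate_se <- function(x, calib = calibration_model()) {
  calib <- stopifnot_calibration(calib)
  b1 <- calib$beta1_mean
  var_num <- (calib$meas_sd^2 + calib$beta0_sd^2) / b1^2
  var_slope <- (x - calib$beta0_mean)^2 * calib$beta1_sd^2 / b1^4
  sqrt(var_num + var_slope)
}

#' Per-specimen seawater delta-18O estimates with confidence intervals
#'
#' Combines [invert_calibration()] and [propagate_se()] and attaches a
#' symmetric normal-quantile confidence interval
#' `m_hat +/- z * se` (z = 1.959964 at the default 95% level).
#'
#' @param records Specimen data frame with `specimen_id` and `d18O_p`
#'   columns, as from [read_specimens()].
#' @param calib A [calibration_model()].
#' @param ci_level Two-sided confidence level in (0, 1).
#' @return Data frame with columns `specimen_id`, `d18O_p`, `m_hat`, `se`,
#'   `ci_level`, `ci_lo`, `ci_hi` (all isotope columns per mil VSMOW).
#' @export
estimate_marine <- function(records, calib = calibration_model(),
                            ci_level = 0.95) {
  calib <- stopifnot_calibration(calib)
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be a single number in (0, 1)", call. = FALSE)
  }
  x <- records$d18O_p
  if (any(is.na(x))) {
    stop("missing d18O_p for specimen(s): ",
         paste(records$specimen_id[is.na(x)], collapse = ", "), call. = FALSE)
  }
  m_hat <- invert_calibration(x, calib)
  se <- propagate_se(x, calib)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(specimen_id = records$specimen_id,
             d18O_p = x,
             m_hat = m_hat,
             se = se,
             ci_level = ci_level,
             ci_lo = m_hat - z * se,
             ci_hi = m_hat + z * se,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo oracle for the propagated standard error
#'
#' Simulation check on [propagate_se()]. Draws `n_draws` independent normal
#' samples of the measured value, the intercept and the slope, and returns
#' the sample SD of the propagated seawater estimate. Deterministic given
#' `seed`.
#'
#' The default `method = "linearized"` pushes the draws through the
#' first-order expansion of `g(x, b0, b1) = (x - b0) / b1` around the
#' means, with the gradient obtained by central finite differences of `g`
#' itself — independent of the closed-form variance algebra it checks. Its
#' sample SD converges to the quantity a first-order Taylor propagation
#' estimates (relative Monte-Carlo error about `1/sqrt(2 n_draws)`).
#'
#' `method = "exact"` applies `g` to the raw draws instead. Because the
#' slope is normal, the exact ratio has no finite variance: with a slope CV
#' near 30% its sample SD is dominated by rare near-zero slope draws and
#' does not stabilise with `n_draws`. It is retained to document how far
#' the first-order treatment is from the exact ratio distribution.
#'
#' @param x Measured delta-18O_P, per mil (scalar).
#' @param calib A [calibration_model()].
#' @param n_draws Number of draws (at least 1e4).
#' @param seed Integer seed.
#' @param method `"linearized"` (default) or `"exact"`, see Details.
#' @return Sample SD of the simulated seawater estimates, per mil.
#' @export
mc_oracle_se <- function(x, calib = calibration_model(),
                         n_draws = 1e6, seed = 1L,
                         method = c("linearized", "exact")) {
  calib <- stopifnot_calibration(calib)
  method <- match.arg(method)
  if (n_draws < 1e4) stop("n_draws must be at least 1e4", call. = FALSE)
  stopifnot(length(x) == 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xs <- stats::rnorm(n_draws, x, calib$meas_sd)
  b0 <- stats::rnorm(n_draws, calib$beta0_mean, calib$beta0_sd)
  b1 <- stats::rnorm(n_draws, calib$beta1_mean, calib$beta1_sd)
  g <- function(x, b0, b1) (x - b0) / b1
  if (method == "exact") {
    return(stats::sd(g(xs, b0, b1)))
  }
  h <- 1e-6
  grad <- c(
    (g(x + h, calib$beta0_mean, calib$beta1_mean) -
       g(x - h, calib$beta0_mean, calib$beta1_mean)) / (2 * h),
    (g(x, calib$beta0_mean + h, calib$beta1_mean) -
       g(x, calib$beta0_mean - h, calib$beta1_mean)) / (2 * h),
    (g(x, calib$beta0_mean, calib$beta1_mean + h) -
       g(x, calib$beta0_mean, calib$beta1_mean - h)) / (2 * h))
  lin <- grad[1L] * (xs - x) + grad[2L] * (b0 - calib$beta0_mean) +
    grad[3L] * (b1 - calib$beta1_mean)
  stats::sd(lin)
}

# save/restore the global RNG state so oracle calls do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
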