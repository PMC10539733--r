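#' Relaxation time series
#'
#' Light container for a relaxation experiment: inversion recovery,
#' echo/CPMG decay or NOE build-up. Repeated time points are allowed and
#' treated as independent observations (the acquisition schedules repeat
#' one delay for uncertainty estimation).
#'
#' @param times Delay/saturation times in seconds (>= 4 distinct values).
#' @param intensities Signal intensities (arbitrary units).
#' @param intensity_errors Optional per-point errors (same units).
#' @param kind One of `"inversion_recovery"`, `"decay"`, `"noe_buildup"`.
#' @return An object of class `decay_series` (a data.frame with a `kind`
#'   attribute).
#' @export
decay_series <- function(times, intensities, intensity_errors = NULL,
                         kind = c("inversion_recovery", "decay", "noe_buildup")) {
  kind <- match.arg(kind)
  if (length(times) != length(intensities))
    stop("'times' and 'intensities' differ in length")
  if (any(times < 0)) stop("'times' must be non-negative")
  if (length(unique(times)) < 4L)
    stop("at least 4 distinct time points are required")
  d <- data.frame(time_s = times, intensity = intensities)
  if (!is.null(intensity_errors)) d$intensity_err <- intensity_errors
  structure(d, kind = kind, class = c("decay_series", "data.frame"))
}

## starting values for A + B exp(-R t) via log-linear regression
init_monoexp <- function(t, y) {
  a0 <- y[which.max(t)]
  dy <- y - a0
  ok <- abs(dy) > 1e-3 * max(abs(dy))
  if (sum(ok) < 3) ok <- rep(TRUE, length(t))
  fit <- stats::lm(log(abs(dy[ok]) + 1e-12 * max(abs(dy))) ~ t[ok])
  r0 <- max(-stats::coef(fit)[2], 1e-3 / max(t))
  b0 <- sign(dy[which.min(t)]) * exp(stats::coef(fit)[1])
  c(A = a0, B = b0, R = unname(r0))
}

#' Fit a three-parameter monoexponential
#'
#' Fits `I(t) = A + B exp(-R t)` by Levenberg-Marquardt least squares.
#' For an inversion recovery the rate is R1; for a spin-echo/CPMG decay
#' it is R2. Parameter uncertainties come from the covariance of the
#' least-squares solution; replicate time points enter as independent
#' observations.
#'
#' @param series A [decay_series] (or anything with `time_s` and
#'   `intensity` columns).
#' @return An object of classes `monoexp_fit`/`nmr_fit` with elements
#'   `coefficients` (`A`, `B`, `rate`), `se`, `vcov`, `residuals`,
#'   `fitted`, `data`.
#' @examples
#' t <- exp(seq(log(1e-3), log(3), length.out = 20))
#' y <- 1 - 2 * exp(-2.23 * t)
#' fit <- fit_monoexponential(decay_series(t, y))
#' coef(fit)["rate"]   # 2.23
#' @export
fit_monoexponential <- function(series) {
  t <- series$time_s; y <- series$intensity
  if (length(unique(t)) < 4L) stop("at least 4 distinct time points required")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop("constant intensity series: decay rate is unidentifiable")
  w <- if (!is.null(series$intensity_err)) 1 / series$intensity_err^2 else NULL
  p0 <- init_monoexp(t, y)
  ## positivity of the rate via log parameterisation
  res_fn <- function(p) y - (p[1] + p[2] * exp(-exp(p[3]) * t))
  fit <- lm_least_squares(c(p0[1], p0[2], log(p0[3])), res_fn, weights = w)
  rate <- exp(fit$par[3])
  cf <- c(A = fit$par[1], B = fit$par[2], rate = rate)
  ## delta method for the rate standard error (log scale internally)
  se <- c(fit$se[1], fit$se[2], fit$se[3] * rate)
  names(se) <- names(cf)
  structure(list(
    coefficients = cf, se = se, vcov = fit$vcov,
    residuals = fit$residuals, fitted = y - fit$residuals,
    rss = fit$rss, dof = fit$dof, converged = fit$converged,
    data = data.frame(time_s = t, intensity = y),
    model = function(p, t) p["A"] + p["B"] * exp(-p["rate"] * t),
    kind = attr(series, "kind", exact = TRUE) %||% "decay"
  ), class = c("monoexp_fit", "nmr_fit"))
}

#' Fit a selective NOE build-up curve
#'
#' Fits the three-parameter build-up of the fluorine intensity under
#' continuous selective saturation of a proton,
#' \deqn{I(t) = I_0 + \frac{\sigma}{\rho}\frac{\gamma_H}{\gamma_F} I_0
#'   \left(1 - e^{-\rho t}\right),}
#' estimating the equilibrium intensity `I0`, the selective longitudinal
#' relaxation rate `rho` and the proton-fluorine cross-relaxation rate
#' `sigma`. The steady-state NOE is the fitted plateau,
#' `noe_max = (gamma_H/gamma_F) sigma / rho`.
#'
#' @param series A [decay_series] of kind `"noe_buildup"`.
#' @return Object of classes `noe_buildup_fit`/`nmr_fit`; coefficients
#'   `I0`, `rho`, `sigma`, plus `noe_max` with its delta-method standard
#'   error.
#' @export
fit_noe_buildup <- function(series) {
  if (!identical(attr(series, "kind", exact = TRUE), "noe_buildup"))
    stop("'series' must be a decay_series of kind 'noe_buildup'")
  t <- series$time_s; y <- series$intensity
  k <- nmr_constants(); gr <- k$gamma_H / k$gamma_F
  w <- if (!is.null(series$intensity_err)) 1 / series$intensity_err^2 else NULL
  ## starting values: I0 from the earliest point, plateau from the tail
  i0 <- y[which.min(t)]
  plateau <- mean(y[t >= stats::quantile(t, 0.75)])
  noe0 <- plateau / i0 - 1
  rho0 <- 1 / max(stats::median(t), 1e-3)
  res_fn <- function(p) {
    i0 <- p[1]; rho <- exp(p[2]); sig <- p[3]
    y - (i0 + sig / rho * gr * i0 * (1 - exp(-rho * t)))
  }
  fit <- lm_least_squares(c(i0, log(rho0), noe0 * rho0 / gr), res_fn,
                          weights = w)
  rho <- exp(fit$par[2]); sigma <- fit$par[3]; i0 <- fit$par[1]
  cf <- c(I0 = i0, rho = rho, sigma = sigma)
  se <- c(fit$se[1], fit$se[2] * rho, fit$se[3]); names(se) <- names(cf)
  noe_max <- gr * sigma / rho
  ## delta method on (log rho, sigma) including their covariance
  V <- fit$vcov[2:3, 2:3]
  grad <- c(-gr * sigma / rho, gr / rho)  # d/d(log rho), d/d(sigma)
  noe_se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  structure(list(
    coefficients = cf, se = se, vcov = fit$vcov,
    noe_max = noe_max, noe_max_se = noe_se,
    residuals = fit$residuals, fitted = y - fit$residuals,
    rss = fit$rss, dof = fit$dof, converged = fit$converged,
    data = data.frame(time_s = t, intensity = y),
    model = function(p, t) p["I0"] + p["sigma"] / p["rho"] * gr * p["I0"] *
      (1 - exp(-p["rho"] * t)),
    kind = "noe_buildup"
  ), class = c("noe_buildup_fit", "nmr_fit"))
}

#' Steady-state NOE from rho and sigma
#'
#' `(gamma_H / gamma_F) * sigma / rho`, the plateau of the selective NOE
#' build-up.
#'
#' @param rho Selective longitudinal relaxation rate (s-1, > 0).
#' @param sigma Cross-relaxation rate (s-1).
#' @return Fractional steady-state NOE.
#' @examples
#' noe_max_from_rates(1.76, -0.33)   # -0.199
#' @export
noe_max_from_rates <- function(rho, sigma) {
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("'rho' must be positive")
  k <- nmr_constants()
  (k$gamma_H / k$gamma_F) * sigma / rho
}

`%||%` <- function(a, b) if (is.null(a)) b else a
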