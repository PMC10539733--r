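#' Exchange parameters of the binding reaction
#'
#' Bundles the kinetic quantities entering the fast-exchange line-width
#' model: the association rate constant, the dissociation constant, the
#' bound-free frequency difference and the intrinsic transverse rates of
#' the two states. The exchange rate is always derived on the fly via
#' [kexc()], never stored.
#'
#' @param kon Association rate constant (M-1 s-1, > 0).
#' @param kd_uM Dissociation constant (uM, > 0).
#' @param delta_nu_hz Bound-minus-free frequency difference (Hz);
#'   `delta_omega = 2 pi delta_nu`.
#' @param r2_free,r2_bound Transverse relaxation rates of the free and
#'   bound peptide (s-1, > 0).
#' @return Object of class `exchange_params`.
#' @export
exchange_params <- function(kon, kd_uM, delta_nu_hz, r2_free, r2_bound) {
  if (kon <= 0 || r2_free <= 0 || r2_bound <= 0 || kd_uM <= 0)
    stop("'kon', 'kd_uM', 'r2_free' and 'r2_bound' must be positive")
  structure(list(kon = kon, kd_uM = kd_uM,
                 delta_omega = 2 * pi * delta_nu_hz,
                 r2_free = r2_free, r2_bound = r2_bound),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf(
    "Exchange: kon = %.3g /M/s, Kd = %.3g uM, dnu = %.3g Hz, R2f = %.3g, R2b = %.3g s-1\n",
    x$kon, x$kd_uM, x$delta_omega / (2 * pi), x$r2_free, x$r2_bound))
  invisible(x)
}

#' Pseudo-first-order exchange rate
#'
#' `k_exc = kon * ([SH3]_free + Kd)` with concentrations converted from
#' micromolar to molar.
#'
#' @param params An [exchange_params] object.
#' @param sh3_free_uM Free SH3 concentration (uM, >= 0).
#' @return Exchange rate in s-1.
#' @examples
#' kexc(exchange_params(1e8, 100, 265, 10, 70), 0)   # 1e4 s-1
#' @export
kexc <- function(params, sh3_free_uM) {
  if (any(sh3_free_uM < 0)) stop("'sh3_free_uM' must be non-negative")
  params$kon * (sh3_free_uM + params$kd_uM) * 1e-6
}

#' Apparent transverse relaxation rate under fast exchange
#'
#' `R2app = pf R2f + pb R2b + pf pb delta_omega^2 / k_exc`, valid when
#' `k_exc >> delta_omega`. A `fast_exchange_ok` attribute is set to
#' `FALSE` when `k_exc < 5 |delta_omega|`, flagging that the closed form
#' is being stretched.
#'
#' @param params An [exchange_params] object.
#' @param conc A `species_conc` object (supplies `pb`, `pf` of the
#'   peptide and the free SH3 concentration).
#' @return Apparent R2 in s-1, with attribute `fast_exchange_ok`.
#' @export
r2_apparent <- function(params, conc) {
  pb <- conc$pb; pf <- conc$pf
  if (isTRUE(conc$pb_undefined)) stop("bound fraction undefined: no peptide")
  ke <- kexc(params, conc$free_sh3)
  if (ke == 0 && pb * pf > 0)
    stop("zero exchange rate with both states populated")
  exch <- if (pb * pf > 0) pf * pb * params$delta_omega^2 / ke else 0
  out <- pf * params$r2_free + pb * params$r2_bound + exch
  attr(out, "fast_exchange_ok") <- ke >= 5 * abs(params$delta_omega)
  out
}

#' Fit Lorentzian peaks to a 1D spectrum
#'
#' Least-squares fit of a sum of Lorentzians plus a constant baseline.
#' Each peak's apparent transverse rate is `R2app = pi * FWHM`. When two
#' fitted centres fall within a quarter of the broader FWHM of one
#' another a resolvability warning is emitted.
#'
#' @param freq_hz,intensity Spectrum axis and intensities.
#' @param n_peaks Number of Lorentzians to fit.
#' @param init Optional data.frame/list of starting values with elements
#'   `centre_hz`, `fwhm_hz`, `amplitude`; guessed from the spectrum when
#'   omitted.
#' @return Object of classes `peak_fit`/`nmr_fit`; element `peaks` is a
#'   data.frame `centre_hz, fwhm_hz, amplitude, r2app_s1` plus standard
#'   errors, `baseline` the fitted offset.
#' @examples
#' f <- seq(-60, 60, by = 0.25)
#' y <- 2 / (1 + (f / (6.366 / 2))^2)       # R2app = 20 /s
#' fit_lorentzian_peaks(f, y, 1)$peaks$r2app_s1
#' @export
fit_lorentzian_peaks <- function(freq_hz, intensity, n_peaks = 1, init = NULL) {
  if (n_peaks < 1) stop("'n_peaks' must be >= 1")
  n <- length(freq_hz)
  if (n != length(intensity)) stop("axis/intensity length mismatch")
  if (is.null(init)) {
    ## greedy peak picking on a lightly smoothed copy
    ys <- stats::filter(intensity, rep(1 / 5, 5), sides = 2)
    ys[is.na(ys)] <- intensity[is.na(ys)]
    base0 <- stats::median(intensity)
    cand <- order(ys, decreasing = TRUE)
    centres <- numeric(0)
    span <- diff(range(freq_hz))
    for (i in cand) {
      if (length(centres) == n_peaks) break
      if (all(abs(freq_hz[i] - centres) > span / (4 * n_peaks)))
        centres <- c(centres, freq_hz[i])
    }
    init <- data.frame(centre_hz = centres,
                       fwhm_hz = rep(span / 20, n_peaks),
                       amplitude = ys[match(centres, freq_hz)] - base0)
  }
  ## parameters: baseline | per peak (centre, log fwhm, amplitude)
  p0 <- c(stats::median(intensity),
          as.vector(rbind(init$centre_hz, log(init$fwhm_hz), init$amplitude)))
  model <- function(p) {
    y <- rep(p[1], n)
    for (k in seq_len(n_peaks)) {
      c0 <- p[3 * k - 1]; hw <- exp(p[3 * k]) / 2; a <- p[3 * k + 1]
      y <- y + a / (1 + ((freq_hz - c0) / hw)^2)
    }
    y
  }
  fit <- lm_least_squares(p0, function(p) intensity - model(p))
  idx <- seq_len(n_peaks)
  centre <- fit$par[3 * idx - 1]
  fwhm <- exp(fit$par[3 * idx])
  amp <- fit$par[3 * idx + 1]
  centre_se <- fit$se[3 * idx - 1]
  fwhm_se <- fit$se[3 * idx] * fwhm
  amp_se <- fit$se[3 * idx + 1]
  if (n_peaks > 1) {
    d <- abs(outer(centre, centre, "-"))
    lim <- outer(fwhm, fwhm, pmax) / 4
    if (any(d[upper.tri(d)] < lim[upper.tri(lim)]))
      warning("fitted peaks overlap (centre separation < FWHM/4); estimates strongly covariant")
  }
  ord <- order(centre)
  peaks <- data.frame(
    centre_hz = centre, fwhm_hz = fwhm, amplitude = amp,
    r2app_s1 = pi * fwhm,
    centre_se = centre_se, fwhm_se = fwhm_se, amplitude_se = amp_se,
    amplitude_consistent_with_zero = abs(amp) < 2 * amp_se
  )[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(
    coefficients = c(baseline = fit$par[1]), se = c(baseline = fit$se[1]),
    peaks = peaks, baseline = fit$par[1], vcov = fit$vcov,
    residuals = fit$residuals, fitted = intensity - fit$residuals,
    rss = fit$rss, dof = fit$dof, converged = fit$converged,
    data = data.frame(freq_hz = freq_hz, intensity = intensity),
    model = NULL
  ), class = c("peak_fit", "nmr_fit"))
}

#' @export
print.peak_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Lorentzian fit: %d peak(s), baseline %.4g\n",
              nrow(x$peaks), x$baseline))
  print(format(x$peaks[, c("centre_hz", "fwhm_hz", "amplitude", "r2app_s1")],
               digits = digits))
  invisible(x)
}

#' Fit the association rate from an exchange-broadening profile
#'
#' Weighted least-squares fit of `kon`, `R2f` and `R2b` to apparent
#' transverse rates measured across a titration, with the bound/free
#' fractions, free SH3 concentrations, Kd and the bound-free frequency
#' difference fixed from the chemical-shift-perturbation fit. `kon` is
#' fitted on the log scale with a multi-start over a 1e6-1e10 M-1 s-1
#' grid. When the exchange term contributes less than 10 % of every
#' R2app value the fit is flagged as kon-unidentifiable.
#'
#' @param r2app_s1 Apparent transverse rates (s-1), one per titration
#'   point.
#' @param conc A list of `species_conc` objects (same length), e.g. from
#'   [solve_equilibrium()] at the fitted Kd.
#' @param delta_nu_hz Bound-minus-free frequency difference (Hz, fixed).
#' @param kd_uM Dissociation constant (uM, fixed).
#' @param r2app_err Optional per-point errors for weighting.
#' @return Object of classes `kon_fit`/`nmr_fit` with coefficients
#'   `kon`, `r2_free`, `r2_bound` and a logical `kon_identifiable`.
#' @export
fit_kon <- function(r2app_s1, conc, delta_nu_hz, kd_uM, r2app_err = NULL) {
  npts <- length(r2app_s1)
  if (npts < 4L) stop("at least 4 titration points are required")
  if (length(conc) != npts) stop("'conc' must match 'r2app_s1' in length")
  if (delta_nu_hz == 0)
    stop("delta_nu is zero: the exchange term vanishes and kon is unidentifiable")
  pb <- vapply(conc, `[[`, numeric(1), "pb")
  pf <- 1 - pb
  lfree <- vapply(conc, `[[`, numeric(1), "free_sh3")
  dw2 <- (2 * pi * delta_nu_hz)^2
  w <- if (is.null(r2app_err)) NULL else 1 / r2app_err^2

  res_fn <- function(p) {
    kon <- exp(p[1]); r2f <- exp(p[2]); r2b <- exp(p[3])
    ke <- kon * (lfree + kd_uM) * 1e-6
    r2app_s1 - (pf * r2f + pb * r2b + pf * pb * dw2 / ke)
  }
  best <- NULL
  for (lk in log(10^seq(6, 10, by = 0.5))) {
    f <- tryCatch(
      suppressWarnings(
        lm_least_squares(c(lk, log(max(min(r2app_s1), 1)),
                           log(max(max(r2app_s1), 2))), res_fn, weights = w)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$rss < best$rss) best <- f
  }
  if (is.null(best)) stop("kon fit failed from every starting value")
  kon <- exp(best$par[1]); r2f <- exp(best$par[2]); r2b <- exp(best$par[3])
  cf <- c(kon = kon, r2_free = r2f, r2_bound = r2b)
  se <- best$se * cf
  names(se) <- names(cf)
  ke <- kon * (lfree + kd_uM) * 1e-6
  exch <- pf * pb * dw2 / ke
  identifiable <- any(exch > 0.1 * r2app_s1)
  if (!identifiable)
    warning("exchange term below 10 % of R2app at every point; kon weakly identified")
  structure(list(
    coefficients = cf, se = se, vcov = best$vcov,
    residuals = best$residuals, fitted = r2app_s1 - best$residuals,
    rss = best$rss, dof = best$dof, converged = best$converged,
    kon_identifiable = identifiable,
    data = data.frame(r2app_s1 = r2app_s1, pb = pb, sh3_free_uM = lfree,
                      exchange_term = exch),
    model = NULL
  ), class = c("kon_fit", "nmr_fit"))
}
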