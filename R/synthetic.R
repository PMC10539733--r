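#' Configuration of the synthetic-data generators
#'
#' Collects the noise model and the titration protocol used by all
#' generators. The defaults restate the experimental conditions: 1.6 Hz
#' standard deviation on 19F shifts (the back-calculation residual of the
#' titration fits), 0.005 ppm on the composite amide CSP, 5 % relative
#' noise on line widths, a 15 % relative uncertainty on stock
#' concentrations (applied once per stock, i.e. as a systematic bias per
#' titration, because all aliquots of a titration come from the same
#' stock), and the 8 Hz exponential broadening applied before Fourier
#' transform.
#'
#' @param seed Integer seed; every generator call is reproducible under a
#'   fixed config.
#' @param noise_shift_19f Gaussian noise on 19F shifts (Hz).
#' @param noise_csp_amide Gaussian noise on the composite CSP (ppm).
#' @param noise_linewidth_rel Relative Gaussian noise on line widths.
#' @param conc_uncertainty_rel Relative uncertainty of each stock
#'   concentration (one multiplicative draw per stock).
#' @param exponential_broadening Line broadening added in processing (Hz).
#' @param schedule Titration schedule data.frame (`peptide_total_uM`,
#'   `sh3_total_uM`); defaults to [titration_schedule()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             noise_shift_19f = 1.6,
                             noise_csp_amide = 0.005,
                             noise_linewidth_rel = 0.05,
                             conc_uncertainty_rel = 0.15,
                             exponential_broadening = 8,
                             schedule = titration_schedule()) {
  if (any(c(noise_shift_19f, noise_csp_amide, noise_linewidth_rel,
            conc_uncertainty_rel, exponential_broadening) < 0))
    stop("noise parameters must be non-negative")
  structure(list(seed = as.integer(seed),
                 noise_shift_19f = noise_shift_19f,
                 noise_csp_amide = noise_csp_amide,
                 noise_linewidth_rel = noise_linewidth_rel,
                 conc_uncertainty_rel = conc_uncertainty_rel,
                 exponential_broadening = exponential_broadening,
                 schedule = schedule),
            class = "generator_config")
}

#' Default titration schedule
#'
#' Reconstructs the titration protocol: an SH3 sample starting at 314 uM
#' in a 3 mm tube (170 uL), titrated by aliquots of a millimolar peptide
#' stock, first point at 50 uM peptide and final points near 2 mM. The
#' exact aliquot list was not tabulated, so nominal peptide targets are
#' chosen on a roughly geometric ladder and the aliquot volumes (hence
#' the progressive dilution of the protein) are solved from the stock
#' concentration.
#'
#' @param peptide_targets_uM Nominal total peptide concentrations; the
#'   default starts at 0 (protein-only reference point).
#' @param sh3_start_uM Initial protein concentration (uM).
#' @param stock_uM Peptide stock concentration (uM); 5100 for MpSR,
#'   5700 for MpRS.
#' @param volume_uL Initial sample volume.
#' @return Data.frame with `peptide_total_uM` and `sh3_total_uM` per
#'   point, dilution accounted for.
#' @examples
#' titration_schedule()
#' @export
titration_schedule <- function(peptide_targets_uM = c(0, 50, 100, 150, 225,
                                                      320, 450, 630, 880,
                                                      1200, 1600, 2000),
                               sh3_start_uM = 314, stock_uM = 5100,
                               volume_uL = 170) {
  p <- peptide_targets_uM
  if (any(p >= stock_uM)) stop("peptide target exceeds stock concentration")
  v_add <- p * volume_uL / (stock_uM - p)
  data.frame(peptide_total_uM = p,
             sh3_total_uM = sh3_start_uM * volume_uL / (volume_uL + v_add))
}

#' Generate a synthetic CSP titration
#'
#' Simulates the joint 19F + amide chemical-shift-perturbation titration:
#' per point the binding equilibrium is solved at the *true*
#' concentrations (nominal schedule times one multiplicative bias drawn
#' per stock), fast-exchange shift perturbations and, when kinetics are
#' supplied, apparent transverse rates from the exchange line-width model
#' are emitted, then Gaussian noise is added per the config. The data
#' frame carries the nominal concentrations (what the experimenter would
#' believe); the ground truth including the bias draws is returned
#' alongside.
#'
#' @param truth List with `model` (a [binding_model]), `dnu_hz` (named
#'   vector of bound-minus-free 19F shifts per signal; may be empty for
#'   an amide-only titration), optional `csp_max_ppm` (saturating
#'   composite amide CSP; omit/NA for a 19F-only titration) and optional
#'   `kinetics` (an [exchange_params]; its `delta_omega` is ignored,
#'   each signal uses its own `dnu_hz`).
#' @param config A [generator_config].
#' @return List of class `titration_sim`: `data` (long data.frame with
#'   columns `point_id, peptide_total_uM, sh3_total_uM, signal,
#'   observable, value` and `linewidth_hz` where applicable) and `truth`
#'   (input truth plus the realised stock bias factors and the per-point
#'   true concentrations and bound fractions).
#' @export
generate_titration <- function(truth, config = generator_config()) {
  stopifnot(inherits(truth$model, "binding_model"))
  set.seed(config$seed)
  sched <- config$schedule
  bias_pep <- max(1 + stats::rnorm(1, 0, config$conc_uncertainty_rel), 0.2)
  bias_sh3 <- max(1 + stats::rnorm(1, 0, config$conc_uncertainty_rel), 0.2)
  p_true <- sched$peptide_total_uM * bias_pep
  l_true <- sched$sh3_total_uM * bias_sh3
  npt <- nrow(sched)
  species <- lapply(seq_len(npt), function(i)
    solve_equilibrium(truth$model, p_true[i], l_true[i]))

  rows <- list()
  dnu <- truth$dnu_hz
  has_kin <- !is.null(truth$kinetics)
  for (i in seq_len(npt)) {
    sp <- species[[i]]
    if (length(dnu) && sched$peptide_total_uM[i] > 0) {
      p1 <- sp$complex_pl / sp$peptide_total
      p2 <- sp$complex_pl2 / sp$peptide_total
      for (s in names(dnu)) {
        val <- (p1 + p2) * dnu[[s]] +
          stats::rnorm(1, 0, config$noise_shift_19f)
        lw <- NA_real_
        if (has_kin) {
          kin <- truth$kinetics
          pars <- exchange_params(kin$kon, truth$model$kd[1], dnu[[s]],
                                  kin$r2_free, kin$r2_bound)
          r2 <- as.numeric(r2_apparent(pars, sp))
          lw <- r2 / pi + config$exponential_broadening
          lw <- lw * (1 + stats::rnorm(1, 0, config$noise_linewidth_rel))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          point_id = i, peptide_total_uM = sched$peptide_total_uM[i],
          sh3_total_uM = sched$sh3_total_uM[i], signal = s,
          observable = "shift_hz", value = val, linewidth_hz = lw)
      }
    }
    if (!is.null(truth$csp_max_ppm) && is.finite(truth$csp_max_ppm)) {
      fb <- if (sp$sh3_total > 0)
        (sp$complex_pl + 2 * sp$complex_pl2) / sp$sh3_total else 0
      val <- fb * truth$csp_max_ppm + stats::rnorm(1, 0, config$noise_csp_amide)
      rows[[length(rows) + 1L]] <- data.frame(
        point_id = i, peptide_total_uM = sched$peptide_total_uM[i],
        sh3_total_uM = sched$sh3_total_uM[i], signal = "amide",
        observable = "csp_ppm", value = val, linewidth_hz = NA_real_)
    }
  }
  data <- do.call(rbind, rows)
  truth$bias <- c(peptide = bias_pep, sh3 = bias_sh3)
  truth$true_concentrations <- data.frame(
    point_id = seq_len(npt), peptide_true_uM = p_true, sh3_true_uM = l_true,
    pb = vapply(species, `[[`, numeric(1), "pb"))
  structure(list(data = data, truth = truth, config = config),
            class = "titration_sim")
}

#' @export
print.titration_sim <- function(x, ...) {
  cat(sprintf("Synthetic titration: %d observations over %d points (%s, Kd %s uM)\n",
              nrow(x$data), length(unique(x$data$point_id)),
              x$truth$model$stoichiometry,
              paste(signif(x$truth$model$kd, 4), collapse = "/")))
  cat(sprintf("  stock bias: peptide %.3f, SH3 %.3f\n",
              x$truth$bias["peptide"], x$truth$bias["sh3"]))
  invisible(x)
}

#' Generate a synthetic 1D spectrum
#'
#' Sum of Lorentzians on a frequency grid with additive Gaussian noise.
#' Peak widths are `FWHM = R2app/pi` plus the exponential broadening of
#' the config, mimicking the processing applied to the real spectra.
#'
#' @param peaks Data.frame with columns `centre_hz`, `r2app_s1`,
#'   `amplitude`.
#' @param freq_hz Frequency axis (Hz).
#' @param config A [generator_config].
#' @param noise_sd Absolute Gaussian noise on the intensities.
#' @return Data.frame `freq_hz, intensity`.
#' @export
generate_spectrum <- function(peaks, freq_hz, config = generator_config(),
                              noise_sd = 0) {
  set.seed(config$seed)
  y <- numeric(length(freq_hz))
  for (k in seq_len(nrow(peaks))) {
    fw <- peaks$r2app_s1[k] / pi + config$exponential_broadening
    y <- y + peaks$amplitude[k] /
      (1 + ((freq_hz - peaks$centre_hz[k]) / (fw / 2))^2)
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(freq_hz = freq_hz, intensity = y)
}

## acquisition schedules: log-spaced with one repeated point for error
## estimation, as in the experiments
schedule_with_repeat <- function(tmin, tmax, n_total) {
  t <- exp(seq(log(tmin), log(tmax), length.out = n_total - 1))
  sort(c(t, t[ceiling((n_total - 1) / 2)]))
}

#' Generate a synthetic relaxation decay or recovery
#'
#' Exact three-parameter monoexponential values plus Gaussian noise on
#' the inversion-recovery schedule (20 points, 1 ms to 3 s, log-spaced,
#' one delay repeated).
#'
#' @param rate Relaxation rate (s-1).
#' @param amplitude,offset Model `I(t) = offset + amplitude exp(-rate t)`
#'   (an inversion recovery has `amplitude` about `-2 offset`).
#' @param times Optional schedule; defaults to the 20-point recovery
#'   schedule.
#' @param noise_sd Absolute Gaussian noise.
#' @param config A [generator_config] (supplies the seed).
#' @param kind Stored series kind.
#' @return A [decay_series].
#' @export
generate_decay <- function(rate, amplitude = -2, offset = 1, times = NULL,
                           noise_sd = 0, config = generator_config(),
                           kind = c("inversion_recovery", "decay")) {
  kind <- match.arg(kind)
  set.seed(config$seed)
  if (is.null(times)) times <- schedule_with_repeat(1e-3, 3, 20)
  y <- offset + amplitude * exp(-rate * times)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  decay_series(times, y, kind = kind)
}

#' Generate a synthetic NOE build-up
#'
#' Exact build-up `I(t) = I0 + (sigma/rho)(gamma_H/gamma_F) I0
#' (1 - exp(-rho t))` plus Gaussian noise, on the 16-point saturation
#' schedule (10 ms to 2.6 s, one repeat).
#'
#' @param i0 Equilibrium intensity.
#' @param rho Selective longitudinal rate (s-1).
#' @param sigma Cross-relaxation rate (s-1).
#' @param times Optional schedule; defaults to the 16-point build-up
#'   schedule.
#' @param noise_sd Absolute Gaussian noise.
#' @param config A [generator_config].
#' @return A [decay_series] of kind `"noe_buildup"`.
#' @export
generate_noe_buildup <- function(i0 = 1, rho, sigma, times = NULL,
                                 noise_sd = 0, config = generator_config()) {
  set.seed(config$seed)
  if (is.null(times)) times <- schedule_with_repeat(1e-2, 2.6, 16)
  k <- nmr_constants()
  y <- i0 + sigma / rho * (k$gamma_H / k$gamma_F) * i0 * (1 - exp(-rho * times))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  decay_series(times, y, kind = "noe_buildup")
}
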