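#' Fit a binding model to chemical-shift-perturbation titrations
#'
#' Joint weighted least-squares fit of the dissociation constant(s) and
#' the per-signal bound-state shift differences to a titration. The
#' observables are, per titration point,
#' \itemize{
#'   \item 19F shift perturbations of peptide signals (Hz relative to the
#'     free peptide): predicted as `pb * dnu` with `pb` the peptide bound
#'     fraction from the equilibrium solver;
#'   \item the composite amide CSP of the protein (ppm, averaged over the
#'     responsive residues): predicted as `fb * csp_max` with `fb` the
#'     protein bound fraction.
#' }
#' The two blocks are combined in a single objective with weights
#' `1/noise^2` (defaults: 1.6 Hz for 19F, 0.005 ppm for the composite
#' CSP). Kd values are fitted on the log scale; uncertainties come from
#' the least-squares covariance. For the 1:2 model each 19F signal gets
#' separate shift differences for the singly and doubly bound states and
#' the protein CSP treats both bound protein molecules alike.
#'
#' @param data A data.frame with columns `peptide_total_uM`,
#'   `sh3_total_uM`, `signal`, `observable` (`"shift_hz"` for 19F,
#'   `"csp_ppm"` for the amide composite) and `value`. See
#'   [read_titration_csv()] for the CSV dialect.
#' @param model A [binding_model] giving the stoichiometry and starting
#'   Kd value(s).
#' @param noise_hz,noise_ppm Measurement noise used for the block
#'   weights.
#' @param start_dnu,start_csp_max Optional starting values.
#' @return Object of classes `csp_fit`/`nmr_fit`: `coefficients`
#'   (`kd_uM`(+`kd2_uM`), one `dnu_<signal>` per 19F signal, `csp_max`
#'   when amide data are present), `se`, `vcov`, `reduced_chi2`
#'   (weighted, per the number of fitted parameters), `residuals`,
#'   `data`, `model`.
#' @examples
#' sim <- generate_titration(
#'   truth = list(model = binding_model("1:1", 96),
#'                dnu_hz = c(F4 = 265, F8 = 218), csp_max_ppm = 0.1),
#'   config = generator_config(seed = 1, noise_shift_19f = 0,
#'                             noise_csp_amide = 0, conc_uncertainty_rel = 0))
#' fit <- fit_titration(sim$data, binding_model("1:1", 150))
#' coef(fit)["kd_uM"]   # recovers 96
#' @export
fit_titration <- function(data, model, noise_hz = 1.6, noise_ppm = 0.005,
                          start_dnu = NULL, start_csp_max = NULL) {
  stopifnot(inherits(model, "binding_model"))
  need <- c("peptide_total_uM", "sh3_total_uM", "signal", "observable", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("titration data lack column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(data) < 4L) stop("at least 4 titration observations are required")
  is_f <- data$observable == "shift_hz"
  is_a <- data$observable == "csp_ppm"
  if (!all(is_f | is_a))
    stop("'observable' must be 'shift_hz' or 'csp_ppm'")
  fsig <- unique(data$signal[is_f])
  two_step <- model$stoichiometry == "1:2"

  ## unique concentration points, solved once per objective evaluation
  pts <- unique(data[, c("peptide_total_uM", "sh3_total_uM")])
  ipt <- match(paste(data$peptide_total_uM, data$sh3_total_uM),
               paste(pts$peptide_total_uM, pts$sh3_total_uM))

  ## parameter layout: log kd (1 or 2) | dnu per F signal (x2 for 1:2) | csp_max
  nkd <- if (two_step) 2L else 1L
  ndnu <- length(fsig) * (if (two_step) 2L else 1L)
  has_amide <- any(is_a)
  start <- c(log(model$kd),
             rep(if (is.null(start_dnu)) 100 else start_dnu,
                 length.out = ndnu),
             if (has_amide) (start_csp_max %||% 0.1))

  predict_all <- function(p) {
    ## clamp against under/overflow of the log parameterisation
    kd <- pmin(pmax(exp(p[seq_len(nkd)]), 1e-9), 1e12)
    m <- if (two_step) binding_model("1:2", kd) else binding_model("1:1", kd)
    pred <- numeric(nrow(data))
    for (j in seq_len(nrow(pts))) {
      sel <- ipt == j
      if (!any(sel)) next
      sp <- solve_equilibrium(m, pts$peptide_total_uM[j], pts$sh3_total_uM[j])
      p1 <- if (sp$peptide_total > 0) sp$complex_pl / sp$peptide_total else 0
      p2 <- if (sp$peptide_total > 0) sp$complex_pl2 / sp$peptide_total else 0
      fb <- if (sp$sh3_total > 0)
        (sp$complex_pl + 2 * sp$complex_pl2) / sp$sh3_total else 0
      for (i in which(sel)) {
        if (is_f[i]) {
          k <- match(data$signal[i], fsig)
          if (two_step) {
            d1 <- p[nkd + 2 * k - 1]; d2 <- p[nkd + 2 * k]
            pred[i] <- p1 * d1 + p2 * d2
          } else pred[i] <- (p1 + p2) * p[nkd + k]
        } else {
          pred[i] <- fb * p[nkd + ndnu + 1]
        }
      }
    }
    pred
  }

  w <- ifelse(is_f, 1 / noise_hz^2, 1 / noise_ppm^2)
  fit <- lm_least_squares(start, function(p) data$value - predict_all(p),
                          weights = w)
  kd <- pmin(pmax(exp(fit$par[seq_len(nkd)]), 1e-9), 1e12)
  kd_se <- fit$se[seq_len(nkd)] * kd
  dnu <- fit$par[nkd + seq_len(ndnu)]
  dnu_se <- fit$se[nkd + seq_len(ndnu)]
  dnu_names <- if (two_step)
    as.vector(rbind(paste0("dnu_", fsig), paste0("dnu2_", fsig)))
  else if (length(fsig)) paste0("dnu_", fsig) else character(0)
  cf <- c(kd, dnu, if (has_amide) fit$par[nkd + ndnu + 1])
  se <- c(kd_se, dnu_se, if (has_amide) fit$se[nkd + ndnu + 1])
  names(cf) <- names(se) <- c(
    if (two_step) c("kd_uM", "kd2_uM") else "kd_uM",
    dnu_names, if (has_amide) "csp_max")

  ## saturation-range identifiability warning (1:1 bound fraction span)
  kd_chk <- kd[1]
  pbs <- vapply(seq_len(nrow(pts)), function(j) {
    s <- solve_equilibrium_1to1(pts$peptide_total_uM[j], pts$sh3_total_uM[j],
                                kd_chk)
    if (isTRUE(s$pb_undefined)) NA_real_ else s$pb
  }, numeric(1))
  pbs <- pbs[is.finite(pbs)]
  if (length(pbs) && (max(pbs) < 0.1 || min(pbs) > 0.9))
    warning("titration saturation range poorly spans the binding curve; Kd weakly identified")

  np <- length(fit$par)
  rchi2 <- sum(fit$weights * fit$residuals^2) / (length(fit$residuals) - np)
  structure(list(
    coefficients = cf, se = se, vcov = fit$vcov,
    residuals = fit$residuals, fitted = data$value - fit$residuals,
    reduced_chi2 = rchi2, rss = fit$rss, dof = fit$dof,
    converged = fit$converged,
    data = data, binding_model = model$stoichiometry,
    signals = fsig, noise = c(hz = noise_hz, ppm = noise_ppm),
    model = NULL
  ), class = c("csp_fit", "nmr_fit"))
}

#' @export
predict.csp_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  cf <- object$coefficients
  two_step <- object$binding_model == "1:2"
  m <- if (two_step) binding_model("1:2", c(cf[["kd_uM"]], cf[["kd2_uM"]]))
       else binding_model("1:1", cf[["kd_uM"]])
  vapply(seq_len(nrow(d)), function(i) {
    sp <- solve_equilibrium(m, d$peptide_total_uM[i], d$sh3_total_uM[i])
    p1 <- if (sp$peptide_total > 0) sp$complex_pl / sp$peptide_total else 0
    p2 <- if (sp$peptide_total > 0) sp$complex_pl2 / sp$peptide_total else 0
    if (d$observable[i] == "shift_hz") {
      s <- d$signal[i]
      if (two_step) p1 * cf[[paste0("dnu_", s)]] + p2 * cf[[paste0("dnu2_", s)]]
      else (p1 + p2) * cf[[paste0("dnu_", s)]]
    } else {
      fb <- if (sp$sh3_total > 0)
        (sp$complex_pl + 2 * sp$complex_pl2) / sp$sh3_total else 0
      fb * cf[["csp_max"]]
    }
  }, numeric(1))
}
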