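#' Cis/trans indicator from the Cbeta-Cgamma shift difference
#'
#' The 13C shift difference `delta = Cbeta - Cgamma` diagnoses the
#' Xaa-Pro peptide-bond isomer: values below 5 ppm indicate trans, values
#' of about 9-10 ppm indicate cis. A conservative cis bound of 8 ppm is
#' used with an explicit "ambiguous" zone in between, so borderline
#' residues are visible rather than silently classified. A fluorinated
#' Cgamma (shift near 95 ppm) makes the indicator meaningless and is
#' returned as `not_applicable`.
#'
#' @param cb,cg 13C beta and gamma shifts (ppm); vectorised.
#' @return A data.frame with columns `delta_ppm` and `call` (factor with
#'   levels trans/ambiguous/cis/not_applicable).
#' @examples
#' cis_trans_indicator(30.86, 26.51)   # MpRS Pro1: 4.35 ppm, trans
#' @export
cis_trans_indicator <- function(cb, cg) {
  delta <- cb - cg
  call <- ifelse(cg > 80, "not_applicable",
          ifelse(delta <= 5, "trans",
          ifelse(delta >= 8, "cis", "ambiguous")))
  data.frame(delta_ppm = delta,
             call = factor(call, levels = c("trans", "ambiguous", "cis",
                                            "not_applicable")))
}

#' Diastereotopic Hdelta shift difference
#'
#' Signed difference `Hdelta2 - Hdelta3` between the two delta protons of
#' a proline, an empirical reporter of local backbone dynamics. The
#' assignment order follows the shift tables (first listed value taken as
#' Hdelta2); the tables carry no stereo-assignment, so only comparisons
#' of magnitudes between residues are meaningful.
#'
#' @param hd2,hd3 Proton shifts (ppm); vectorised.
#' @return Difference in ppm.
#' @export
hd_diastereotopic_difference <- function(hd2, hd3) hd2 - hd3

#' Classify fluoroproline ring pucker from scalar couplings
#'
#' Matches a measured set of 3J couplings (F-Hbeta, F-Hdelta and
#' Halpha-Hbeta) against reference sets (typically the free
#' (4R)/(4S)-fluoroproline literature values) by root-mean-square
#' difference over the couplings present in both. The stereochemistry of
#' the nearest reference implies the pucker: (4R)-FPro locks Cgamma-exo,
#' (4S)-FPro locks Cgamma-endo. Residuals above `flag_hz` are reported
#' as dominant deviations.
#'
#' @param measured Named numeric vector of couplings in Hz, names among
#'   `c("jfb2","jfb3","jfd2","jfd3","jab2","jab3")`.
#' @param references A named list of such vectors, one per reference.
#' @param flag_hz Residual magnitude (Hz) above which a coupling is
#'   flagged.
#' @return A list with `best` (reference label(s); more than one on a
#'   tie), `pucker` (`"Cgamma-exo"` or `"Cgamma-endo"` when the label
#'   identifies the stereochemistry), `rms` (named, all references),
#'   `residuals` (measured - best reference, shared couplings) and
#'   `flagged` (names of couplings deviating by more than `flag_hz`).
#' @export
classify_pucker <- function(measured, references, flag_hz = 4) {
  valid <- c("jfb2", "jfb3", "jfd2", "jfd3", "jab2", "jab3")
  measured <- measured[names(measured) %in% valid & !is.na(measured)]
  rms <- vapply(references, function(ref) {
    shared <- intersect(names(measured), names(ref)[!is.na(ref)])
    if (length(shared) < 2) return(NA_real_)
    sqrt(mean((measured[shared] - ref[shared])^2))
  }, numeric(1))
  if (all(is.na(rms)))
    stop("no reference shares at least two couplings with the measurement")
  best <- names(rms)[which(rms <= min(rms, na.rm = TRUE) + 1e-12)]
  ref <- references[[best[1]]]
  shared <- intersect(names(measured), names(ref)[!is.na(ref)])
  resid <- measured[shared] - ref[shared]
  pucker <- if (grepl("4R", best[1], fixed = TRUE)) "Cgamma-exo"
            else if (grepl("4S", best[1], fixed = TRUE)) "Cgamma-endo"
            else NA_character_
  list(best = best, pucker = pucker, rms = rms, residuals = resid,
       flagged = names(resid)[abs(resid) > flag_hz])
}
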