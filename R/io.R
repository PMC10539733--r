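## CSV readers/writers for the dialects the package consumes, plus JSON
## result files. Every reader validates its mandatory columns and
## reports malformed (non-numeric) rows with their line numbers.

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

check_numeric_rows <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop(sprintf("%s: non-numeric value in column '%s' at data row(s) %s",
                     what, cl, paste(bad, collapse = ", ")))
      df[[cl]] <- num
    }
  }
  df
}

#' Read a spin-system geometry table
#'
#' Columns: `label, r_HG, r_HB2, r_HB3, r_HD2, r_HD3, delta_sigma_ppm,
#' eta, anti_xy_ppm, anti_xz_ppm, anti_yz_ppm` (one row per conformer).
#' The packaged `fpro_geometry.csv` fixture carries the four DFT-derived
#' fluoroproline conformers; see [fpro_geometries()].
#'
#' @param path CSV file path.
#' @return Named list of [spin_geometry] objects.
#' @export
read_geometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("label", "r_HG", "r_HB2", "r_HB3", "r_HD2", "r_HD3",
           "delta_sigma_ppm", "eta")
  check_columns(df, req, basename(path))
  df <- check_numeric_rows(df, setdiff(names(df), "label"), basename(path))
  out <- lapply(seq_len(nrow(df)), function(i) {
    spin_geometry(
      label = df$label[i],
      proton_distances = c(HG = df$r_HG[i], HB2 = df$r_HB2[i],
                           HB3 = df$r_HB3[i], HD2 = df$r_HD2[i],
                           HD3 = df$r_HD3[i]),
      delta_sigma = df$delta_sigma_ppm[i], eta_csa = df$eta[i],
      anti_xy = df$anti_xy_ppm[i] %||% 0,
      anti_xz = df$anti_xz_ppm[i] %||% 0,
      anti_yz = df$anti_yz_ppm[i] %||% 0)
  })
  names(out) <- df$label
  out
}

#' Read a chemical-shift assignment table
#'
#' Mirrors the assignment table layout: one row per residue with 13C and
#' Hdelta shifts plus the printed indicator columns. The packaged
#' `peptide_shifts.csv` fixture transcribes the assignments of the two
#' model peptides.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data.frame with at least `peptide, residue, position, cb_ppm,
#'   cg_ppm, hd2_ppm, hd3_ppm, dd_printed_ppm`.
#' @export
read_shift_table_csv <- function(path = system.file("extdata",
                                                    "peptide_shifts.csv",
                                                    package = "fpronmr")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("peptide", "residue", "position", "cb_ppm", "cg_ppm"),
                basename(path))
  check_numeric_rows(df, setdiff(names(df), c("peptide", "residue")),
                     basename(path))
}

#' Read a scalar-coupling table
#'
#' One row per source (peptide residue or free amino acid) with the six
#' diagnostic couplings `jfb2, jfb3, jfd2, jfd3, jab2, jab3` in Hz. The
#' packaged `fpro_couplings.csv` fixture transcribes the measured peptide
#' values alongside the free-fluoroproline literature references.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data.frame with a `source` column and the coupling columns.
#' @export
read_coupling_csv <- function(path = system.file("extdata",
                                                 "fpro_couplings.csv",
                                                 package = "fpronmr")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("source", "jfb2", "jfb3", "jfd2", "jfd3",
                      "jab2", "jab3"), basename(path))
  df <- check_numeric_rows(df, setdiff(names(df), "source"), basename(path))
  if (any(stats::na.omit(unlist(df[, -1])) < 0) ||
      any(stats::na.omit(unlist(df[, -1])) >= 60))
    stop("couplings must lie in [0, 60) Hz")
  df
}

#' Coupling table as a list of named vectors
#'
#' Convenience accessor turning [read_coupling_csv()] rows into the
#' format [classify_pucker()] consumes.
#'
#' @inheritParams read_coupling_csv
#' @return Named list of coupling vectors keyed by `source`.
#' @export
coupling_sets <- function(path = system.file("extdata", "fpro_couplings.csv",
                                             package = "fpronmr")) {
  df <- read_coupling_csv(path)
  cols <- c("jfb2", "jfb3", "jfd2", "jfd3", "jab2", "jab3")
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, cols]); names(v) <- cols; v
  })
  names(out) <- df$source
  out
}

#' Read a relaxation time-series CSV
#'
#' Columns `time_s, intensity` and optionally `intensity_err`.
#'
#' @param path CSV path.
#' @param kind Series kind, see [decay_series()].
#' @return A [decay_series].
#' @export
read_series_csv <- function(path, kind = c("inversion_recovery", "decay",
                                           "noe_buildup")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_s", "intensity"), basename(path))
  df <- check_numeric_rows(df, names(df), basename(path))
  decay_series(df$time_s, df$intensity, df$intensity_err, kind = kind)
}

#' Write a relaxation time series
#' @param series A [decay_series].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a titration CSV
#'
#' Long-format dialect: `point_id, peptide_total_uM, sh3_total_uM,
#' signal, observable, value` with optional `linewidth_hz` and
#' `shift_unit`. 19F rows (`observable = "shift_hz"`) given in ppm
#' (`shift_unit = "ppm"`) are converted to Hz, which requires the 19F
#' spectrometer frequency: pass `field` or a `spectrometer_mhz_19f`
#' argument, otherwise the read errors out.
#'
#' @param path CSV path.
#' @param field Optional [field_settings] used for ppm-to-Hz conversion.
#' @param spectrometer_mhz_19f Optional explicit 19F frequency (MHz);
#'   overrides `field`.
#' @return Data.frame ready for [fit_titration()].
#' @export
read_titration_csv <- function(path, field = NULL,
                               spectrometer_mhz_19f = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("peptide_total_uM", "sh3_total_uM", "signal",
                      "observable", "value"), basename(path))
  df <- check_numeric_rows(df, c("peptide_total_uM", "sh3_total_uM", "value"),
                           basename(path))
  if (!is.null(df$shift_unit)) {
    ppm_rows <- df$observable == "shift_hz" & df$shift_unit == "ppm"
    if (any(ppm_rows)) {
      mhz <- spectrometer_mhz_19f %||%
        (if (!is.null(field)) field$freq_F_mhz else NULL)
      if (is.null(mhz))
        stop("ppm 19F shifts need a spectrometer frequency: supply 'field' or 'spectrometer_mhz_19f'")
      df$value[ppm_rows] <- df$value[ppm_rows] * mhz
      df$shift_unit[ppm_rows] <- "Hz"
    }
  }
  df
}

#' Write titration data
#' @param data Titration data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read an exchange-broadening profile CSV
#'
#' Columns `point_id, signal, r2app_s1, peptide_total_uM, sh3_total_uM`
#' (one row per signal per titration point), the input of [fit_kon()].
#'
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("point_id", "signal", "r2app_s1", "peptide_total_uM",
                      "sh3_total_uM"), basename(path))
  check_numeric_rows(df, setdiff(names(df), "signal"), basename(path))
}

#' Write relaxation curves to CSV
#'
#' Emits the grid of a [relaxation_curves()] object in the dialect
#' `tau_c_s, R1_s1, R2_s1, sigma_HG_s1, noe_fraction`.
#'
#' @param curves A `relax_curves` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "relax_curves"))
  utils::write.csv(curves$grid, path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' Serialises parameters, uncertainties, goodness of fit and the package
#' version for provenance.
#'
#' @param fit Any `nmr_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(fit, path) {
  stopifnot(inherits(fit, "nmr_fit"))
  out <- list(
    class = class(fit)[1],
    parameters = as.list(fit$coefficients),
    uncertainties = as.list(fit$se),
    rss = fit$rss,
    reduced_chi2 = fit$reduced_chi2,
    converged = fit$converged,
    package_version = as.character(utils::packageVersion("fpronmr")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged experimental relaxation rates
#'
#' The measured 19F relaxation parameters of the four fluoroproline
#' signals (R1, steady-state NOE, rho, sigma, spin-echo and CPMG R2) as a
#' data.frame keyed by peptide and position.
#'
#' @return Data.frame from the packaged `fpro_relaxation_rates.csv`.
#' @export
fpro_relaxation_rates <- function() {
  path <- system.file("extdata", "fpro_relaxation_rates.csv",
                      package = "fpronmr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
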