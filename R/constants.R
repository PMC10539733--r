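#' Physical constants for the 1H/19F spin pair
#'
#' Gyromagnetic ratios of the proton and the fluorine-19 nucleus together
#' with the reduced Planck constant and the vacuum permeability factor
#' needed by the dipolar coupling constant. CODATA values.
#'
#' @return A list with elements `gamma_H`, `gamma_F` (rad s-1 T-1),
#'   `hbar` (J s) and `mu0_over_4pi` (T m A-1).
#' @examples
#' k <- nmr_constants()
#' k$gamma_H / k$gamma_F  # about 1.0624
#' @export
nmr_constants <- function() {
  list(
    gamma_H      = 2.6752218744e8,
    gamma_F      = 2.5181480e8,
    hbar         = 1.054571817e-34,
    mu0_over_4pi = 1e-7
  )
}

#' Static field settings
#'
#' Derives the angular Larmor frequencies of 1H and 19F from the static
#' field strength. The default 14.1 T corresponds to the 600 MHz (1H)
#' spectrometer on which the relaxation and titration data were acquired.
#'
#' @param b0 Static magnetic field in tesla.
#' @return An object of class `field_settings`: a list with `b0` (T),
#'   `omega_H` and `omega_F` (angular frequencies, rad s-1) and the 19F
#'   spectrometer frequency `freq_F_mhz` (MHz) used for ppm/Hz conversion.
#' @examples
#' field_settings()           # 14.1 T
#' field_settings(18.8)       # 800 MHz 1H magnet
#' @export
field_settings <- function(b0 = 14.1) {
  if (!is.numeric(b0) || length(b0) != 1L || !is.finite(b0) || b0 <= 0)
    stop("'b0' must be a single positive field strength in tesla")
  k <- nmr_constants()
  structure(list(
    b0         = b0,
    omega_H    = k$gamma_H * b0,
    omega_F    = k$gamma_F * b0,
    freq_F_mhz = k$gamma_F * b0 / (2 * pi) / 1e6
  ), class = "field_settings")
}

#' @export
print.field_settings <- function(x, ...) {
  cat(sprintf("Field settings: B0 = %.2f T  (1H %.1f MHz, 19F %.1f MHz)\n",
              x$b0, x$omega_H / (2 * pi) / 1e6, x$freq_F_mhz))
  invisible(x)
}
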