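#' Lorentzian spectral density
#'
#' Spectral density of rigid isotropic rotational diffusion,
#' `J(omega) = (2/5) tau_c / (1 + (omega tau_c)^2)`. This normalisation is
#' paired with the rate prefactors used by [r1_longitudinal()] and
#' friends; changing one without the other breaks the closed-form limits.
#'
#' @param omega Angular frequency (rad s-1); may be a vector.
#' @param tau_c Rotational correlation time (s); may be a vector if
#'   `omega` is scalar.
#' @return Spectral density in seconds.
#' @examples
#' spectral_density(0, 1e-9)        # (2/5) tau_c
#' spectral_density(1e9, 1e-9)      # halved at omega tau_c = 1
#' @export
spectral_density <- function(omega, tau_c) {
  if (any(!is.finite(tau_c)) || any(tau_c <= 0))
    stop("'tau_c' must be positive and finite")
  0.4 * tau_c / (1 + (omega * tau_c)^2)
}

#' Heteronuclear dipolar coupling constant
#'
#' `d = (mu0/4pi) gamma_H gamma_F hbar / r^3` for an F-H pair at distance
#' `r`, the amplitude entering the pairwise dipolar relaxation rates
#' (which scale as `d^2`, i.e. `r^-6`).
#'
#' @param r Internuclear distance in angstrom; may be a vector.
#' @param constants Physical constants, see [nmr_constants()].
#' @return Coupling constant in rad s-1.
#' @examples
#' dipolar_constant(2.03)   # about 8.5e4 rad/s
#' @export
dipolar_constant <- function(r, constants = nmr_constants()) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be a positive distance in angstrom")
  with(constants, mu0_over_4pi * gamma_H * gamma_F * hbar / (r * 1e-10)^3)
}

## CSA amplitude in rad/s from ppm anisotropy at the 19F Larmor frequency
csa_omega <- function(geom, field) geom$delta_sigma * 1e-6 * field$omega_F

#' 19F longitudinal relaxation rate
#'
#' Pairwise-additive dipole-dipole plus symmetric-CSA longitudinal rate:
#' \deqn{R_1 = \sum_i \frac{d_i^2}{4}\left[J(\omega_H-\omega_F) +
#'   3J(\omega_F) + 6J(\omega_H+\omega_F)\right] +
#'   \frac{(\Delta\sigma\,\omega_F)^2}{3}\left(1+\eta^2/3\right) J(\omega_F)}
#' summed over all protons of the geometry. Cross-correlations, H-H
#' couplings and the antisymmetric CSA are neglected; see the vignette
#' for what this costs relative to a full multi-spin treatment.
#'
#' @param geom A [spin_geometry].
#' @param tau_c Rotational correlation time(s) in seconds.
#' @param field A [field_settings] object.
#' @return Rate(s) in s-1, same length as `tau_c`.
#' @seealso [r2_transverse()], [noe_steady_state()], [relaxation_curves()]
#' @export
r1_longitudinal <- function(geom, tau_c, field = field_settings()) {
  stopifnot(inherits(geom, "spin_geometry"))
  if (length(geom$proton_distances) == 0L)
    stop("geometry has no protons")
  d2 <- dipolar_constant(geom$proton_distances)^2
  wH <- field$omega_H; wF <- field$omega_F
  dd <- vapply(tau_c, function(tc) {
    sum(d2 / 4 * (spectral_density(wH - wF, tc) +
                  3 * spectral_density(wF, tc) +
                  6 * spectral_density(wH + wF, tc)))
  }, numeric(1))
  csa <- csa_omega(geom, field)^2 / 3 * (1 + geom$eta_csa^2 / 3) *
    spectral_density(wF, tau_c)
  dd + csa
}

#' 19F transverse relaxation rate
#'
#' Pairwise-additive dipole-dipole plus symmetric-CSA transverse rate:
#' \deqn{R_2 = \sum_i \frac{d_i^2}{8}\left[4J(0) + J(\omega_H-\omega_F) +
#'   3J(\omega_F) + 6J(\omega_H) + 6J(\omega_H+\omega_F)\right] +
#'   \frac{(\Delta\sigma\,\omega_F)^2}{18}\left(1+\eta^2/3\right)
#'   \left[4J(0) + 3J(\omega_F)\right]}
#'
#' @inheritParams r1_longitudinal
#' @return Rate(s) in s-1.
#' @export
r2_transverse <- function(geom, tau_c, field = field_settings()) {
  stopifnot(inherits(geom, "spin_geometry"))
  if (length(geom$proton_distances) == 0L)
    stop("geometry has no protons")
  d2 <- dipolar_constant(geom$proton_distances)^2
  wH <- field$omega_H; wF <- field$omega_F
  dd <- vapply(tau_c, function(tc) {
    sum(d2 / 8 * (4 * spectral_density(0, tc) +
                  spectral_density(wH - wF, tc) +
                  3 * spectral_density(wF, tc) +
                  6 * spectral_density(wH, tc) +
                  6 * spectral_density(wH + wF, tc)))
  }, numeric(1))
  csa <- csa_omega(geom, field)^2 / 18 * (1 + geom$eta_csa^2 / 3) *
    (4 * spectral_density(0, tau_c) + 3 * spectral_density(wF, tau_c))
  dd + csa
}

#' Proton-fluorine cross-relaxation rate
#'
#' `sigma = (d^2/4) [6 J(omega_H + omega_F) - J(omega_H - omega_F)]` for a
#' single F-H vector. Positive in the extreme-narrowing limit, negative
#' for slow tumbling; the sign change drives the NOE sign inversion.
#'
#' @param r F-H distance in angstrom.
#' @param tau_c Correlation time(s) in seconds.
#' @param field A [field_settings].
#' @return Cross-relaxation rate(s) in s-1.
#' @examples
#' cross_relaxation_sigma(2.03, 0.5e-9)   # about -0.21 s-1 at 14.1 T
#' @export
cross_relaxation_sigma <- function(r, tau_c, field = field_settings()) {
  d2 <- dipolar_constant(r)^2
  d2 / 4 * (6 * spectral_density(field$omega_H + field$omega_F, tau_c) -
            spectral_density(field$omega_H - field$omega_F, tau_c))
}

#' Steady-state heteronuclear NOE on 19F
#'
#' Fractional steady-state NOE on the fluorine upon saturation of one
#' proton (default the geminal Hgamma):
#' `NOE = (gamma_H / gamma_F) sigma_sat / rho_total`,
#' where `rho_total` is the full 19F auto-relaxation rate
#' ([r1_longitudinal()], including CSA and the dipolar leakage from all
#' non-saturated protons) and `sigma_sat` the cross-relaxation rate to the
#' saturated proton (two-spin-plus-sink approximation).
#'
#' @inheritParams r1_longitudinal
#' @param saturated_proton Label of the saturated proton (must be present
#'   in the geometry).
#' @return Fractional NOE(s), e.g. `-0.199` for -19.9 %.
#' @export
noe_steady_state <- function(geom, tau_c, field = field_settings(),
                             saturated_proton = "HG") {
  stopifnot(inherits(geom, "spin_geometry"))
  if (!saturated_proton %in% names(geom$proton_distances))
    stop("saturated proton '", saturated_proton,
         "' not present in geometry (have: ",
         paste(names(geom$proton_distances), collapse = ", "), ")")
  k <- nmr_constants()
  sig <- cross_relaxation_sigma(geom$proton_distances[[saturated_proton]],
                                tau_c, field)
  (k$gamma_H / k$gamma_F) * sig / r1_longitudinal(geom, tau_c, field)
}

#' Invert the steady-state NOE to a rotational correlation time
#'
#' The NOE is strictly decreasing in `tau_c` on the sigmoidal branch
#' between about 10 ps and 5 ns; a measured NOE on that branch therefore
#' maps to a unique correlation time, found here by bisection on log
#' `tau_c` to 1e-6 relative tolerance.
#'
#' @inheritParams noe_steady_state
#' @param observed_noe Measured fractional NOE (e.g. `-0.199`).
#' @param bracket Search bracket in seconds (default 10 ps to 5 ns, the
#'   range over which the NOE is a reliable motion probe).
#' @return Correlation time in seconds.
#' @export
invert_tauc_from_noe <- function(geom, field = field_settings(),
                                 observed_noe, saturated_proton = "HG",
                                 bracket = c(1e-11, 5e-9)) {
  lo <- noe_steady_state(geom, bracket[2], field, saturated_proton)
  hi <- noe_steady_state(geom, bracket[1], field, saturated_proton)
  if (observed_noe < lo || observed_noe > hi)
    stop(sprintf(
      "observed NOE %.4f outside the attainable interval [%.4f, %.4f] for tau_c in [%.3g, %.3g] s",
      observed_noe, lo, hi, bracket[1], bracket[2]))
  f <- function(lt) noe_steady_state(geom, 10^lt, field, saturated_proton) -
    observed_noe
  root <- stats::uniroot(f, log10(bracket), tol = 1e-7)$root
  10^root
}

#' Find all correlation times consistent with an observed R1
#'
#' Because the dipolar and CSA contributions peak at different
#' frequencies, the R1(tau_c) curve can be "camel-hump" shaped and a
#' single measured R1 can correspond to up to four correlation times.
#' All crossings on the search window are located on a dense log grid and
#' refined by bisection; the caller picks the physically plausible one.
#'
#' @inheritParams r1_longitudinal
#' @param observed_r1 Measured longitudinal rate (s-1).
#' @param window Search window in seconds.
#' @param points_per_decade Grid density for crossing detection.
#' @return Sorted vector of correlation times (possibly empty).
#' @export
invert_tauc_from_r1 <- function(geom, field = field_settings(), observed_r1,
                                window = c(1e-11, 1e-7),
                                points_per_decade = 80) {
  if (!is.finite(observed_r1) || observed_r1 <= 0)
    stop("'observed_r1' must be positive")
  n <- ceiling(log10(window[2] / window[1]) * points_per_decade) + 1
  lt <- seq(log10(window[1]), log10(window[2]), length.out = n)
  f <- r1_longitudinal(geom, 10^lt, field) - observed_r1
  idx <- which(f[-1] * f[-n] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(x) r1_longitudinal(geom, 10^x, field) - observed_r1,
                   c(lt[i], lt[i + 1]), tol = 1e-8)$root
  }, numeric(1))
  exact <- lt[f == 0]
  sort(10^c(roots, exact))
}

#' Relaxation rates and NOE over a correlation-time grid
#'
#' Evaluates R1, R2, the Hgamma cross-relaxation rate and the
#' steady-state NOE on a log-spaced correlation-time grid, and locates
#' the local maxima of R1 (discrete detection followed by golden-section
#' refinement on log tau_c).
#'
#' @inheritParams r1_longitudinal
#' @param tau_min,tau_max Grid limits in seconds.
#' @param points_per_decade Grid density; at least 50 per decade is
#'   needed for dependable maxima detection (a warning is emitted below
#'   10).
#' @param saturated_proton Proton saturated for the NOE column.
#' @return An object of class `relax_curves`: list with `grid` (a
#'   data.frame `tau_c_s, R1_s1, R2_s1, sigma_HG_s1, noe_fraction`),
#'   `r1_maxima` (s), `geom` and `field`.
#' @examples
#' \donttest{
#' rc <- relaxation_curves(fpro_geometries("(4R)-exo major"))
#' rc$r1_maxima * 1e9   # two maxima, near 0.3 and 4 ns
#' }
#' @export
relaxation_curves <- function(geom, field = field_settings(),
                              tau_min = 1e-11, tau_max = 1e-7,
                              points_per_decade = 50,
                              saturated_proton = "HG") {
  if (points_per_decade < 10)
    warning("fewer than 10 grid points per decade; maxima detection unreliable")
  n <- ceiling(log10(tau_max / tau_min) * points_per_decade) + 1
  tau <- 10^seq(log10(tau_min), log10(tau_max), length.out = n)
  r1 <- r1_longitudinal(geom, tau, field)
  r2 <- r2_transverse(geom, tau, field)
  sg <- cross_relaxation_sigma(geom$proton_distances[[saturated_proton]],
                               tau, field)
  noe <- noe_steady_state(geom, tau, field, saturated_proton)
  ## local maxima of R1: discrete then golden-section refinement on log tau
  ix <- which(diff(sign(diff(r1))) == -2) + 1
  maxima <- vapply(ix, function(i) {
    opt <- stats::optimize(function(lt) -r1_longitudinal(geom, 10^lt, field),
                           interval = log10(c(tau[i - 1], tau[i + 1])),
                           tol = 1e-4)
    10^opt$minimum
  }, numeric(1))
  structure(list(
    grid = data.frame(tau_c_s = tau, R1_s1 = r1, R2_s1 = r2,
                      sigma_HG_s1 = sg, noe_fraction = noe),
    r1_maxima = maxima,
    geom = geom, field = field
  ), class = "relax_curves")
}

#' @export
print.relax_curves <- function(x, ...) {
  g <- x$grid
  cat("19F relaxation curves:", x$geom$label, "\n")
  cat(sprintf("  %d points, tau_c %.3g - %.3g s at %.1f T\n",
              nrow(g), min(g$tau_c_s), max(g$tau_c_s), x$field$b0))
  if (length(x$r1_maxima))
    cat("  R1 local maxima at tau_c =",
        paste(sprintf("%.3g ns", x$r1_maxima * 1e9), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.relax_curves <- function(x, which = c("R1", "R2", "noe"), ...) {
  which <- match.arg(which)
  g <- x$grid
  y <- switch(which, R1 = g$R1_s1, R2 = g$R2_s1, noe = 100 * g$noe_fraction)
  ylab <- switch(which, R1 = "R1 (s-1)", R2 = "R2 (s-1)", noe = "NOE (%)")
  graphics::plot(g$tau_c_s, y, type = "l", log = "x",
                 xlab = "tau_c (s)", ylab = ylab,
                 main = x$geom$label, ...)
  if (which == "R1" && length(x$r1_maxima))
    graphics::abline(v = x$r1_maxima, lty = 3)
  invisible(x)
}
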