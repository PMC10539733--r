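#' Spin-system geometry of a fluoroproline conformer
#'
#' Bundles the fluorine-proton internuclear distances and the 19F
#' chemical-shift-anisotropy (CSA) tensor summary of one ring conformer.
#' Distances are between the Cgamma fluorine and the ring protons that
#' dominate dipolar relaxation (Hgamma plus the two Hbeta and two Hdelta
#' protons). The antisymmetric CSA components are stored but not used by
#' the default relaxation model.
#'
#' @param label Conformer identifier, e.g. `"(4R)-exo major"`.
#' @param proton_distances Named numeric vector of F-H distances in
#'   angstrom; names from `c("HG","HB2","HB3","HD2","HD3")` (at least one
#'   required, all within 1.5-10 A).
#' @param delta_sigma CSA anisotropy (ppm, sign carried).
#' @param eta_csa CSA asymmetry parameter, in `[0, 1]`.
#' @param anti_xy,anti_xz,anti_yz Antisymmetric CSA tensor components
#'   (ppm); stored for completeness, unused by the rate expressions.
#' @return An object of class `spin_geometry`.
#' @examples
#' g <- spin_geometry("(4R)-exo major",
#'                    c(HG = 2.03, HB2 = 3.29, HB3 = 2.56, HD2 = 3.3, HD3 = 2.5),
#'                    delta_sigma = -74.2, eta_csa = 0.120)
#' g
#' @export
spin_geometry <- function(label, proton_distances, delta_sigma = 0,
                          eta_csa = 0, anti_xy = 0, anti_xz = 0, anti_yz = 0) {
  proton_distances <- proton_distances[!is.na(proton_distances)]
  if (length(proton_distances) == 0L)
    stop("at least one proton distance is required")
  if (is.null(names(proton_distances)) || any(names(proton_distances) == ""))
    stop("'proton_distances' must be a named vector (HG, HB2, HB3, HD2, HD3)")
  if (any(proton_distances <= 1.5 | proton_distances >= 10))
    stop("proton distances must lie in (1.5, 10) angstrom")
  if (!is.finite(eta_csa) || eta_csa < 0 || eta_csa > 1)
    stop("'eta_csa' must lie in [0, 1]")
  structure(list(
    label            = as.character(label),
    proton_distances = proton_distances,
    delta_sigma      = delta_sigma,
    eta_csa          = eta_csa,
    anti             = c(xy = anti_xy, xz = anti_xz, yz = anti_yz)
  ), class = "spin_geometry")
}

#' @export
print.spin_geometry <- function(x, ...) {
  cat("Fluoroproline spin geometry:", x$label, "\n")
  cat("  F-H distances (A): ",
      paste(sprintf("%s %.2f", names(x$proton_distances), x$proton_distances),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  CSA: delta_sigma = %.1f ppm, eta = %.3f\n",
              x$delta_sigma, x$eta_csa))
  invisible(x)
}

#' Packaged fluoroproline conformer geometries
#'
#' Loads the packaged table of DFT-derived F-H distances and 19F CSA
#' tensor parameters for the four Ac-FPro-NMe2 ring conformers: the major
#' pucker of each stereoisomer ((4R) Cgamma-exo, (4S) Cgamma-endo) and the
#' corresponding minor puckers.
#'
#' @param label Optional conformer label; if given, the single matching
#'   [spin_geometry] is returned, otherwise a named list of all four.
#' @return A `spin_geometry` or a named list of them.
#' @examples
#' names(fpro_geometries())
#' fpro_geometries("(4R)-exo major")
#' @export
fpro_geometries <- function(label = NULL) {
  path <- system.file("extdata", "fpro_geometry.csv", package = "fpronmr",
                      mustWork = TRUE)
  geoms <- read_geometry_csv(path)
  if (is.null(label)) return(geoms)
  if (!label %in% names(geoms))
    stop("unknown conformer '", label, "'; available: ",
         paste(names(geoms), collapse = ", "))
  geoms[[label]]
}
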