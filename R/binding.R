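#' Peptide-SH3 binding model
#'
#' Stoichiometry and macroscopic dissociation constants of the
#' peptide-SH3 interaction. The 1:2 model is two sequential steps
#' (P + L = PL with Kd1, PL + L = PL2 with Kd2), with no statistical
#' factors or cooperativity parameter.
#'
#' @param stoichiometry `"1:1"` or `"1:2"` (peptide:SH3).
#' @param kd Dissociation constant(s) in micromolar: one value for 1:1,
#'   two for 1:2.
#' @return Object of class `binding_model`.
#' @examples
#' binding_model("1:1", 96)
#' binding_model("1:2", c(96, 500))
#' @export
binding_model <- function(stoichiometry = c("1:1", "1:2"), kd) {
  stoichiometry <- match.arg(stoichiometry)
  nk <- if (stoichiometry == "1:1") 1L else 2L
  if (length(kd) != nk)
    stop(sprintf("a %s model needs exactly %d dissociation constant(s)",
                 stoichiometry, nk))
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("all Kd must be positive")
  structure(list(stoichiometry = stoichiometry, kd = as.numeric(kd)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Binding model %s (peptide:SH3), Kd = %s uM\n",
              x$stoichiometry, paste(signif(x$kd, 4), collapse = ", ")))
  invisible(x)
}

species_result <- function(free_peptide, free_sh3, complex_pl,
                           complex_pl2 = 0, peptide_total, sh3_total) {
  bound <- complex_pl + complex_pl2
  pb <- if (peptide_total > 0) bound / peptide_total else NA_real_
  structure(list(
    free_peptide = free_peptide, free_sh3 = free_sh3,
    complex_pl = complex_pl, complex_pl2 = complex_pl2,
    peptide_total = peptide_total, sh3_total = sh3_total,
    pb = pb, pf = 1 - pb,
    pb_undefined = peptide_total <= 0
  ), class = "species_conc")
}

#' @export
print.species_conc <- function(x, ...) {
  cat(sprintf("Species (uM): free peptide %.4g, free SH3 %.4g, PL %.4g, PL2 %.4g\n",
              x$free_peptide, x$free_sh3, x$complex_pl, x$complex_pl2))
  if (isTRUE(x$pb_undefined)) cat("  bound fraction undefined (no peptide)\n")
  else cat(sprintf("  peptide bound fraction pb = %.4f\n", x$pb))
  invisible(x)
}

#' Closed-form 1:1 equilibrium speciation
#'
#' Quadratic-formula solution of the single-site binding equilibrium:
#' `PL = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2` with the free
#' species following by mass conservation.
#'
#' @param peptide_total,sh3_total Total concentrations (uM, >= 0).
#' @param kd Dissociation constant (uM, > 0).
#' @return A `species_conc` object; `pb` is flagged undefined when
#'   `peptide_total` is zero.
#' @examples
#' s <- solve_equilibrium_1to1(314, 314, 96)
#' s$complex_pl   # about 181.9 uM
#' s$pb           # about 0.579
#' @export
solve_equilibrium_1to1 <- function(peptide_total, sh3_total, kd) {
  if (peptide_total < 0 || sh3_total < 0) stop("totals must be non-negative")
  if (!is.finite(kd) || kd <= 0) stop("'kd' must be positive")
  s <- peptide_total + sh3_total + kd
  cpx <- (s - sqrt(s^2 - 4 * peptide_total * sh3_total)) / 2
  cpx <- min(max(cpx, 0), peptide_total, sh3_total)
  species_result(peptide_total - cpx, sh3_total - cpx, cpx,
                 peptide_total = peptide_total, sh3_total = sh3_total)
}

## 1:2 speciation via monotone 1-D root solve on free SH3.
## P_free = P_tot / (1 + x/Kd1 + x^2/(Kd1 Kd2)); ligand conservation
## closes the system. Used by predictors/fitters for speed.
solve_equilibrium_1to2 <- function(peptide_total, sh3_total, kd1, kd2) {
  if (peptide_total < 0 || sh3_total < 0) stop("totals must be non-negative")
  if (sh3_total == 0 || peptide_total == 0) {
    return(species_result(peptide_total, sh3_total, 0, 0,
                          peptide_total, sh3_total))
  }
  f <- function(x) {
    pf <- peptide_total / (1 + x / kd1 + x^2 / (kd1 * kd2))
    x + pf * x / kd1 + 2 * pf * x^2 / (kd1 * kd2) - sh3_total
  }
  x <- stats::uniroot(f, c(0, sh3_total), tol = 1e-12 * max(sh3_total, 1))$root
  pf <- peptide_total / (1 + x / kd1 + x^2 / (kd1 * kd2))
  species_result(pf, x, pf * x / kd1, pf * x^2 / (kd1 * kd2),
                 peptide_total, sh3_total)
}

#' Equilibrium speciation for a binding model
#'
#' Dispatches to the closed-form quadratic (1:1) or the algebraic
#' root-solve (1:2). [solve_equilibrium_ode()] reaches the same state by
#' integrating the mass-action rate equations and serves as the
#' general-purpose route.
#'
#' @param model A [binding_model].
#' @param peptide_total,sh3_total Total concentrations (uM).
#' @return A `species_conc` object.
#' @export
solve_equilibrium <- function(model, peptide_total, sh3_total) {
  stopifnot(inherits(model, "binding_model"))
  if (model$stoichiometry == "1:1")
    solve_equilibrium_1to1(peptide_total, sh3_total, model$kd)
  else
    solve_equilibrium_1to2(peptide_total, sh3_total, model$kd[1], model$kd[2])
}

#' Equilibrium speciation by integrating mass-action kinetics
#'
#' Integrates the coupled mass-action differential equations of the
#' binding model (association rate constants normalised to 1 per uM per
#' unit time, dissociation rates equal to the Kd values) from the
#' all-free state until steady state, defined as a maximal concentration
#' derivative below `tol_deriv * max(totals, 1)` per unit time. The
#' stepper is backward Euler with Newton iterations on the (at most
#' two-dimensional) state: unconditionally stable, so arbitrarily stiff
#' rate constants (e.g. a second binding step switched off by a huge
#' Kd2) are handled, with the step size growing geometrically as the
#' stationary point is approached.
#'
#' @inheritParams solve_equilibrium
#' @param tol_deriv Steady-state threshold (relative, per unit time).
#' @param max_steps Step budget before giving up.
#' @return A `species_conc` object satisfying mass conservation and
#'   per-step detailed balance.
#' @examples
#' s <- solve_equilibrium_ode(binding_model("1:1", 96), 314, 314)
#' s$complex_pl   # matches the closed form
#' @export
solve_equilibrium_ode <- function(model, peptide_total, sh3_total,
                                  tol_deriv = 1e-10, max_steps = 1e4) {
  stopifnot(inherits(model, "binding_model"))
  if (peptide_total < 0 || sh3_total < 0) stop("totals must be non-negative")
  two_step <- model$stoichiometry == "1:2"
  kd1 <- model$kd[1]; kd2 <- if (two_step) model$kd[2] else Inf
  scale <- max(peptide_total, sh3_total, 1)
  thresh <- tol_deriv * scale

  deriv <- function(y) {
    c1 <- y[1]; c2 <- y[2]
    pf <- peptide_total - c1 - c2
    lf <- sh3_total - c1 - 2 * c2
    d1 <- pf * lf - kd1 * c1 - (if (two_step) c1 * lf - kd2 * c2 else 0)
    d2 <- if (two_step) c1 * lf - kd2 * c2 else 0
    c(d1, d2)
  }
  jac <- function(y) {
    eps <- 1e-7 * scale
    f0 <- deriv(y)
    cbind((deriv(y + c(eps, 0)) - f0) / eps,
          (deriv(y + c(0, eps)) - f0) / eps)
  }
  h <- 1 / (peptide_total + sh3_total + kd1 + 1)
  y <- c(0, 0)
  for (i in seq_len(max_steps)) {
    f <- deriv(y)
    if (max(abs(f)) < thresh)
      return(species_result(peptide_total - y[1] - y[2],
                            sh3_total - y[1] - 2 * y[2], y[1], y[2],
                            peptide_total, sh3_total))
    ## one backward-Euler step: Newton on g(z) = z - y - h f(z)
    z <- y
    ok <- FALSE
    for (newt in 1:50) {
      g <- z - y - h * deriv(z)
      if (max(abs(g)) < 1e-13 * scale) { ok <- TRUE; break }
      step <- tryCatch(solve(diag(2) - h * jac(z), -g),
                       error = function(e) NULL)
      if (is.null(step)) break
      z <- z + as.numeric(step)
    }
    if (ok) {
      y <- z
      h <- h * 1.5       # march towards stationarity with growing steps
    } else {
      h <- h / 4         # Newton failed: retry more cautiously
    }
  }
  stop(sprintf(
    "equilibrium integration did not reach steady state in %d steps (max |dX/dt| = %.3g)",
    max_steps, max(abs(deriv(y)))))
}

#' Fast-exchange population-averaged shift
#'
#' Under fast exchange the observed shift is the population-weighted
#' average over the free and bound states of the observed molecule. For
#' a peptide 19F signal the weights are the peptide's state fractions;
#' for a protein amide signal, use the protein's (see
#' [fit_titration()]). In the 1:2 model the doubly bound state
#' contributes with its own shift.
#'
#' @param conc A `species_conc` from one of the equilibrium solvers.
#' @param delta_free Shift of the free state (any unit).
#' @param delta_bound Shift of the singly bound state (same unit).
#' @param delta_bound2 Shift of the doubly bound state; defaults to
#'   `delta_bound`.
#' @return Observed shift, same unit as the inputs.
#' @export
predict_fast_exchange_shift <- function(conc, delta_free, delta_bound,
                                        delta_bound2 = delta_bound) {
  if (isTRUE(conc$pb_undefined))
    stop("bound fraction undefined: no peptide present")
  p1 <- conc$complex_pl / conc$peptide_total
  p2 <- conc$complex_pl2 / conc$peptide_total
  (1 - p1 - p2) * delta_free + p1 * delta_bound + p2 * delta_bound2
}

#' Composite amide chemical-shift perturbation
#'
#' `sqrt(dN^2 + weight * dH^2)` combining the 15N and 1H shift changes of
#' an amide correlation into one scalar. The relative weighting of the
#' two nuclei varies between conventions, so `weight` is configurable
#' (default 5).
#'
#' @param delta_n,delta_h 15N and 1H shift differences (ppm).
#' @param weight Weight on the squared proton term.
#' @return Composite shift perturbation (ppm).
#' @examples
#' composite_csp(0.2, 0.05)   # 0.2291
#' @export
composite_csp <- function(delta_n, delta_h, weight = 5) {
  sqrt(delta_n^2 + weight * delta_h^2)
}

#' Reduced chi-square of a fit
#'
#' `(1/(N - NP)) * sum((observed - calculated)^2)` with `N` observations
#' and `NP` fitted parameters.
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @param n_params Number of fitted parameters (`NP < N`).
#' @return The reduced chi-square.
#' @export
reduced_chi2 <- function(observed, calculated, n_params) {
  n <- length(observed)
  if (length(calculated) != n) stop("length mismatch")
  if (n_params >= n) stop("need more observations than parameters")
  sum((observed - calculated)^2) / (n - n_params)
}
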