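## Compact Levenberg-Marquardt least squares with forward-difference
## Jacobian. Internal: every fitting function in the package funnels
## through here so parameter covariance is computed the same way
## everywhere: vcov = s2 * (J'WJ)^-1 with s2 the reduced weighted RSS.

lm_least_squares <- function(par, resid_fn, weights = NULL,
                             maxit = 200, ftol = 1e-10, ptol = 1e-10) {
  par <- as.numeric(par)
  np <- length(par)
  r <- resid_fn(par)
  if (any(!is.finite(r))) stop("residuals not finite at the starting values")
  n <- length(r)
  if (n <= np) stop("fewer residuals (", n, ") than parameters (", np, ")")
  w <- if (is.null(weights)) rep(1, n) else weights
  sw <- sqrt(w)
  rss <- sum(w * r^2)

  jac <- function(p, r0) {
    J <- matrix(0, length(r0), np)
    for (j in seq_len(np)) {
      h <- max(1e-7 * abs(p[j]), 1e-10)
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (resid_fn(pj) - r0) / h
    }
    J
  }

  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(maxit)) {
    J <- jac(par, r)
    A <- crossprod(J * sw)
    g <- crossprod(J * w, r)
    improved <- FALSE
    for (k in 1:25) {
      step <- tryCatch(
        solve(A + lambda * diag(pmax(diag(A), 1e-12), np), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- par + as.numeric(step)
        rc <- resid_fn(cand)
        if (all(is.finite(rc))) {
          rssc <- sum(w * rc^2)
          if (rssc < rss) {
            rel_f <- (rss - rssc) / max(rss, .Machine$double.eps)
            rel_p <- max(abs(cand - par) / pmax(abs(par), 1e-12))
            par <- cand; r <- rc; rss <- rssc
            lambda <- max(lambda / 4, 1e-12)
            improved <- TRUE
            if (rel_f < ftol || rel_p < ptol) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 8
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  if (!converged && it == maxit)
    warning("Levenberg-Marquardt reached the iteration limit (residual norm ",
            format(sqrt(rss)), ")")

  J <- jac(par, r)
  A <- crossprod(J * sw)
  dof <- n - np
  s2 <- rss / dof
  vcov <- tryCatch(s2 * solve(A), error = function(e) {
    matrix(NA_real_, np, np)
  })
  list(par = par, residuals = r, rss = rss, weights = w,
       vcov = vcov, se = sqrt(pmax(diag(vcov), 0)), dof = dof,
       converged = converged, iterations = it)
}
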