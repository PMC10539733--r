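## Shared S3 methods for all fit objects in the package.

#' @export
coef.nmr_fit <- function(object, ...) object$coefficients

#' @export
vcov.nmr_fit <- function(object, ...) object$vcov

#' @export
residuals.nmr_fit <- function(object, ...) object$residuals

#' @export
fitted.nmr_fit <- function(object, ...) object$fitted

#' @export
print.nmr_fit <- function(x, digits = 4, ...) {
  cat(class(x)[1], if (!isTRUE(x$converged)) "(NOT converged)", "\n")
  est <- format(signif(x$coefficients, digits))
  se <- format(signif(x$se, digits))
  cat(paste0("  ", names(x$coefficients), " = ", est, " +/- ", se,
             collapse = "\n"), "\n")
  if (!is.null(x$noe_max))
    cat(sprintf("  steady-state NOE = %.1f %% +/- %.1f %%\n",
                100 * x$noe_max, 100 * x$noe_max_se))
  if (!is.null(x$reduced_chi2))
    cat(sprintf("  reduced chi-square = %.4g\n", x$reduced_chi2))
  invisible(x)
}

#' @export
summary.nmr_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(fit = object, coefficients = tab,
              rss = object$rss, dof = object$dof,
              sigma = sqrt(object$rss / object$dof))
  class(out) <- "summary.nmr_fit"
  out
}

#' @export
print.summary.nmr_fit <- function(x, ...) {
  cat("Fit:", class(x$fit)[1], "\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual standard error %.4g on %d degrees of freedom\n",
              x$sigma, x$dof))
  if (!is.null(x$fit$reduced_chi2))
    cat(sprintf("Reduced chi-square: %.4g\n", x$fit$reduced_chi2))
  invisible(x)
}

#' @export
predict.nmr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) stop("no prediction model stored in this fit")
  t <- if (is.null(newdata)) object$data$time_s else {
    if (is.list(newdata)) newdata$time_s else newdata
  }
  object$model(object$coefficients, t)
}

#' @export
plot.nmr_fit <- function(x, n = 200, ...) {
  d <- x$data
  if (is.null(d$time_s)) stop("no time-series data stored in this fit")
  graphics::plot(d$time_s, d$intensity, xlab = "time (s)",
                 ylab = "intensity", ...)
  tt <- seq(min(d$time_s), max(d$time_s), length.out = n)
  graphics::lines(tt, x$model(x$coefficients, tt))
  invisible(x)
}
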