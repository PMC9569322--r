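# Shared S3 methods for fitted model objects ("quench_fit").

#' @export
coef.quench_fit <- function(object, ...) object$coefficients

#' @export
fitted.quench_fit <- function(object, ...) object$fitted_values

#' @export
residuals.quench_fit <- function(object, ...) object$gof$residuals

#' Standard errors of fitted parameters
#'
#' @param object a fitted model returned by one of the `fit_*` functions.
#' @return named numeric vector of standard errors.
#' @export
std_errors <- function(object) UseMethod("std_errors")

#' @export
std_errors.quench_fit <- function(object) object$se

#' @export
print.quench_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  est <- x$coefficients
  se <- x$se
  for (nm in names(est)) {
    if (!is.na(se[nm])) {
      cat(sprintf("  %-12s %s +/- %s\n", nm,
                  format(est[[nm]], digits = digits),
                  format(se[[nm]], digits = 2)))
    } else {
      cat(sprintf("  %-12s %s\n", nm, format(est[[nm]], digits = digits)))
    }
  }
  cat("  "); print(x$gof)
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.quench_fit <- function(object, ...) {
  out <- list(
    class = class(object)[1],
    coefficients = cbind(Estimate = object$coefficients,
                         `Std. Error` = object$se),
    rmsd = object$gof$rmsd,
    chi2_red = object$gof$chi2_red,
    n = object$gof$n,
    flags = object$flags
  )
  class(out) <- "summary.quench_fit"
  out
}

#' @export
print.summary.quench_fit <- function(x, ...) {
  cat(sprintf("Model: %s  (n = %d points)\n", x$class, x$n))
  print(x$coefficients)
  cat(sprintf("RMSD = %.4g, chi2_red = %.4g\n", x$rmsd, x$chi2_red))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.quench_fit <- function(x, ...) {
  # Generic data-vs-fit display; subclasses supply axis metadata via
  # the plot_info() hook.
  info <- plot_info(x)
  plot(info$x, info$y, xlab = info$xlab, ylab = info$ylab,
       main = class(x)[1], ...)
  ord <- order(info$x)
  lines(info$x[ord], info$yhat[ord], col = "firebrick", lwd = 2)
  invisible(x)
}

plot_info <- function(x) UseMethod("plot_info")
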