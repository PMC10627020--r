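#' @export
print.kernel_curve <- function(x, ...) {
  cat("Kernel-width correlation curve")
  if (!is.na(x$band)) cat(sprintf(" (band: %s)", x$band))
  cat("\n")
  cat(sprintf("  %d electrodes, sigma %g-%g mm (%d widths), %s correlation\n",
              x$n_electrodes, min(x$sigma), max(x$sigma), length(x$sigma),
              x$method))
  cat(sprintf("  peak:      sigma = %6.2f mm, r2 = %.3f%s\n",
              x$peak_sigma, x$peak_r2,
              if (x$peak_on_boundary) "  [on grid boundary]" else ""))
  if (x$concavity_flag == "ok") {
    cat(sprintf("  concavity: sigma = %6.2f mm, r2 = %.3f\n",
                x$concavity_sigma, x$concavity_r2))
  } else {
    cat("  concavity: none (second derivative nowhere negative)\n")
  }
  invisible(x)
}

#' @export
summary.kernel_curve <- function(object, ...) {
  out <- list(
    band = object$band, n_electrodes = object$n_electrodes,
    n_dropped = object$n_dropped,
    sigma_range = range(object$sigma), n_sigma = length(object$sigma),
    peak_sigma = object$peak_sigma, peak_r2 = object$peak_r2,
    peak_slope = object$peak_slope,
    peak_on_boundary = object$peak_on_boundary,
    concavity_sigma = object$concavity_sigma,
    concavity_r2 = object$concavity_r2,
    concavity_flag = object$concavity_flag,
    slope_sign = sign(object$peak_slope)
  )
  class(out) <- "summary.kernel_curve"
  out
}

#' @export
print.summary.kernel_curve <- function(x, ...) {
  cat("Kernel-width curve summary\n")
  cat(sprintf("  band                 %s\n", x$band))
  cat(sprintf("  electrodes used      %d (%d dropped)\n", x$n_electrodes, x$n_dropped))
  cat(sprintf("  sigma grid           %g-%g mm, %d points\n",
              x$sigma_range[1], x$sigma_range[2], x$n_sigma))
  cat(sprintf("  peak sigma           %.2f mm (r2 = %.3f, slope = %+.3f)%s\n",
              x$peak_sigma, x$peak_r2, x$peak_slope,
              if (x$peak_on_boundary) " [boundary]" else ""))
  if (x$concavity_flag == "ok")
    cat(sprintf("  concavity sigma      %.2f mm (r2 = %.3f)\n",
                x$concavity_sigma, x$concavity_r2))
  else
    cat("  concavity sigma      not defined (no downwards concavity)\n")
  invisible(x)
}

#' Extract the fitted kernel-width summaries
#'
#' @param object A `kernel_curve`.
#' @param ... Unused.
#' @return Named numeric vector: `peak_sigma`, `peak_r2`, `peak_slope`,
#'   `concavity_sigma`, `concavity_r2`.
#' @export
coef.kernel_curve <- function(object, ...) {
  c(peak_sigma = object$peak_sigma, peak_r2 = object$peak_r2,
    peak_slope = object$peak_slope,
    concavity_sigma = object$concavity_sigma,
    concavity_r2 = object$concavity_r2)
}

#' @export
as.data.frame.kernel_curve <- function(x, ...) {
  data.frame(sigma = x$sigma, r = x$r, r2 = x$r2, slope = x$slope,
             n_electrodes = x$n_electrodes)
}

#' Plot an explained-variance versus kernel-width curve
#'
#' Top panel: r-squared against kernel width with the peak and concavity
#' widths marked. Bottom panel: the discrete second derivative whose
#' lowest trough defines the concavity point.
#'
#' @param x A `kernel_curve`.
#' @param ... Passed to the underlying line plot.
#' @export
plot.kernel_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$sigma, x$r2, type = "l", lwd = 2,
                 xlab = "kernel width sigma (mm)", ylab = expression(r^2),
                 main = if (!is.na(x$band)) paste("band:", x$band) else "", ...)
  graphics::abline(v = x$peak_sigma, col = "red3", lty = 2)
  if (x$concavity_flag == "ok")
    graphics::abline(v = x$concavity_sigma, col = "blue3", lty = 3)
  graphics::legend("bottomright", lty = c(2, 3), col = c("red3", "blue3"),
                   legend = c(sprintf("peak %.2f mm", x$peak_sigma),
                              if (x$concavity_flag == "ok")
                                sprintf("concavity %.2f mm", x$concavity_sigma)
                              else "no concavity"),
                   bty = "n")
  graphics::plot(as.numeric(names(x$d2r2)), x$d2r2, type = "l",
                 xlab = "kernel width sigma (mm)",
                 ylab = expression(d^2 * r^2 / d * sigma^2))
  graphics::abline(h = 0, col = "gray")
  invisible(x)
}
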