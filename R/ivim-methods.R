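#' @export
print.ivim <- function(x, digits = 4, ...) {
  cat(sprintf("IVIM bi-exponential fit (%s)\n", x$method))
  est <- coef(x)
  cat(sprintf("  S0 = %.*g, f = %.2f%%, D* = %.*g um^2/ms, D = %.*g um^2/ms\n",
              digits, est["S0"], 100 * est["f"], digits, est["Dstar"],
              digits, est["D"]))
  cat(sprintf("  RSS %.3g over %d points%s\n", x$rss, length(x$data$b),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Summarize an IVIM fit
#'
#' @param object an `ivim` fit.
#' @param ... unused.
#' @return an object of class `summary.ivim`.
#' @export
summary.ivim <- function(object, ...) {
  est <- coef(object)
  structure(list(coefficients = est,
                 f_percent = 100 * est[["f"]],
                 rss = object$rss,
                 sigma = sqrt(object$rss / max(1, length(object$data$b) - 4)),
                 n = length(object$data$b),
                 b_range = range(object$data$b),
                 method = object$method,
                 threshold = object$threshold,
                 converged = object$converged,
                 call = object$call),
            class = "summary.ivim")
}

#' @export
print.summary.ivim <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\nMethod: %s", x$method))
  if (x$method == "segmented")
    cat(sprintf(" (threshold %g s/mm^2)", x$threshold))
  cat(sprintf("\n%d b-values in [%g, %g] s/mm^2\n", x$n,
              x$b_range[1], x$b_range[2]))
  cat("\nEstimates:\n")
  print(signif(c(x$coefficients, `f (%)` = x$f_percent), digits))
  cat(sprintf("\nResidual sum of squares: %.4g (sigma %.4g)\n", x$rss, x$sigma))
  if (!x$converged) cat("Warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.ivim <- function(object, ...) object$coefficients

#' Predict IVIM signals
#'
#' @param object an `ivim` fit.
#' @param newdata optional vector of b-values, or a data frame with column
#'   `b`; defaults to the fitted b-values.
#' @param ... unused.
#' @return predicted signal values.
#' @export
predict.ivim <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$data$b
       else if (is.data.frame(newdata)) newdata$b
       else as.numeric(newdata)
  est <- coef(object)
  ivim_signal(b, est["S0"], est["f"], est["Dstar"], est["D"])
}

#' @export
fitted.ivim <- function(object, ...) object$fitted.values

#' @export
residuals.ivim <- function(object, ...) object$residuals

#' @export
deviance.ivim <- function(object, ...) object$rss

#' Plot an IVIM fit
#'
#' Signal versus b-value on a log scale with the fitted bi-exponential curve
#' and its mono-exponential tissue component.
#'
#' @param x an `ivim` fit.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ivim <- function(x, ...) {
  b <- x$data$b
  est <- coef(x)
  bb <- seq(min(b), max(b), length.out = 200)
  plot(b, x$data$signal, log = "y", xlab = expression(b ~ (s/mm^2)),
       ylab = "signal", ...)
  lines(bb, predict(x, bb), col = "steelblue", lwd = 2)
  lines(bb, est["S0"] * (1 - est["f"]) * exp(-bb * est["D"] * 1e-3),
        col = "grey50", lty = 2)
  legend("topright", bty = "n",
         legend = c("fit", "tissue component"),
         col = c("steelblue", "grey50"), lty = c(1, 2), lwd = c(2, 1))
  invisible(x)
}

#' Simulate Rician-noise replicates from an IVIM fit
#'
#' Draws noisy signal replicates at the fitted b-values: the noise-free
#' signal is treated as the magnitude of a complex value perturbed by
#' independent Gaussian noise with sigma = S0 / snr per channel.
#'
#' @param object an `ivim` fit.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param snr signal-to-noise ratio at b = 0.
#' @param ... unused.
#' @return a data frame with one column per replicate.
#' @export
simulate.ivim <- function(object, nsim = 1, seed = NULL, snr = 50, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old))
    set.seed(seed)
  }
  est <- coef(object)
  s <- predict(object)
  sigma <- est[["S0"]] / snr
  out <- replicate(nsim, rician(s, sigma))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# magnitude of a complex Gaussian perturbation of s
rician <- function(s, sigma) {
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}
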