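#' @export
print.exp_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%d-phase exponential fit (%d points)\n", x$n_phases, x$n))
  ph <- x$phases
  for (i in seq_len(nrow(ph))) {
    cat(sprintf("  phase %d: A = %s, k_obs = %s s^-1 (t1/2 = %s s)\n", i,
                signif(ph$amplitude[i], digits), signif(ph$k_obs[i], digits),
                signif(ph$t_half[i], digits)))
  }
  cat(sprintf("  offset = %s, reduced chi^2 = %s, runs-test p = %s\n",
              signif(x$offset, digits), signif(x$chi2_red, digits),
              signif(x$runs_p, digits)))
  invisible(x)
}

#' @export
summary.exp_fit <- function(object, ...) {
  ph <- object$phases
  tab <- cbind(
    estimate = c(ph$amplitude, ph$k_obs, object$offset),
    std.error = c(ph$se_amplitude, ph$se_k_obs, object$se_offset))
  rownames(tab) <- c(paste0("A", seq_len(nrow(ph))),
                     paste0("k_obs", seq_len(nrow(ph))), "offset")
  out <- list(coefficients = tab, phases = ph, n_phases = object$n_phases,
              chi2_red = object$chi2_red, runs_p = object$runs_p,
              sigma = object$sigma, n = object$n, converged = object$converged)
  class(out) <- "summary.exp_fit"
  out
}

#' @export
print.summary.exp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential-phase fit: %d phase(s), n = %d\n", x$n_phases, x$n))
  printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("half-lives (s): %s\n",
              paste(signif(x$phases$t_half, digits), collapse = ", ")))
  cat(sprintf("noise sigma = %s RFU, reduced chi^2 = %s, runs-test p = %s\n",
              signif(x$sigma, digits), signif(x$chi2_red, digits),
              signif(x$runs_p, digits)))
  if (!x$converged) cat("warning: fit did not report clean convergence\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  ph <- object$phases
  setNames(c(ph$amplitude, ph$k_obs, object$offset),
           c(paste0("A", seq_len(nrow(ph))),
             paste0("k_obs", seq_len(nrow(ph))), "offset"))
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time
       else if (is.list(newdata)) newdata$time %||% newdata[[1]]
       else as.numeric(newdata)
  .exp_model(t, object$phases$amplitude, object$phases$k_obs, object$offset)
}

#' @export
fitted.exp_fit <- function(object, ...) object$fitted.values

#' @export
residuals.exp_fit <- function(object, ...) object$residuals

#' @export
plot.exp_fit <- function(x, log = "x", ...) {
  op <- par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(par(op))
  plot(x$time, x$signal, log = log, col = "grey60", pch = 16, cex = 0.3,
       xlab = "", ylab = "signal (RFU)", xaxt = "n", ...)
  lines(x$time, x$fitted.values, col = "firebrick", lwd = 2)
  legend("topright", bty = "n",
         legend = sprintf("t1/2 = %s s",
                          paste(signif(x$phases$t_half, 3), collapse = ", ")))
  par(mar = c(4, 4, 0.5, 1))
  plot(x$time, x$residuals, log = log, col = "grey40", pch = 16, cex = 0.3,
       xlab = "time (s)", ylab = "residual")
  abline(h = 0, col = "firebrick")
  invisible(x)
}

#' Simulate traces from a fitted exponential model
#'
#' Draws new traces from the fitted rate equation plus Gaussian noise at
#' the estimated noise level.
#'
#' @param object an `"exp_fit"`.
#' @param nsim number of traces.
#' @param seed integer seed (required).
#' @param ... unused.
#' @return A list of [sf_trace()] objects.
#' @export
simulate.exp_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  mu <- object$fitted.values
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sf_trace(object$time, mu + rnorm(length(mu), 0, object$sigma),
             list(simulated_from_fit = TRUE))))
}

#' @importFrom stats printCoefmat
NULL
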