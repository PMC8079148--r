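# index of the first bin exceeding 5% of the channel maximum (the "steep
# rise"); used for background estimation and rise detection
.rise_index <- function(counts) {
  which(counts > 0.05 * max(counts))[1]
}

.check_rise <- function(counts, label) {
  idx <- .rise_index(counts)
  pre <- if (idx > 1) mean(counts[seq_len(idx - 1)]) else 0
  if (max(counts) <= 5 * max(pre, 1e-12) && pre > 0)
    stop("no detectable rise in channel ", label, call. = FALSE)
  idx
}

#' Align the polarization channels
#'
#' The vertical and horizontal channels traverse different path lengths,
#' offsetting their time axes (~380 ps on the reference setup).  The two
#' rising edges are timed by their half-maximum crossings (linearly
#' interpolated, a constant-fraction timing estimate -- the rising edge is
#' IRF-dominated and identical in both channels, unlike the decaying
#' tails, whose shapes differ with polarization) and the vertical channel
#' is shifted by the nearest integer-bin lag; the applied shift is
#' recorded in the metadata.
#'
#' @param decay a [polarized_decay()].
#' @param max_lag_bins largest admissible lag (bins).
#' @return The aligned `"polarized_decay"` (integer counts preserved;
#'   trailing bins pad with the edge value).
#' @export
align_channels <- function(decay, max_lag_bins = 60) {
  stopifnot(inherits(decay, "polarized_decay"))
  vv <- as.numeric(decay$i_vv); vh <- as.numeric(decay$i_vh)
  .check_rise(vv, "VV"); .check_rise(vh, "VH")
  n <- length(vv)
  edge <- function(x) {
    half <- max(x) / 2
    i <- which(x >= half)[1]
    if (is.na(i) || i == 1) return(i %||% NA_real_)
    i - 1 + (half - x[i - 1]) / (x[i] - x[i - 1])
  }
  edge_lag <- edge(vv) - edge(vh)
  lag <- round(edge_lag)
  if (!is.finite(lag) || abs(lag) > max_lag_bins)
    stop("rising edges could not be aligned within ", max_lag_bins,
         " bins", call. = FALSE)
  shift <- function(x, L) {
    if (L == 0) return(x)
    if (L > 0) c(x[(L + 1):n], rep(x[n], L))
    else c(rep(x[1], -L), x[seq_len(n + L)])
  }
  meta <- modifyList(decay$metadata,
                     list(applied_shift_bins = lag,
                          applied_shift_ps = lag * decay$bin_width_ps,
                          residual_shift_bins = edge_lag - lag))
  polarized_decay(decay$bin_ps, shift(vv, lag), vh, decay$bin_width_ps, meta)
}

#' Subtract the dark background
#'
#' The background of each channel is estimated as the average of the
#' signal before the steep rise (the pre-rise region), subtracted, and
#' negative bins floored at zero.  The estimates are recorded in the
#' metadata.
#'
#' @param decay a [polarized_decay()].
#' @param min_pre_bins minimum number of pre-rise bins required.
#' @param guard_bins bins immediately before the 5% crossing excluded from
#'   the average (default 8, about two IRF widths): the Gaussian IRF foot
#'   already carries signal there.
#' @return The background-subtracted `"polarized_decay"` (counts become
#'   non-integer).
#' @export
subtract_background <- function(decay, min_pre_bins = 20, guard_bins = 8) {
  stopifnot(inherits(decay, "polarized_decay"))
  bg <- numeric(2)
  out <- list(decay$i_vv, decay$i_vh)
  for (ch in 1:2) {
    x <- as.numeric(out[[ch]])
    idx <- .rise_index(x)
    if (is.na(idx) || idx - 1 < min_pre_bins)
      stop("insufficient pre-rise region (need >= ", min_pre_bins,
           " bins before the rise)", call. = FALSE)
    bg[ch] <- mean(x[seq_len(max(idx - 1 - guard_bins, min_pre_bins %/% 2))])
    out[[ch]] <- pmax(x - bg[ch], 0)
  }
  meta <- modifyList(decay$metadata,
                     list(background = c(vv = bg[1], vh = bg[2])))
  polarized_decay(decay$bin_ps, out[[1]], out[[2]], decay$bin_width_ps, meta)
}

#' Estimate the g factor by tail-matching
#'
#' The detection-efficiency ratio between the polarization channels
#' (including any neutral-density attenuation) is calibrated on a
#' fast-rotating free-dye control: beyond `window_start_ns` after the
#' rise the control is fully depolarized (`r ~ 0`), so the corrected
#' channels must overlap and `g` is the ratio of horizontal to vertical
#' counts there.  The ratio is computed from the summed counts over the
#' window (the Poisson maximum-likelihood scale factor), confined to a
#' window of `window_length_ns` where the control still has signal.
#'
#' The free chromophore is fully depolarized at equilibrium, so its true
#' limiting anisotropy is zero; with `refine = TRUE` (the default) the
#' initial ratio is polished by one Newton step that zeroes the control's
#' fitted limiting anisotropy, removing the small negative bias left by
#' residual rotational correlation inside the tail window.
#'
#' The g of a run's control sample is used for all samples of that run.
#'
#' @param decay a [polarized_decay()] of the sample; used as its own
#'   reference when `reference` is `NULL`.
#' @param reference aligned, background-subtracted control decay.
#' @param window_start_ns window start after the histogram peak (ns); the
#'   control's rotational correlation time must be much shorter.
#' @param window_length_ns window length (ns).
#' @param min_bins minimum number of bins in the window.
#' @param refine polish g so the reference's fitted limiting anisotropy
#'   is zero (valid when the reference is a free-rotor control).
#' @return The scalar g (I_VH / I_VV tail ratio) with the window recorded
#'   as attributes.
#' @export
estimate_g <- function(decay, reference = NULL, window_start_ns = 2,
                       window_length_ns = 1, min_bins = 30,
                       refine = TRUE) {
  ref <- reference %||% decay
  stopifnot(inherits(ref, "polarized_decay"))
  t <- ref$bin_ps / 1000
  peak <- t[which.max(ref$i_vh)]
  win <- which(t >= peak + window_start_ns &
                 t < peak + window_start_ns + window_length_ns)
  if (length(win) < min_bins)
    stop("tail window has fewer than ", min_bins, " bins", call. = FALSE)
  zero <- (ref$i_vv[win] + ref$i_vh[win]) == 0
  if (mean(zero) > 0.5)
    stop("more than half the tail-window bins are empty", call. = FALSE)
  vv <- as.numeric(ref$i_vv)
  # integer-bin alignment leaves a sub-bin residual delay; on a 300 ps
  # tail even +-4 ps skews the ratio by ~1%, so interpolate it out
  rho <- ref$metadata$residual_shift_bins %||% 0
  if (abs(rho) > 1e-6)
    vv <- approx(t, vv, xout = t + rho * ref$bin_width_ps / 1000,
                 rule = 2)$y
  svv <- sum(vv[win])
  if (svv <= 0) stop("no vertical-channel counts in the tail window",
                     call. = FALSE)
  g <- sum(ref$i_vh[win]) / svv
  if (refine) {
    ref2 <- polarized_decay(ref$bin_ps, vv, ref$i_vh, ref$bin_width_ps,
                            ref$metadata["background"])
    fit <- try(suppressWarnings(
      fit_anisotropy(anisotropy_trace(ref2, g), n_phases = 1)),
      silent = TRUE)
    # dr/dg = 1/(3g) where r ~ 0, so zeroing r_inf moves g by -3 g r_inf
    if (!inherits(fit, "try-error") && is.finite(fit$r_inf) &&
        abs(fit$r_inf) < 0.1)
      g <- g * (1 - 3 * fit$r_inf)
  }
  structure(g,
            window_ns = c(start = peak + window_start_ns,
                          end = peak + window_start_ns + window_length_ns))
}

#' Total fluorescence intensity
#'
#' `I_tot(t) = g I_VV(t) + 2 I_VH(t)`, the anisotropy-free total emission
#' of the sample, from aligned and background-subtracted channels.
#'
#' @param decay a [polarized_decay()].
#' @param g detection-efficiency ratio from [estimate_g()].
#' @return Object of class `"intensity_trace"`: `time_ns`, `intensity`,
#'   Poisson-propagated `variance`, and the peak time.
#' @export
total_intensity <- function(decay, g) {
  stopifnot(inherits(decay, "polarized_decay"))
  stop_if_not_scalar_pos(as.numeric(g), "g")
  g <- as.numeric(g)
  intensity <- g * decay$i_vv + 2 * decay$i_vh
  structure(list(time_ns = decay$bin_ps / 1000, intensity = intensity,
                 variance = g^2 * decay$i_vv + 4 * decay$i_vh,
                 t_peak_ns = decay$bin_ps[which.max(intensity)] / 1000,
                 g = g, metadata = decay$metadata),
            class = "intensity_trace")
}

#' Transient fluorescence anisotropy
#'
#' `r(t) = (g I_VV - I_VH) / (g I_VV + 2 I_VH)` per bin, from aligned and
#' background-subtracted channels.  Bins before the histogram peak and
#' bins whose denominator holds fewer than `min_counts` counts are masked
#' (per-bin anisotropy noise diverges as counts vanish).
#'
#' @inheritParams total_intensity
#' @param min_counts minimum denominator counts per valid bin.
#' @param max_sd bins whose Poisson-propagated anisotropy standard
#'   deviation exceeds this are masked as well: with a strong
#'   neutral-density imbalance the scaled denominator can clear
#'   `min_counts` while the per-bin anisotropy is still essentially
#'   unconstrained.
#' @return Object of class `"anisotropy_trace"`: `time_ns`, `r`,
#'   Poisson-propagated `var_r`, logical `valid`, peak time `t_peak_ns`
#'   and rising-edge zero-time `t_zero_ns`.
#' @export
anisotropy_trace <- function(decay, g, min_counts = 100, max_sd = 0.04) {
  stopifnot(inherits(decay, "polarized_decay"))
  g <- as.numeric(g)
  stop_if_not_scalar_pos(g, "g")
  D <- g * decay$i_vv
  H <- decay$i_vh
  S <- D + 2 * H
  t <- decay$bin_ps / 1000
  t_peak <- t[which.max(S)]
  # excitation zero-time: half-maximum crossing of the rising edge (the
  # histogram maximum falls a few bins later because early bins integrate
  # the rising flank); decays are referenced to this time
  half <- max(S) / 2
  i <- which(S >= half)[1]
  t_zero <- if (i > 1)
    t[i - 1] + (half - S[i - 1]) / (S[i] - S[i - 1]) * diff(t[1:2])
  else t[i]
  r <- ifelse(S > 0, (D - H) / S, NA_real_)
  # delta-method variance: Var(VV) ~ VV, Var(VH) ~ VH (Poisson); counts
  # floored at 1 so empty-channel bins keep a finite, positive variance
  VVf <- pmax(as.numeric(decay$i_vv), 1)
  VHf <- pmax(as.numeric(decay$i_vh), 1)
  Df <- g * VVf; Sf <- Df + 2 * VHf
  var_r <- (3 * VHf / Sf^2)^2 * g^2 * VVf + (3 * Df / Sf^2)^2 * VHf
  valid <- S >= min_counts & t >= t_peak & sqrt(var_r) <= max_sd
  if (!any(valid)) stop("all bins masked; nothing to analyze", call. = FALSE)
  r[!valid] <- NA_real_
  structure(list(time_ns = t, r = r, var_r = var_r, valid = valid,
                 t_peak_ns = t_peak, t_zero_ns = t_zero, g = g,
                 metadata = decay$metadata),
            class = "anisotropy_trace")
}

#' @export
print.anisotropy_trace <- function(x, ...) {
  cat(sprintf("Anisotropy trace: %d valid bins, peak at %.3g ns\n",
              sum(x$valid), x$t_peak_ns))
  invisible(x)
}

#' @export
plot.anisotropy_trace <- function(x, ...) {
  plot(x$time_ns[x$valid], x$r[x$valid], pch = 16, cex = 0.4,
       xlab = "time (ns)", ylab = "anisotropy r(t)", ...)
  invisible(x)
}

#' Fit the fluorescence lifetime decay
#'
#' Tail fit (no IRF reconvolution) of the total-intensity decay with a
#' single- or bi-exponential model, starting `start_offset_ps` after the
#' histogram peak; all reported lifetimes are well above the 60 ps IRF so
#' the tail is undistorted.  With `n_components = NULL` the number of
#' components follows the minimal-number-of-terms rule of
#' [select_model()].  The mean lifetime is the amplitude-weighted average.
#'
#' @param intensity an [total_intensity()] trace.
#' @param n_components 1, 2 or `NULL` (automatic).
#' @param start_offset_ps fit start after the peak (ps).
#' @param min_counts bins below this intensity are excluded from the fit.
#' @return Object of class `"lifetime_fit"`: `components` (data frame of
#'   `tau_ns`, `amplitude`, `fraction`), `mean_lifetime_ns`, `chi2_red`.
#' @export
fit_lifetime <- function(intensity, n_components = NULL,
                         start_offset_ps = 100, min_counts = 10) {
  stopifnot(inherits(intensity, "intensity_trace"))
  sel <- intensity$time_ns >= intensity$t_peak_ns + start_offset_ps / 1000 &
    intensity$intensity >= min_counts
  t <- intensity$time_ns[sel] - intensity$t_peak_ns
  y <- intensity$intensity[sel]
  if (length(t) < 50)
    stop("fewer than 50 usable bins after the peak", call. = FALSE)
  w <- 1 / pmax(intensity$variance[sel], 1)

  fit_n <- function(nc) {
    f <- .fit_multiexp(t, y, nc, weights = w)
    f$n_phases <- nc; f$n <- length(t)
    f$aicc <- {
      p <- 2 * nc + 1
      length(t) * log(f$rss / length(t)) + 2 * p +
        2 * p * (p + 1) / max(length(t) - p - 1, 1)
    }
    f
  }
  if (!is.null(n_components)) {
    f <- fit_n(as.integer(n_components))
  } else {
    f1 <- fit_n(1L)
    f2 <- try(fit_n(2L), silent = TRUE)
    f <- f1
    if (!inherits(f2, "try-error")) {
      amp <- abs(f2$A)
      if ((f1$aicc - f2$aicc) > 10 && all(amp >= 0.05 * sum(amp)) &&
          f2$k[1] / f2$k[2] >= 3) f <- f2
    }
  }
  tau <- 1 / f$k                       # k sorted fast->slow => tau short->long
  amp <- f$A
  structure(list(
    components = data.frame(tau_ns = tau, amplitude = amp,
                            fraction = amp / sum(amp)),
    mean_lifetime_ns = sum(amp * tau) / sum(amp),
    offset = f$offset, chi2_red = f$rss / f$dof,
    n_components = length(tau), time_ns = t + intensity$t_peak_ns,
    fitted = f$fitted, observed = y), class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Lifetime fit: %d component(s)\n", x$n_components))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  tau%d = %s ns (%s%%)\n", i, signif(comp$tau_ns[i], digits),
                signif(100 * comp$fraction[i], digits)))
  cat(sprintf("  mean lifetime = %s ns, reduced chi^2 = %s\n",
              signif(x$mean_lifetime_ns, digits), signif(x$chi2_red, digits)))
  invisible(x)
}

#' Fit the anisotropy decay
#'
#' Weighted least-squares fit of
#' `r(t) = sum_i A_i exp(-(t - t_zero)/phi_i) + r_inf` with one or two
#' phases over the valid bins, starting `start_offset_bins` after the
#' excitation zero-time (about 1.5 IRF widths, skipping
#' convolution-distorted bins around the peak); weights are the inverse
#' Poisson-propagated variances.  The fundamental anisotropy
#' `r0 = sum(A_i) + r_inf` is the fit extrapolated to the zero-time (the
#' rising-edge half-maximum crossing, the estimate of the IRF peak), and
#' `delta_r = r0 - r_inf`.  With `n_phases = NULL` the
#' minimal-number-of-terms rule applies, and a trace with no resolvable
#' decay returns zero phases with `delta_r = 0`.
#'
#' @param trace an [anisotropy_trace()].
#' @param n_phases 1, 2 or `NULL` (automatic).
#' @param start_offset_bins bins skipped after the excitation zero-time.
#' @param delta_aicc,min_amp_frac,min_ratio selection thresholds as in
#'   [select_model()].
#' @return Object of class `"anisotropy_fit"`: `phases` (data frame of
#'   `amplitude`, `phi_ns`, standard errors, sorted fast to slow),
#'   `r_inf`, `r0`, `delta_r`, `chi2_red`.  Fits with `r0 > 0.44` (beyond
#'   the one-photon limit plus tolerance) are flagged.
#' @export
fit_anisotropy <- function(trace, n_phases = NULL, start_offset_bins = 6,
                           delta_aicc = 10, min_amp_frac = 0.05,
                           min_ratio = 3) {
  stopifnot(inherits(trace, "anisotropy_trace"))
  bw_ns <- diff(trace$time_ns[1:2])
  sel <- trace$valid &
    trace$time_ns >= trace$t_zero_ns + start_offset_bins * bw_ns
  t <- trace$time_ns[sel] - trace$t_zero_ns
  y <- trace$r[sel]
  w <- 1 / pmax(trace$var_r[sel], 1e-12)
  if (length(t) < 50) stop("fewer than 50 valid points", call. = FALSE)

  fit_n <- function(nc) {
    f <- .fit_multiexp(t, y, nc, weights = w)
    p <- 2 * nc + 1
    f$aicc <- length(t) * log(f$rss / length(t)) + 2 * p +
      2 * p * (p + 1) / max(length(t) - p - 1, 1)
    f$nc <- nc
    f
  }

  f1 <- fit_n(1L)
  no_decay <- abs(f1$A[1]) < max(2 * f1$se_A[1], 2e-3, na.rm = TRUE)
  if (is.null(n_phases)) {
    if (no_decay) {
      f <- NULL
    } else {
      f2 <- try(fit_n(2L), silent = TRUE)
      f <- f1
      if (!inherits(f2, "try-error")) {
        amp <- abs(f2$A)
        if ((f1$aicc - f2$aicc) > delta_aicc &&
            all(amp >= min_amp_frac * sum(amp)) &&
            f2$k[1] / f2$k[2] >= min_ratio) f <- f2
      }
    }
  } else if (n_phases == 0) {
    f <- NULL
  } else {
    f <- fit_n(as.integer(n_phases))
  }

  if (is.null(f)) {                     # constant anisotropy
    r_inf <- sum(w * y) / sum(w)
    out <- list(phases = data.frame(amplitude = numeric(0),
                                    phi_ns = numeric(0),
                                    se_amplitude = numeric(0),
                                    se_phi_ns = numeric(0)),
                r_inf = r_inf, r0 = r_inf, delta_r = 0,
                chi2_red = sum(w * (y - r_inf)^2) / max(length(y) - 1, 1),
                n_phases = 0L, fitted = rep(r_inf, length(y)))
  } else {
    phi <- 1 / f$k
    out <- list(phases = data.frame(amplitude = f$A, phi_ns = phi,
                                    se_amplitude = f$se_A,
                                    se_phi_ns = f$se_k / f$k^2),
                r_inf = f$offset, r0 = sum(f$A) + f$offset,
                delta_r = sum(f$A), chi2_red = f$rss / f$dof,
                n_phases = f$nc, fitted = f$fitted)
  }
  out$time_ns <- t + trace$t_zero_ns
  out$observed <- y
  out$t_zero_ns <- trace$t_zero_ns
  out$flag_r0 <- out$r0 > 0.44
  if (out$flag_r0)
    warning("fitted r0 exceeds the one-photon limit (0.44); check g factor")
  structure(out, class = "anisotropy_fit")
}

#' @export
print.anisotropy_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Anisotropy fit: %d phase(s)\n", x$n_phases))
  ph <- x$phases
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  phi%d = %s ns (A = %s)\n", i, signif(ph$phi_ns[i], digits),
                signif(ph$amplitude[i], digits)))
  cat(sprintf("  r0 = %s, r_inf = %s, delta_r = %s, reduced chi^2 = %s\n",
              signif(x$r0, digits), signif(x$r_inf, digits),
              signif(x$delta_r, digits), signif(x$chi2_red, digits)))
  invisible(x)
}

#' @export
coef.anisotropy_fit <- function(object, ...) {
  ph <- object$phases
  setNames(c(ph$amplitude, ph$phi_ns, object$r_inf),
           c(paste0("A", seq_len(nrow(ph))),
             paste0("phi", seq_len(nrow(ph))), "r_inf"))
}

#' @export
plot.anisotropy_fit <- function(x, ...) {
  plot(x$time_ns, x$observed, pch = 16, cex = 0.4, col = "grey60",
       xlab = "time (ns)", ylab = "anisotropy r(t)", ...)
  lines(x$time_ns, x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Independent single-exponential refit of the fast anisotropy phase
#'
#' Sub-nanosecond correlation times from a global two-phase fit are
#' entangled with the slow phase; to obtain precise fast-phase values the
#' early window is analyzed separately with a single-exponential rate
#' equation.  When a two-phase global fit is supplied, its slow component
#' and limiting anisotropy are first subtracted (the slow phase is not
#' flat even over a short window, so a free constant alone cannot absorb
#' it); the refit values supersede the global fast phase in reports.
#'
#' @param trace an [anisotropy_trace()].
#' @param fit optional global [fit_anisotropy()] result; supplies the
#'   default window (a third of the slow correlation time) and the slow
#'   component to subtract.
#' @param window_ns fit window length after the excitation zero-time (ns).
#' @param start_offset_bins bins skipped after the zero-time.
#' @return Object of class `"anisotropy_refit"`: `amplitude`, `phi_ns`,
#'   `se_phi_ns`.
#' @export
refit_fast_phase <- function(trace, fit = NULL, window_ns = NULL,
                             start_offset_bins = 6) {
  stopifnot(inherits(trace, "anisotropy_trace"))
  if (is.null(window_ns)) {
    if (is.null(fit) || fit$n_phases < 2)
      stop("supply `window_ns` or a two-phase global fit", call. = FALSE)
    window_ns <- fit$phases$phi_ns[fit$n_phases] / 3
  }
  bw_ns <- diff(trace$time_ns[1:2])
  sel <- trace$valid &
    trace$time_ns >= trace$t_zero_ns + start_offset_bins * bw_ns &
    trace$time_ns <= trace$t_zero_ns + window_ns
  if (sum(sel) < 10) stop("fast-phase window has fewer than 10 points",
                          call. = FALSE)
  t <- trace$time_ns[sel] - trace$t_zero_ns
  y <- trace$r[sel]
  if (!is.null(fit) && fit$n_phases >= 2) {
    slow <- seq_len(nrow(fit$phases))[-1]
    y <- y - fit$r_inf -
      as.numeric(exp(-outer(t, 1 / fit$phases$phi_ns[slow])) %*%
                   fit$phases$amplitude[slow])
  }
  w <- 1 / pmax(trace$var_r[sel], 1e-12)
  f <- .fit_multiexp(t, y, 1L, weights = w)
  structure(list(amplitude = f$A[1], phi_ns = 1 / f$k[1],
                 se_phi_ns = f$se_k[1] / f$k[1]^2, offset = f$offset,
                 window_ns = window_ns, n = length(t)),
            class = "anisotropy_refit")
}

#' @export
print.anisotropy_refit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Fast-phase refit: phi = %s ns (A = %s) over %g ns window (%d pts)\n",
    signif(x$phi_ns, digits), signif(x$amplitude, digits), x$window_ns, x$n))
  invisible(x)
}

#' Run the full TCSPC processing chain
#'
#' Align channels, subtract background, calibrate g on the control (or the
#' decay itself for a free-dye run), build the total-intensity and
#' anisotropy traces, and fit lifetimes and anisotropy decay; for
#' two-phase anisotropy fits the fast phase is refit independently over an
#' early window, and the refit values supersede the global fast phase in
#' reports.
#'
#' @param decay sample [polarized_decay()].
#' @param control optional control-sample decay (free dye); processed the
#'   same way and used for [estimate_g()].
#' @param g optionally a known g factor (skips estimation).
#' @param n_lifetimes,n_phases passed to [fit_lifetime()] and
#'   [fit_anisotropy()].
#' @param ... passed to [fit_anisotropy()].
#' @return Object of class `"tcspc_analysis"`: `g`, `lifetime`,
#'   `anisotropy`, `fast_refit` (or `NULL`), and the processed traces.
#' @export
process_decay <- function(decay, control = NULL, g = NULL,
                          n_lifetimes = NULL, n_phases = NULL, ...) {
  prep <- function(d) subtract_background(align_channels(d))
  d <- prep(decay)
  if (is.null(g)) {
    ref <- if (is.null(control)) d else prep(control)
    g <- estimate_g(d, reference = ref)
  }
  itot <- total_intensity(d, g)
  atr <- anisotropy_trace(d, g)
  lf <- fit_lifetime(itot, n_components = n_lifetimes)
  af <- fit_anisotropy(atr, n_phases = n_phases, ...)
  refit <- if (af$n_phases >= 2)
    refit_fast_phase(atr, fit = af) else NULL
  structure(list(g = as.numeric(g), lifetime = lf, anisotropy = af,
                 fast_refit = refit, intensity = itot, trace = atr,
                 decay = d), class = "tcspc_analysis")
}

#' @export
print.tcspc_analysis <- function(x, digits = 3, ...) {
  cat("TCSPC analysis (g =", signif(x$g, digits), ")\n")
  print(x$lifetime, digits = digits)
  print(x$anisotropy, digits = digits)
  if (!is.null(x$fast_refit)) print(x$fast_refit, digits = digits)
  invisible(x)
}
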