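#' Photophysics model for a labeled sample
#'
#' Fluorescence intensity decay (one or two lifetimes) plus an anisotropy
#' decay model `r(t) = sum_i A_i exp(-t/phi_i) + r_inf`.  The fundamental
#' anisotropy `r0 = sum(A_i) + r_inf` must lie in (0, 0.4], the one-photon
#' excitation limit.
#'
#' @param lifetimes data frame with columns `tau_ns` (> 0) and `fraction`
#'   (summing to 1).
#' @param anisotropy data frame with columns `amplitude` and `phi_ns`
#'   (rotational correlation times, > 0).
#' @param r_inf limiting anisotropy (plateau), nonnegative.
#' @return Object of class `"photophysics_model"`.
#' @examples
#' cy3_nhs_control()
#' @export
photophysics_model <- function(lifetimes, anisotropy, r_inf = 0) {
  stopifnot(is.data.frame(lifetimes),
            all(c("tau_ns", "fraction") %in% names(lifetimes)),
            is.data.frame(anisotropy),
            all(c("amplitude", "phi_ns") %in% names(anisotropy)))
  if (any(lifetimes$tau_ns <= 0) || any(anisotropy$phi_ns <= 0))
    stop("lifetimes and correlation times must be positive", call. = FALSE)
  if (abs(sum(lifetimes$fraction) - 1) > 1e-8)
    stop("lifetime fractions must sum to 1", call. = FALSE)
  r0 <- sum(anisotropy$amplitude) + r_inf
  if (r0 <= 0 || r0 > 0.4 + 1e-12)
    stop("r0 = sum(A) + r_inf must lie in (0, 0.4]", call. = FALSE)
  structure(list(lifetimes = lifetimes, anisotropy = anisotropy,
                 r_inf = r_inf, r0 = r0), class = "photophysics_model")
}

#' @export
print.photophysics_model <- function(x, ...) {
  cat("Photophysics model\n  lifetimes (ns):",
      paste(sprintf("%g (%g%%)", x$lifetimes$tau_ns,
                    100 * x$lifetimes$fraction), collapse = ", "), "\n")
  cat("  anisotropy: r0 =", x$r0, "; phi (ns):",
      paste(sprintf("%g (A=%g)", x$anisotropy$phi_ns,
                    x$anisotropy$amplitude), collapse = ", "),
      "; r_inf =", x$r_inf, "\n")
  invisible(x)
}

#' Free-dye control photophysics (Cy3-NHS in buffer)
#'
#' Fast-rotating free chromophore used for g-factor tail-matching:
#' fluorescence lifetime 300 ps, fundamental anisotropy 0.40, rotational
#' diffusion time 440 ps, no residual anisotropy.
#'
#' @return A [photophysics_model()].
#' @export
cy3_nhs_control <- function() {
  photophysics_model(
    lifetimes = data.frame(tau_ns = 0.3, fraction = 1),
    anisotropy = data.frame(amplitude = 0.40, phi_ns = 0.44),
    r_inf = 0)
}

#' Free Cy3-end-labeled 52-bp dsRNA photophysics
#'
#' Bi-exponential intensity decay (1.21 and 2.28 ns, 88%/12%) and a
#' two-component anisotropy decay: fast local probe wobble (phi1 0.34 ns)
#' and slower local tumbling of the hydrated duplex (phi2 2.6 ns) carrying
#' 20% and 80% of the decaying anisotropy span, with r0 = 0.40 and a small
#' limiting anisotropy.
#'
#' @param r_inf limiting anisotropy (default 0.02).
#' @return A [photophysics_model()].
#' @export
dsrna_free_model <- function(r_inf = 0.02) {
  dr <- 0.40 - r_inf
  photophysics_model(
    lifetimes = data.frame(tau_ns = c(1.21, 2.28), fraction = c(0.88, 0.12)),
    anisotropy = data.frame(amplitude = dr * c(0.20, 0.80),
                            phi_ns = c(0.34, 2.6)),
    r_inf = r_inf)
}

#' TCSPC instrument model
#'
#' Instrument distortions applied by [simulate_decay()]: Gaussian IRF
#' (FWHM default 60 ps), 16 ps bins over one 80 MHz excitation period
#' (12.5 ns, truncated to 781 whole bins = 12.496 ns), ~380 ps
#' inter-channel path delay applied to the vertical
#' channel, detection-efficiency mismatch `g_true`, a neutral-density
#' filter (OD 1.0, factor 10) attenuating the vertical channel, dark
#' background, and Poisson counting.  The IRF peak sits 1.5 ns into the
#' window so a pre-rise background region exists, as in real histograms.
#'
#' @param irf_fwhm_ps IRF full width at half maximum (ps).
#' @param bin_width_ps histogram bin width (ps).
#' @param window_ns histogram window (ns); must be an integer number of
#'   bins.
#' @param channel_delay_ps vertical-channel delay (ps).
#' @param g_true detection-efficiency ratio (dimensionless, > 0).
#' @param nd_attenuation attenuation factor of the vertical channel
#'   (default 10, OD 1.0).
#' @param background_rate dark counts per bin per channel.
#' @param total_counts expected total signal counts over both channels.
#' @param irf_peak_ns position of the IRF peak in the window (ns).
#' @return Object of class `"instrument_model"`.
#' @export
instrument_model <- function(irf_fwhm_ps = 60, bin_width_ps = 16,
                             window_ns = 12.496, channel_delay_ps = 380,
                             g_true = 1, nd_attenuation = 10,
                             background_rate = 0, total_counts = 1e7,
                             irf_peak_ns = 1.5) {
  stop_if_not_scalar_pos(bin_width_ps, "bin_width_ps")
  stop_if_not_scalar_pos(g_true, "g_true")
  n_bins <- window_ns * 1000 / bin_width_ps
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("window must be an integer number of bins", call. = FALSE)
  structure(list(irf_fwhm_ps = irf_fwhm_ps, bin_width_ps = bin_width_ps,
                 window_ns = window_ns, channel_delay_ps = channel_delay_ps,
                 g_true = g_true, nd_attenuation = nd_attenuation,
                 background_rate = background_rate,
                 total_counts = total_counts, irf_peak_ns = irf_peak_ns,
                 n_bins = as.integer(round(n_bins))),
            class = "instrument_model")
}

#' Histogram bin centers of an instrument model
#'
#' @param inst an [instrument_model()].
#' @return Bin-center times (ps).
#' @export
tcspc_bin_grid <- function(inst) {
  (seq_len(inst$n_bins) - 0.5) * inst$bin_width_ps
}

#' Ideal polarized fluorescence intensities
#'
#' Standard polarized decomposition: `I_tot(t) = sum_j f_j exp(-t/tau_j)`,
#' `r(t) = sum_i A_i exp(-t/phi_i) + r_inf`, and
#' `I_par = I_tot (1 + 2 r) / 3`, `I_perp = I_tot (1 - r) / 3`.
#' Intensities are zero for `t < 0`.
#'
#' @param model a [photophysics_model()].
#' @param tgrid_ns times (ns).
#' @return List with `time_ns`, `i_par`, `i_perp`, `i_tot`, `r`.
#' @export
ideal_polarized_intensities <- function(model, tgrid_ns) {
  stopifnot(inherits(model, "photophysics_model"))
  t <- as.numeric(tgrid_ns)
  pos <- t >= 0
  itot <- numeric(length(t))
  for (j in seq_len(nrow(model$lifetimes)))
    itot[pos] <- itot[pos] + model$lifetimes$fraction[j] *
      exp(-t[pos] / model$lifetimes$tau_ns[j])
  r <- rep(model$r_inf, length(t))
  for (i in seq_len(nrow(model$anisotropy)))
    r <- r + model$anisotropy$amplitude[i] *
      exp(-pmax(t, 0) / model$anisotropy$phi_ns[i])
  if (any(r <= -0.5) || any(r >= 1))
    stop("anisotropy model leaves the physical range (-0.5, 1)",
         call. = FALSE)
  list(time_ns = t, i_par = itot * (1 + 2 * r) / 3,
       i_perp = itot * (1 - r) / 3, i_tot = itot, r = r)
}

#' Polarized decay constructor
#'
#' @param bin_ps bin-center times (ps).
#' @param i_vv,i_vh nonnegative count histograms (vertical / horizontal
#'   detection channels), equal length.
#' @param bin_width_ps bin width (ps).
#' @param metadata named list (instrument echo, seed, processing flags).
#' @return Object of class `"polarized_decay"`.
#' @export
polarized_decay <- function(bin_ps, i_vv, i_vh, bin_width_ps,
                            metadata = list()) {
  if (length(i_vv) != length(i_vh) || length(i_vv) != length(bin_ps))
    stop("channel and bin-grid lengths differ", call. = FALSE)
  if (any(i_vv < 0) || any(i_vh < 0))
    stop("counts must be nonnegative", call. = FALSE)
  structure(list(bin_ps = as.numeric(bin_ps), i_vv = i_vv, i_vh = i_vh,
                 bin_width_ps = bin_width_ps, metadata = metadata),
            class = "polarized_decay")
}

#' @export
print.polarized_decay <- function(x, ...) {
  cat(sprintf(
    "Polarized decay: %d bins x %g ps; %.3g (VV) + %.3g (VH) counts\n",
    length(x$bin_ps), x$bin_width_ps, sum(x$i_vv), sum(x$i_vh)))
  invisible(x)
}

#' @export
plot.polarized_decay <- function(x, log = "y", ...) {
  plot(x$bin_ps / 1000, pmax(x$i_vh, 0.5), type = "l", log = log,
       xlab = "time (ns)", ylab = "counts", col = "steelblue", ...)
  lines(x$bin_ps / 1000, pmax(x$i_vv, 0.5), col = "firebrick")
  legend("topright", legend = c("VH", "VV"), bty = "n", lty = 1,
         col = c("steelblue", "firebrick"))
  invisible(x)
}

#' Simulate a polarized TCSPC photon-count histogram pair
#'
#' Convolves the ideal polarized intensities with a Gaussian IRF, delays
#' the vertical channel by the inter-channel path difference, applies the
#' detection-efficiency mismatch and neutral-density attenuation to the
#' vertical channel, adds a uniform dark background, and draws independent
#' Poisson counts per bin.  Reproducible per seed.
#'
#' @param model a [photophysics_model()].
#' @param inst an [instrument_model()].
#' @param seed integer seed (required).
#' @return A [polarized_decay()] with the instrument and ground-truth
#'   model echoed in `metadata`.  If the window is shorter than 5 times
#'   the longest lifetime a `truncated` flag is set in the metadata.
#' @examples
#' d <- simulate_decay(cy3_nhs_control(),
#'                     instrument_model(total_counts = 1e5), seed = 1)
#' @export
simulate_decay <- function(model, inst, seed) {
  stopifnot(inherits(model, "photophysics_model"),
            inherits(inst, "instrument_model"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stop_if_not_scalar_pos(inst$total_counts, "total_counts")

  window_ps <- inst$window_ns * 1000
  dt <- min(inst$bin_width_ps / 8, 2)
  t_fine <- seq(dt / 2, window_ps - dt / 2, by = dt)
  t0 <- inst$irf_peak_ns * 1000

  ideal <- ideal_polarized_intensities(model, (t_fine - t0) / 1000)

  sigma <- inst$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  if (sigma > 0) {
    half <- ceiling(5 * sigma / dt)
    kern <- dnorm(seq(-half, half) * dt, sd = sigma)
    kern <- kern / sum(kern)
    smooth <- function(x) {
      y <- convolve(c(numeric(half), x, numeric(half)), rev(kern),
                    type = "filter")
      y[seq_along(x)]
    }
  } else smooth <- identity
  par_c <- smooth(ideal$i_par)
  perp_c <- smooth(ideal$i_perp)

  # vertical channel arrives later by the inter-channel delay
  vv_fine <- approx(t_fine, par_c, xout = t_fine - inst$channel_delay_ps,
                    yleft = 0, rule = 2)$y
  vh_fine <- perp_c

  bin_of <- pmin(floor(t_fine / inst$bin_width_ps) + 1L, inst$n_bins)
  evv <- as.numeric(rowsum(vv_fine, bin_of, reorder = TRUE))
  evh <- as.numeric(rowsum(vh_fine, bin_of, reorder = TRUE))

  evv <- pmax(evv, 0) / (inst$g_true * inst$nd_attenuation)
  evh <- pmax(evh, 0)
  norm <- inst$total_counts / (sum(evv) + sum(evh))
  evv <- evv * norm + inst$background_rate
  evh <- evh * norm + inst$background_rate

  counts <- with_seed(seed, list(vv = rpois(length(evv), evv),
                                 vh = rpois(length(evh), evh)))
  truncated <- inst$window_ns < 5 * max(model$lifetimes$tau_ns)
  if (truncated)
    warning("histogram window shorter than 5x the longest lifetime")
  polarized_decay(tcspc_bin_grid(inst), counts$vv, counts$vh,
                  inst$bin_width_ps,
                  metadata = list(instrument = inst, model = model,
                                  seed = seed, truncated = truncated))
}
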