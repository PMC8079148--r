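test_that("channel alignment recovers injected delays", {
  m <- cy3_nhs_control()
  # zero injected delay -> zero shift
  d0 <- simulate_decay(m, test_instrument(channel_delay_ps = 0), seed = 2)
  expect_equal(align_channels(d0)$metadata$applied_shift_bins, 0)
  # 380 ps at 16 ps bins -> 24 bins (nearest whole bin to 23.75)
  d <- simulate_decay(m, test_instrument(channel_delay_ps = 380), seed = 2)
  expect_equal(align_channels(d)$metadata$applied_shift_bins, 24)
  # invariance to a 10x intensity rescaling of one channel
  d10 <- polarized_decay(d$bin_ps, d$i_vv * 10L, d$i_vh, d$bin_width_ps,
                         d$metadata)
  expect_equal(align_channels(d10)$metadata$applied_shift_bins, 24)
})

test_that("background subtraction estimates the injected level", {
  m <- cy3_nhs_control()
  # background-free: estimated offsets ~ 0
  d0 <- simulate_decay(m, test_instrument(background_rate = 0), seed = 6)
  s0 <- subtract_background(d0)
  expect_lt(max(abs(s0$metadata$background)), 0.3)
  # injected 5 counts/bin over ~80+ pre-rise bins: Poisson s.e. bound
  d5 <- simulate_decay(m, test_instrument(background_rate = 5), seed = 6)
  s5 <- subtract_background(d5)
  for (b in s5$metadata$background)
    expect_lt(abs(b - 5), 3 * sqrt(5 / 80))
  # tail decay rate essentially unchanged by subtraction
  tail_tau <- function(decay) {
    t <- decay$bin_ps / 1000
    sel <- t > 2.2 & t < 2.8
    y <- pmax(as.numeric(decay$i_vh[sel]), 0.5)
    -1 / coef(lm(log(y) ~ t[sel]))[2]
  }
  expect_equal(tail_tau(d0), tail_tau(subtract_background(d0)),
               tolerance = 0.01)
})

test_that("g-factor tail-matching recovers the channel mismatch", {
  # perfectly matched channels and a depolarized tail: g ~ 1
  iso <- photophysics_model(
    data.frame(tau_ns = 1, fraction = 1),
    data.frame(amplitude = 1e-12, phi_ns = 1))
  d <- simulate_decay(iso, instrument_model(
    g_true = 1, nd_attenuation = 1, channel_delay_ps = 0,
    background_rate = 0, total_counts = 5e6), seed = 3)
  g <- estimate_g(d)
  expect_equal(as.numeric(g), 1, tolerance = 0.02)

  # injected mismatch 10 on the free-dye control, median of 20 seeds
  inst <- test_instrument(total_counts = 1e7)
  gs <- sapply(1:20, function(s) {
    dd <- simulate_decay(cy3_nhs_control(), inst, seed = 400 + s)
    as.numeric(estimate_g(subtract_background(align_channels(dd))))
  })
  expect_equal(median(gs), 10, tolerance = 0.02)

  # invariance to the background level after subtraction
  g_hi <- sapply(1:5, function(s) {
    dd <- simulate_decay(cy3_nhs_control(),
                         test_instrument(total_counts = 1e7,
                                         background_rate = 20),
                         seed = 400 + s)
    as.numeric(estimate_g(subtract_background(align_channels(dd))))
  })
  g_lo <- gs[1:5]
  expect_equal(median(g_hi), median(g_lo), tolerance = 0.03)
})

test_that("corrected channels reconstruct from I_tot and r exactly", {
  # Eq 2 / Eq 3 consistency is an algebraic identity on any data
  set.seed(10)
  vv <- runif(200, 50, 5000)
  vh <- runif(200, 50, 5000)
  g <- 7.3
  d <- polarized_decay(seq(8, by = 16, length.out = 200), vv, vh, 16)
  itot <- g * vv + 2 * vh
  r <- (g * vv - vh) / (g * vv + 2 * vh)
  expect_equal(itot * (1 + 2 * r) / 3, g * vv, tolerance = 1e-12)
  expect_equal(itot * (1 - r) / 3, vh, tolerance = 1e-12)
})

test_that("anisotropy trace reproduces the model and masks thin bins", {
  # I_VH = g I_VV everywhere -> r identically zero
  vv <- rep(1000, 300); vh <- rep(3000, 300)
  d <- polarized_decay(seq(8, by = 16, length.out = 300), vv, vh, 16)
  atr <- anisotropy_trace(d, g = 3)
  expect_true(all(abs(atr$r[atr$valid]) < 1e-12))

  # noiseless synthetic channels: r recovered within 0.005 beyond 3 FWHM
  m <- dsrna_free_model()
  inst <- instrument_model(g_true = 1, nd_attenuation = 1,
                           channel_delay_ps = 0, background_rate = 0,
                           total_counts = 1e9)
  dd <- simulate_decay(m, inst, seed = 31)
  atr2 <- anisotropy_trace(dd, g = 1)
  tau_rel <- atr2$time_ns - 1.5
  sel <- atr2$valid & tau_rel > 3 * 0.06 & tau_rel < 6
  r_true <- 0.076 * exp(-tau_rel / 0.34) + 0.304 * exp(-tau_rel / 2.6) +
    0.02
  expect_lt(max(abs(atr2$r[sel] - r_true[sel])), 0.005)

  # low-count bins are masked
  expect_true(all(3 * 1000 + 2 * 0 >= 100))
  dlow <- polarized_decay(d$bin_ps, rep(5, 300), rep(10, 300), 16)
  expect_error(anisotropy_trace(dlow, g = 3), "masked")
})

test_that("r stays within physical bounds on simulated data", {
  inst <- test_instrument(total_counts = 2e6)
  for (s in 1:3) {
    d <- simulate_decay(dsrna_free_model(), inst, seed = 60 + s)
    an <- process_decay(d)
    r <- an$trace$r[an$trace$valid]
    expect_true(all(r > -0.2 & r <= 0.42))
  }
})

test_that("lifetime fit recovers mono- and bi-exponential decays", {
  # free-dye control: tau = 300 ps within 2%
  inst <- test_instrument(total_counts = 1e7)
  d <- simulate_decay(cy3_nhs_control(), inst, seed = 44)
  p <- process_decay(d)
  expect_equal(p$lifetime$n_components, 1)
  expect_equal(p$lifetime$components$tau_ns, 0.3, tolerance = 0.02)

  # bi-exponential dsRNA source at 1e7 counts, both components within 5%
  dd <- simulate_decay(dsrna_free_model(),
                       test_instrument(total_counts = 1e7), seed = 45)
  pp <- process_decay(dd, control = d, n_lifetimes = 2)
  expect_equal(pp$lifetime$components$tau_ns, c(1.21, 2.28),
               tolerance = 0.05)
})

test_that("anisotropy fit: delta_r identity, constant traces, flags", {
  tvec <- seq(8, by = 16, length.out = 400)
  # constant r trace -> no decay phase, delta_r = 0
  vv <- rpois(400, round(3000 * exp(-tvec / 1500)) + 50)
  const <- polarized_decay(tvec, vv, 2 * vv, 16)
  atr <- anisotropy_trace(const, g = 2, min_counts = 50)
  fit <- fit_anisotropy(atr)
  expect_equal(fit$n_phases, 0L)
  expect_equal(fit$delta_r, 0)
  expect_equal(fit$r0, fit$r_inf)

  # delta_r = r0 - r_inf to machine precision on real fits
  d <- simulate_decay(dsrna_free_model(),
                      test_instrument(total_counts = 2e6), seed = 71)
  an <- process_decay(d)
  expect_equal(an$anisotropy$delta_r,
               an$anisotropy$r0 - an$anisotropy$r_inf, tolerance = 1e-12)
})

test_that("full chain recovers the free-dye control photophysics", {
  inst <- test_instrument(total_counts = 1e7)
  res <- t(sapply(1:6, function(s) {
    d <- simulate_decay(cy3_nhs_control(), inst, seed = 500 + s)
    an <- process_decay(d)
    c(tau = an$lifetime$mean_lifetime_ns, r0 = an$anisotropy$r0,
      phi = an$anisotropy$phases$phi_ns[1])
  }))
  expect_equal(median(res[, "tau"]), 0.300, tolerance = 0.02)
  expect_lt(abs(median(res[, "r0"]) - 0.40), 0.02)
  expect_equal(median(res[, "phi"]), 0.44, tolerance = 0.10)
})

test_that("fast-phase refit matches a global single-exponential fit", {
  # pure single-phi decay: windowed refit equals the global fit within se
  inst <- test_instrument(total_counts = 1e7)
  d <- simulate_decay(cy3_nhs_control(), inst, seed = 81)
  dd <- subtract_background(align_channels(d))
  atr <- anisotropy_trace(dd, g = 10)
  glob <- fit_anisotropy(atr, n_phases = 1)
  ref <- refit_fast_phase(atr, window_ns = 3)
  expect_equal(ref$phi_ns, glob$phases$phi_ns[1],
               tolerance = 3 * (ref$se_phi_ns + 1e-3) / ref$phi_ns)
  # window spanning the full decay reproduces the global fit closely
  ref_full <- refit_fast_phase(atr, window_ns = 8)
  expect_equal(ref_full$phi_ns, glob$phases$phi_ns[1], tolerance = 0.05)
  expect_error(refit_fast_phase(atr, window_ns = 0.05), "fewer than 10")
})

test_that("windowed refit resolves the fast correlation time of dsRNA", {
  inst <- test_instrument(total_counts = 1e7)
  phi1 <- sapply(1:8, function(s) {
    d <- simulate_decay(dsrna_free_model(), inst, seed = 700 + s)
    dd <- subtract_background(align_channels(d))
    atr <- anisotropy_trace(dd, g = 10)
    af <- fit_anisotropy(atr, n_phases = 2)
    refit_fast_phase(atr, fit = af)$phi_ns
  })
  expect_equal(median(phi1), 0.34, tolerance = 0.15)
})
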