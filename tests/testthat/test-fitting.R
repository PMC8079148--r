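test_that("trace averaging: identity, symmetry, noise reduction", {
  sch <- kinetic_scheme("translocation", rates = c(k_trans = 0.05))
  tr <- to_trace(simulate_scheme(sch, tgrid = log_tgrid(1e-3, 200, 1500)))
  expect_equal(average_traces(list(tr))$signal, tr$signal)

  delta <- sin(seq_along(tr$time))
  up <- sf_trace(tr$time, tr$signal + 0.1 * delta)
  dn <- sf_trace(tr$time, tr$signal - 0.1 * delta)
  expect_equal(average_traces(list(up, dn))$signal, tr$signal)

  expect_error(average_traces(list()), "empty")
  short <- sf_trace(tr$time[-1], tr$signal[-1])
  expect_error(average_traces(list(tr, short)), "mismatched")

  # averaging 8 replicates shrinks residual sd by ~ sqrt(8)
  one_sd <- mean(sapply(1:10, function(s)
    sd(add_noise(tr, 0.02, seed = s)$signal - tr$signal)))
  avg_sd <- mean(sapply(1:10, function(s) {
    reps <- lapply(1:8, function(i) add_noise(tr, 0.02, seed = s * 50 + i))
    sd(average_traces(reps)$signal - tr$signal)
  }))
  expect_equal(one_sd / avg_sd, sqrt(8), tolerance = 0.2)
})

test_that("normalization fixes the maximum at one and preserves shape", {
  tr <- sf_trace(0:99, 0.42 * exp(-(0:99) / 30))
  nm <- normalize_trace(tr)
  expect_equal(max(nm$signal), 1)
  expect_equal(nm$signal, tr$signal / 0.42)
  expect_equal(normalize_trace(nm)$signal, nm$signal)
  # scale invariance
  sc <- sf_trace(tr$time, 3.7 * tr$signal)
  expect_equal(normalize_trace(sc)$signal, nm$signal)
  expect_error(normalize_trace(sf_trace(1:5, rep(0, 5))), "normalize")
})

test_that("noiseless single exponential recovers the printed half-life", {
  k <- log(2) / 55.5
  t <- log_tgrid(1e-2, 1200, 400)
  tr <- sf_trace(t, 0.8 * exp(-k * t) + 0.2)
  fit <- fit_exponentials(tr, 1)
  expect_equal(fit$phases$t_half, 55.5, tolerance = 1e-6)
  expect_equal(signif(fit$phases$k_obs, 2), 0.012)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
})

test_that("constant trace fits to near-zero amplitude", {
  tr <- sf_trace(seq(0.1, 100, length.out = 200), rep(0.7, 200))
  fit <- fit_exponentials(tr, 1)
  expect_lt(abs(fit$phases$amplitude), 1e-6)
  expect_equal(fit$offset + fit$phases$amplitude *
                 exp(-fit$phases$k_obs * 0.1), 0.7, tolerance = 1e-6)
})

test_that("noiseless biphasic parameters match the grid+polish oracle", {
  t <- log_tgrid(1e-3, 200, 300)
  y <- 0.6 * exp(-1.0 * t) + 0.4 * exp(-0.05 * t) + 0.1
  tr <- sf_trace(t, y)
  fit <- fit_exponentials(tr, 2)
  expect_equal(fit$phases$k_obs, c(1.0, 0.05), tolerance = 1e-6)
  expect_equal(fit$phases$amplitude, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(fit$offset, 0.1, tolerance = 1e-6)
  oracle <- oracle_biexp_fit(t, y)
  expect_equal(fit$phases$k_obs, oracle$k, tolerance = 1e-4)
  expect_equal(fit$phases$amplitude, as.numeric(oracle$A),
               tolerance = 1e-4)
})

test_that("fit agrees with the oracle over random well-separated draws", {
  set.seed(7)
  for (i in 1:8) {
    k2 <- 10^runif(1, -2, -0.5)
    k1 <- k2 * runif(1, 5, 40)
    A <- runif(2, 0.2, 0.8) * sample(c(-1, 1), 2, replace = TRUE)
    off <- runif(1, 0, 0.4)
    t <- log_tgrid(1e-3, 20 * log(2) / k2, 250)
    y <- A[1] * exp(-k1 * t) + A[2] * exp(-k2 * t) + off
    fit <- fit_exponentials(sf_trace(t, y), 2)
    expect_equal(fit$phases$k_obs, c(k1, k2), tolerance = 1e-5)
    expect_equal(fit$phases$amplitude, A, tolerance = 1e-5)
  }
})

test_that("fitted k_obs equals the scheme eigenrates on noiseless traces", {
  # oracle equivalence, eigenvalue ratio >= 5
  sch <- kinetic_scheme("unwind_rewind",
                        rates = c(k_unwind = 1.2, k_rewind = 0.15))
  ev <- observed_eigenrates(sch)
  tr <- to_trace(simulate_scheme(sch))
  fit <- fit_exponentials(tr, 2)
  expect_equal(fit$phases$k_obs, ev, tolerance = 1e-3)
})

test_that("fitted fast-phase k_obs is affine in enzyme concentration", {
  k1 <- 2e6; km1 <- 0.4
  sch <- kinetic_scheme("two_step_binding",
                        rates = c(k1 = k1, k_minus1 = km1,
                                  k2 = 0.01, k_minus2 = 0.002))
  concs <- c(1, 2, 4, 8) * 1e-6
  kfast <- sapply(concs, function(cc) {
    # labeled RNA at 1/50 of enzyme so [E] stays effectively clamped
    init <- c(E = cc, R = 2e-8, C1 = 0, C2 = 0)
    tr <- to_trace(simulate_scheme(sch, init,
                                   tgrid = log_tgrid(1e-4, 400, 1500)))
    fit_exponentials(tr, 2)$phases$k_obs[1]
  })
  co <- coef(lm(kfast ~ concs))
  expect_equal(unname(co[2]), k1, tolerance = 0.01)
  expect_equal(unname(co[1]), km1, tolerance = 0.01)
})

test_that("model selection follows the minimal-phases rule", {
  t <- log_tgrid(1e-3, 300, 2000)
  single <- sf_trace(t, 0.9 * exp(-0.1 * t) + 0.1)
  expect_equal(select_model(add_noise(single, 0.02, seed = 3))$n_phases, 1L)

  # BLT binding with ATPgS: fast 0.8 s and slow 55.5 s phases
  bi <- sf_trace(t, 0.45 * exp(-log(2) / 0.8 * t) +
                   0.45 * exp(-log(2) / 55.5 * t) + 0.1)
  expect_equal(select_model(add_noise(bi, 0.02, seed = 3))$n_phases, 2L)

  # second amplitude only 1% of the total: parsimony keeps one phase
  tiny <- sf_trace(t, 0.89 * exp(-0.1 * t) + 0.009 * exp(-0.005 * t) + 0.1)
  expect_equal(select_model(add_noise(tiny, 0.02, seed = 3))$n_phases, 1L)
})

test_that("half-life conversions match printed values and round trip", {
  expect_equal(signif(kobs_from_halflife(55.5), 2), 0.012)
  expect_equal(signif(kobs_from_halflife(95.9), 1), 0.007)
  expect_equal(kobs_from_halflife(log(2)), 1)
  for (x in c(0.5, 14, 55.5, 346))
    expect_equal(halflife_from_kobs(kobs_from_halflife(x)), x,
                 tolerance = 1e-12)
  expect_error(kobs_from_halflife(0), "positive")
  expect_error(halflife_from_kobs(-2), "positive")
})

test_that("chase-fit off-rates are unbiased over replicate seeds", {
  sch <- blt_chase_scheme()
  tr <- to_trace(simulate_scheme(sch))
  ks <- t(sapply(1:40, function(s) {
    fit_exponentials(add_noise(tr, 0.02, seed = 900 + s), 2)$phases$k_obs
  }))
  expect_equal(median(ks[, 1]), 0.12, tolerance = 0.03)
  expect_equal(median(ks[, 2]), 0.002, tolerance = 0.03)
})

test_that("runs-test p is approximately uniform under a correct model", {
  t <- log_tgrid(1e-2, 100, 300)
  mu <- 0.8 * exp(-0.08 * t) + 0.2
  ps <- sapply(1:300, function(s) {
    tr <- add_noise(sf_trace(t, mu), 0.02, seed = 5000 + s)
    fit_exponentials(tr, 1)$runs_p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("exp_fit methods are coherent", {
  t <- log_tgrid(1e-2, 300, 400)
  tr <- add_noise(sf_trace(t, 0.7 * exp(-0.05 * t) + 0.3), 0.01, seed = 2)
  fit <- fit_exponentials(tr, 1)
  expect_named(coef(fit), c("A1", "k_obs1", "offset"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit), tr$signal)
  expect_equal(fit$phases$t_half * fit$phases$k_obs, log(2),
               tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.exp_fit")
  expect_equal(unname(s$coefficients["k_obs1", "estimate"]),
               fit$phases$k_obs)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$signal, sims[[2]]$signal))
})
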