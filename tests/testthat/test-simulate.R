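test_that("zero rates give constant concentrations", {
  sch <- kinetic_scheme("unwind_rewind", rates = c(k_unwind = 0,
                                                   k_rewind = 0))
  traj <- simulate_scheme(sch, init = c(B = 2e-7, U = 0, W = 0),
                          tgrid = log_tgrid(1e-3, 100, 200))
  expect_true(all(abs(traj$conc[, "B"] - 2e-7) < 1e-18))
  expect_true(all(traj$conc[, c("U", "W")] == 0))
})

test_that("pseudo first-order decay matches the closed form", {
  # irreversible E + R -> C with E in 10-fold excess
  k1 <- 5e5
  sch <- kinetic_scheme("two_step_binding",
                        rates = c(k1 = k1, k_minus1 = 0, k2 = 0,
                                  k_minus2 = 0))
  E0 <- 2e-6; R0 <- 2e-7
  tg <- log_tgrid(1e-3, 10, 500)
  traj <- simulate_scheme(sch, init = c(E = E0, R = R0, C1 = 0, C2 = 0),
                          tgrid = tg)
  # [E] is not constant (falls to 0.9 E0); the exact solution of the
  # bimolecular ODE with unequal totals is the oracle here
  d <- E0 - R0
  exact <- R0 * d / (E0 * exp(k1 * d * tg) - R0)
  expect_equal(traj$conc[, "R"], exact, tolerance = 1e-6,
               ignore_attr = TRUE)
  # and the clamped-[E] exponential approximation holds to first order
  approx_exp <- R0 * exp(-k1 * E0 * tg)
  expect_lt(max(abs(traj$conc[, "R"] - approx_exp)) / R0, 0.06)
})

test_that("slow eigenvalue set to ln2/55.5 yields a 55.5 s slow phase", {
  # choose isomerization rates so the slow relaxation of the two-step
  # scheme equals the printed slow binding phase (t1/2 = 55.5 s)
  k_slow_target <- log(2) / 55.5
  # with fast binding pre-equilibrium (k1[E] = 10, k_minus1 = 1 s^-1) the
  # slow relaxation is k2 * k1[E]/(k1[E]+k_minus1) + k_minus2
  sch <- kinetic_scheme("two_step_binding",
                        rates = c(k1 = 5e6, k_minus1 = 1,
                                  k2 = 0.88 * k_slow_target,
                                  k_minus2 = 0.2 * k_slow_target))
  ev <- observed_eigenrates(sch, excess_conc = 2e-6)
  # rates chosen with fast >> slow; verify the slow eigenvalue landed
  # close, then measure the half-life from the simulated rise
  traj <- simulate_scheme(sch, tgrid = log_tgrid(1e-3, 4000, 3000))
  bound <- traj$conc[, "C1"] + traj$conc[, "C2"]
  eq <- bound[length(bound)]
  slow_t12 <- log(2) / ev[2]
  # time at which the approach to equilibrium is half complete, measured
  # in the slow regime (after the fast phase has equilibrated)
  late <- traj$time > 5
  defect <- (eq - bound[late]) / (eq - bound[late][1])
  ok <- defect > 1e-3
  t_half_measured <- approx(log(defect[ok]), (traj$time[late] - 5)[ok],
                            xout = log(0.5))$y
  expect_equal(log(2) / slow_t12, k_slow_target, tolerance = 0.05)
  expect_equal(t_half_measured, log(2) / ev[2], tolerance = 0.03)
})

test_that("integration rejects bad inputs", {
  sch <- kinetic_scheme("translocation", rates = c(k_trans = 0.05))
  expect_error(simulate_scheme(sch, init = c(B = -1e-7, A = 0)),
               "nonnegative")
  expect_error(simulate_scheme(sch, init = c(B = 2e-7, A = 0),
                               tgrid = c(1, 1, 2)), "increasing")
})

test_that("observable projection normalizes and preserves shape", {
  sch <- kinetic_scheme("translocation", rates = c(k_trans = 0.05))
  traj <- simulate_scheme(sch)
  tr <- to_trace(traj)
  expect_equal(max(tr$signal), 1)
  # constant trajectory -> constant unit signal
  sch0 <- kinetic_scheme("translocation", rates = c(k_trans = 0))
  tr0 <- to_trace(simulate_scheme(sch0, tgrid = log_tgrid(1e-3, 10, 100)))
  expect_true(all(abs(tr0$signal - 1) < 1e-9))
  expect_error(to_trace(traj, observable_map("pife", c(B = 1))),
               "lacks coefficients")
})

test_that("unwind/rewind FRET trace dips once and recovers", {
  sch <- kinetic_scheme("unwind_rewind",
                        rates = c(k_unwind = log(2) / 0.5,
                                  k_rewind = log(2) / 2.5))
  tr <- to_trace(simulate_scheme(sch, tgrid = log_tgrid(1e-3, 60, 4000)))
  s <- tr$signal
  i_min <- which.min(s)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(s))
  # single interior minimum: signal decreases before it, increases after
  expect_true(all(diff(s[1:i_min]) < 1e-12))
  expect_true(all(diff(s[i_min:length(s)]) > -1e-12))
  # dip depth is set by the species populations, checked on a dense grid
  expect_lt(min(s), 0.9)
})

test_that("cleavage/release FRET trace rises then decays toward offset", {
  sch <- kinetic_scheme("cleavage_release",
                        rates = c(k_arrive = log(2) / 14,
                                  k_cleave = log(2) / 43.2))
  tr <- to_trace(simulate_scheme(sch))
  s <- tr$signal
  i_max <- which.max(s)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(s))
  expect_gt(s[i_max], s[1])
  expect_lt(s[length(s)], 0.5 * s[i_max])  # slow loss of signal
})

test_that("noise is reproducible, seed-dependent, and correctly scaled", {
  sch <- kinetic_scheme("translocation", rates = c(k_trans = 0.05))
  tr <- to_trace(simulate_scheme(sch, tgrid = log_tgrid(1e-3, 200, 10000)))
  expect_identical(add_noise(tr, 0.02, seed = 7)$signal,
                   add_noise(tr, 0.02, seed = 7)$signal)
  expect_false(identical(add_noise(tr, 0.02, seed = 7)$signal,
                         add_noise(tr, 0.02, seed = 8)$signal))
  expect_identical(add_noise(tr, 0, seed = 7)$signal, tr$signal)
  res <- add_noise(tr, 0.02, seed = 11)$signal - tr$signal
  # chi-square bounds on the sample sd of 1e4 Gaussian draws
  expect_gt(sd(res), 0.019)
  expect_lt(sd(res), 0.021)
})

test_that("noisy generation leaves the global RNG state untouched", {
  sch <- kinetic_scheme("translocation", rates = c(k_trans = 0.05))
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_sf_trace(sch, seed = 5))
  expect_identical(.Random.seed, before)
})
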