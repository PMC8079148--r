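# shared fixtures, built in code

ln2 <- log(2)

blt_chase_scheme <- function() {
  kinetic_scheme("dissociation_chase",
                 rates = c(k_minus1 = 0.12, k_minus2 = 0.002))
}

ovr_chase_scheme <- function() {
  kinetic_scheme("dissociation_chase",
                 rates = c(k_minus1 = 0.28, k_minus2 = 0.008))
}

# small, fast instrument for TCSPC tests that do not need 1e7 counts
test_instrument <- function(total_counts = 2e6, background_rate = 2,
                            g_true = 1, nd_attenuation = 10, ...) {
  instrument_model(total_counts = total_counts,
                   background_rate = background_rate,
                   g_true = g_true, nd_attenuation = nd_attenuation, ...)
}

# independent oracle for multi-exponential least squares: dense log-grid
# search over rates with linear amplitude solve, then Nelder-Mead polish
# (no Levenberg-Marquardt, no shared code with the package internals)
oracle_biexp_fit <- function(t, y, n_grid = 40) {
  grid <- exp(seq(log(1 / (10 * max(t))), log(2 / min(t[t > 0])),
                  length.out = n_grid))
  rss_of <- function(k1, k2) {
    X <- cbind(exp(-k1 * t), exp(-k2 * t), 1)
    f <- lm.fit(X, y)
    sum(f$residuals^2)
  }
  best <- c(Inf, NA, NA)
  for (i in seq_along(grid)) for (j in seq_len(i - 1)) {
    r <- rss_of(grid[i], grid[j])
    if (r < best[1]) best <- c(r, grid[i], grid[j])
  }
  obj <- function(p) rss_of(exp(p[1]), exp(p[2]))
  opt <- optim(log(best[2:3]), obj, control = list(reltol = 1e-14,
                                                   maxit = 5000))
  k <- sort(exp(opt$par), decreasing = TRUE)
  X <- cbind(exp(-k[1] * t), exp(-k[2] * t), 1)
  cf <- lm.fit(X, y)$coefficients
  list(k = k, A = cf[1:2], offset = cf[3], rss = opt$value)
}
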