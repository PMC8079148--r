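# Multi-exponential least squares:  y = sum_i A_i exp(-k_i t) + c
#
# Strategy: variable-projection grid seeding (rates on a log grid, amplitudes
# and offset solved linearly), then Levenberg-Marquardt polish of the full
# parameter set with rates log-parameterized to stay positive.  Amplitudes
# are unconstrained and signed, so rising phases carry negative amplitudes.

.exp_model <- function(t, A, k, c) {
  as.numeric(exp(-outer(t, k)) %*% A) + c
}

# linear solve for (A, c) at fixed rates; returns list(A, c, rss) or NULL
.varpro_solve <- function(t, y, k, w) {
  X <- cbind(exp(-outer(t, k)), 1)
  fit <- try(lm.wfit(X, y, w), silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(fit$coefficients)))
    return(NULL)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  res <- y - X %*% cf
  list(A = unname(cf[seq_along(k)]), c = unname(cf[length(k) + 1L]),
       rss = sum(w * res^2))
}

# core fitter; t >= 0, length(t) == length(y); weights default 1
.fit_multiexp <- function(t, y, n_phases, weights = NULL, init = NULL,
                          n_restarts = 5L) {
  n <- length(t)
  w <- weights %||% rep(1, n)

  tpos <- t[t > 0]
  span_lo <- 1 / (20 * max(t))
  span_hi <- 5 / max(min(tpos), 1e-12)
  grid <- exp(seq(log(span_lo), log(span_hi), length.out = 24))

  seeds <- list()
  if (!is.null(init)) seeds[[1]] <- log(init$k)
  if (n_phases == 1L) {
    rss <- vapply(grid, function(k) {
      s <- .varpro_solve(t, y, k, w); if (is.null(s)) Inf else s$rss
    }, numeric(1))
    best <- order(rss)[seq_len(min(n_restarts, length(grid)))]
    seeds <- c(seeds, lapply(grid[best], log))
  } else {
    pairs <- expand.grid(i = seq_along(grid), j = seq_along(grid))
    pairs <- pairs[pairs$i < pairs$j, ]
    rss <- apply(pairs, 1, function(p) {
      s <- .varpro_solve(t, y, grid[c(p[["j"]], p[["i"]])], w)
      if (is.null(s)) Inf else s$rss
    })
    best <- order(rss)[seq_len(min(n_restarts, nrow(pairs)))]
    seeds <- c(seeds, lapply(best, function(b)
      log(grid[c(pairs$j[b], pairs$i[b])])))
  }

  resid_fn <- function(par) {
    k <- exp(par[seq_len(n_phases)])
    A <- par[n_phases + seq_len(n_phases)]
    c0 <- par[2 * n_phases + 1L]
    sqrt(w) * (y - .exp_model(t, A, k, c0))
  }

  best_fit <- NULL
  for (lk in seeds) {
    s <- .varpro_solve(t, y, exp(lk), w)
    if (is.null(s)) next
    par0 <- c(lk, s$A, s$c)
    fit <- try(minpack.lm::nls.lm(par = par0, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-14,
                                    ptol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best_fit) || fit$deviance < best_fit$deviance) best_fit <- fit
  }
  if (is.null(best_fit))
    stop("exponential fit failed to converge from any start", call. = FALSE)

  par <- unname(best_fit$par)
  k <- exp(par[seq_len(n_phases)])
  A <- par[n_phases + seq_len(n_phases)]
  c0 <- par[2 * n_phases + 1L]

  # order phases fast -> slow
  o <- order(k, decreasing = TRUE)
  k <- k[o]; A <- A[o]

  # standard errors from the Jacobian of the (A, k, c) parameterization
  X <- exp(-outer(t, k))
  J <- cbind(X, -X * outer(t, rep(1, n_phases)) * rep(A, each = n),
             rep(1, n))  # d/dA, d/dk, d/dc
  J <- J * sqrt(w)
  rss <- best_fit$deviance
  dof <- max(n - (2 * n_phases + 1L), 1L)
  s2 <- rss / dof
  cov <- try(solve(crossprod(J)) * s2, silent = TRUE)
  se <- if (inherits(cov, "try-error")) rep(NA_real_, ncol(J))
        else sqrt(pmax(diag(cov), 0))

  list(k = k, A = A, offset = c0, rss = rss, dof = dof,
       se_A = se[seq_len(n_phases)],
       se_k = se[n_phases + seq_len(n_phases)],
       se_offset = se[2 * n_phases + 1L],
       fitted = .exp_model(t, A, k, c0),
       converged = best_fit$info %in% 1:4)
}

# Wald-Wolfowitz runs test on residual signs (two-sided, normal
# approximation with continuity correction); returns a p-value.
runs_test_p <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  nn <- n1 + n2
  mu <- 2 * n1 * n2 / nn + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  if (v <= 0) return(1)
  z <- (abs(runs - mu) - 0.5) / sqrt(v)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Fit single or double exponential rate equations to a trace
#'
#' Least-squares fit of `RFU = sum_i A_i exp(-k_obs_i t) + offset` with one
#' or two phases, by Levenberg-Marquardt iteration seeded from a log-spaced
#' rate grid (amplitudes and offset solved linearly at each grid point,
#' then the best five starts polished).  Rates are log-parameterized so
#' `k_obs > 0`; amplitudes are signed, so a rising phase has `A < 0` in the
#' model and is reported as an amplitude of change.
#'
#' @param trace an [sf_trace()] (or anything with `time` and `signal`).
#' @param n_phases 1 or 2.
#' @param init optional list with element `k` (vector of starting rates).
#' @param sigma known noise standard deviation (RFU) for the reduced
#'   chi-square; if `NULL`, estimated from first differences of the signal
#'   (`sd(diff(signal)) / sqrt(2)`).
#' @return Object of class `"exp_fit"` with components `phases` (data frame
#'   of `amplitude`, `k_obs`, `t_half`, and standard errors, sorted fast to
#'   slow), `offset`, `chi2_red`, `runs_p`, `fitted`, `residuals`.
#' @seealso [select_model()] for automatic choice of the number of phases.
#' @examples
#' sch <- kinetic_scheme("translocation", rates = c(k_trans = log(2) / 14))
#' tr <- simulate_sf_trace(sch, seed = 1)
#' fit <- fit_exponentials(tr, n_phases = 1)
#' coef(fit)
#' @export
fit_exponentials <- function(trace, n_phases = 1, init = NULL, sigma = NULL) {
  t <- trace$time; y <- trace$signal
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% 1:2) stop("n_phases must be 1 or 2", call. = FALSE)
  if (length(t) < 5 * (2 * n_phases + 1))
    stop("too few points: need at least 5 per free parameter", call. = FALSE)

  f <- .fit_multiexp(t, y, n_phases, init = init)
  if (!f$converged)
    warning("Levenberg-Marquardt did not report clean convergence; ",
            "returning best parameters found")

  sig <- sigma %||% max(sd(diff(y)) / sqrt(2), 1e-12)
  res <- y - f$fitted
  phases <- data.frame(
    amplitude = f$A, k_obs = f$k, t_half = log(2) / f$k,
    se_amplitude = f$se_A, se_k_obs = f$se_k)

  structure(list(
    phases = phases, offset = f$offset, se_offset = f$se_offset,
    n_phases = n_phases, sigma = sig,
    chi2_red = f$rss / f$dof / sig^2,
    runs_p = runs_test_p(res),
    rss = f$rss, dof = f$dof, n = length(t),
    fitted.values = f$fitted, residuals = res,
    time = t, signal = y, metadata = trace$metadata,
    converged = f$converged, call = match.call()),
    class = "exp_fit")
}

.aicc <- function(fit) {
  p <- 2 * fit$n_phases + 1
  n <- fit$n
  n * log(fit$rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

#' Choose the minimal number of exponential phases
#'
#' Fits one- and two-phase rate equations and keeps the biphasic fit only
#' when it is decisively better: corrected-AIC improvement > `delta_aicc`,
#' both amplitudes at least `min_amp_frac` of the total amplitude, and rate
#' separation `k_1/k_2 >= min_ratio`.  Ties default to fewer phases
#' (parsimony, the minimum-number-of-terms convention).
#'
#' @inheritParams fit_exponentials
#' @param delta_aicc required corrected-AIC improvement (default 10).
#' @param min_amp_frac minimum fraction of total absolute amplitude per
#'   phase (default 0.05).
#' @param min_ratio minimum fast/slow rate ratio (default 3).
#' @return The selected `"exp_fit"`.
#' @export
select_model <- function(trace, sigma = NULL, delta_aicc = 10,
                         min_amp_frac = 0.05, min_ratio = 3) {
  f1 <- fit_exponentials(trace, 1, sigma = sigma)
  # the trial two-phase fit is legitimately degenerate on one-phase data;
  # its convergence warnings are not informative here
  f2 <- try(suppressWarnings(fit_exponentials(trace, 2, sigma = sigma)),
            silent = TRUE)
  if (inherits(f2, "try-error")) return(f1)
  amp <- abs(f2$phases$amplitude)
  ok <- (.aicc(f1) - .aicc(f2)) > delta_aicc &&
    all(amp >= min_amp_frac * sum(amp)) &&
    f2$phases$k_obs[1] / f2$phases$k_obs[2] >= min_ratio
  if (ok) f2 else f1
}

#' Convert between half-life and observed rate constant
#'
#' `k_obs = ln(2) / t_half`, with `ln 2` at full precision internally; the
#' common printed "0.693" is a display convention.  Use [signif()] on the
#' result to reproduce reported significant-figure values.
#'
#' @param t_half half-life (s), positive.
#' @param k_obs observed rate constant (s^-1), positive.
#' @return The converted value.
#' @examples
#' signif(kobs_from_halflife(55.5), 2)  # 0.012 s^-1
#' @export
kobs_from_halflife <- function(t_half) {
  if (any(t_half <= 0)) stop("t_half must be positive", call. = FALSE)
  log(2) / t_half
}

#' @rdname kobs_from_halflife
#' @export
halflife_from_kobs <- function(k_obs) {
  if (any(k_obs <= 0)) stop("k_obs must be positive", call. = FALSE)
  log(2) / k_obs
}

#' Average replicate stopped-flow traces
#'
#' Pointwise mean of replicate traces recorded on identical time grids;
#' the replicate count is recorded in the metadata (conditions are
#' typically averaged over 4-10 collected traces).
#'
#' @param traces list of [sf_trace()] objects with identical time grids.
#' @return The averaged `"sf_trace"`.
#' @export
average_traces <- function(traces) {
  if (!length(traces)) stop("empty trace list", call. = FALSE)
  t0 <- traces[[1]]$time
  for (tr in traces)
    if (length(tr$time) != length(t0) || any(tr$time != t0))
      stop("traces have mismatched time grids", call. = FALSE)
  sig <- rowMeans(vapply(traces, function(tr) tr$signal,
                         numeric(length(t0))))
  meta <- modifyList(traces[[1]]$metadata, list(n_replicates = length(traces)))
  sf_trace(t0, sig, meta)
}

#' Normalize a trace to unit maximum
#'
#' Divides the signal by its maximum so `max(signal) = 1`; ratios of any
#' two points are preserved.
#'
#' @param trace an [sf_trace()].
#' @return The normalized `"sf_trace"`.
#' @export
normalize_trace <- function(trace) {
  m <- max(trace$signal)
  if (m <= 0) stop("cannot normalize: maximum signal is not positive",
                   call. = FALSE)
  sf_trace(trace$time, trace$signal / m,
           modifyList(trace$metadata, list(normalized = TRUE)))
}
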