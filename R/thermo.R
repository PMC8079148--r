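#' Thermodynamic constants for Eyring analysis
#'
#' Defaults are the low-precision printed conventions used in transient
#' kinetics reports: gas constant R = 1.986 cal K^-1 mol^-1, Planck
#' constant h = 1.58e-34 cal s, Boltzmann constant k_B = 3.3e-24 cal K^-1,
#' and T = 298.15 K (assays at 25 C).  A `"codata"` preset gives the exact
#' SI-derived values (1 cal = 4.184 J).
#'
#' @param R gas constant (cal K^-1 mol^-1).
#' @param h Planck constant (cal s).
#' @param k_B Boltzmann constant (cal K^-1).
#' @param T temperature (K).
#' @param preset `"printed"` (default) or `"codata"`.
#' @return Object of class `"thermo_constants"`.
#' @export
thermo_constants <- function(R = 1.986, h = 1.58e-34, k_B = 3.3e-24,
                             T = 298.15, preset = c("printed", "codata")) {
  preset <- match.arg(preset)
  if (preset == "codata") {
    R <- 8.31446261815324 / 4.184
    h <- 6.62607015e-34 / 4.184
    k_B <- 1.380649e-23 / 4.184
  }
  for (v in c(R = R, h = h, k_B = k_B, T = T))
    if (!is.numeric(v) || v <= 0) stop("all constants must be positive",
                                       call. = FALSE)
  structure(list(R = R, h = h, k_B = k_B, T = T, preset = preset),
            class = "thermo_constants")
}

#' Residence time of a bound complex
#'
#' The half-life of the complex given the slow dissociation off-rate:
#' `t_res = ln(2) / k_off_slow`.
#'
#' @param k_off_slow slow-phase dissociation rate constant (s^-1).
#' @return Residence time (s).
#' @examples
#' residence_time(0.002)  # 346.6 s (the 0.693 display convention gives 346)
#' @export
residence_time <- function(k_off_slow) {
  if (any(k_off_slow <= 0)) stop("k_off_slow must be positive", call. = FALSE)
  log(2) / k_off_slow
}

#' Eyring activation free energy of dissociation
#'
#' `dG^± = -R T ln(k_off h / (k_B T))`, reported in kcal/mol.
#'
#' @param k_off off-rate constant (s^-1), positive; vectorized.
#' @param constants a [thermo_constants()].
#' @return Activation free energy (kcal/mol), with the constants attached
#'   as an attribute.
#' @examples
#' eyring_dg(0.12)  # about 18.7 kcal/mol with the printed constants
#' @export
eyring_dg <- function(k_off, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (any(k_off <= 0)) stop("k_off must be positive", call. = FALSE)
  dg <- -constants$R * constants$T *
    log(k_off * constants$h / (constants$k_B * constants$T)) / 1000
  structure(dg, constants = constants)
}

#' Difference in activation free energy between two off-rates
#'
#' `dG(a) - dG(b) = R T ln(k_off_b / k_off_a)`; depends only on the rate
#' ratio.
#'
#' @param k_off_a,k_off_b off-rates (s^-1), positive.
#' @inheritParams eyring_dg
#' @return Difference (kcal/mol).
#' @export
delta_delta_g <- function(k_off_a, k_off_b, constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  if (any(k_off_a <= 0) || any(k_off_b <= 0))
    stop("off-rates must be positive", call. = FALSE)
  constants$R * constants$T * log(k_off_b / k_off_a) / 1000
}

#' Kinetically determined two-step dissociation constant
#'
#' Apparent K_d of the two-step mechanism E + R <-> C1 <-> C2:
#' `Kd_app = (k_minus1 / k1) * k_minus2 / (k2 + k_minus2)`.
#' Isomerization can only tighten binding, so `Kd_app <= k_minus1 / k1`.
#'
#' @param k1 bimolecular on-rate (M^-1 s^-1), positive.
#' @param k_minus1 encounter-complex off-rate (s^-1), nonnegative.
#' @param k2,k_minus2 forward and reverse isomerization rates (s^-1),
#'   nonnegative with `k2 + k_minus2 > 0`.
#' @return Object of class `"two_step_kd"` with element `kd_app` (M).
#' @examples
#' two_step_kd(1e6, 0.12, 0.01, 0.002)
#' @export
two_step_kd <- function(k1, k_minus1, k2, k_minus2) {
  stop_if_not_scalar_pos(k1, "k1")
  for (nm in c("k_minus1", "k2", "k_minus2"))
    stop_if_not_scalar_pos(get(nm), nm, allow_zero = TRUE)
  if (k2 + k_minus2 <= 0) stop("k2 + k_minus2 must be positive", call. = FALSE)
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
                 kd_app = (k_minus1 / k1) * k_minus2 / (k2 + k_minus2)),
            class = "two_step_kd")
}

#' @export
print.two_step_kd <- function(x, digits = 3, ...) {
  cat(sprintf("Two-step apparent Kd: %s M (single-step Kd %s M)\n",
              signif(x$kd_app, digits), signif(x$k_minus1 / x$k1, digits)))
  invisible(x)
}

#' Catalytic-cycle summary table
#'
#' Tabulates per-step half-lives for blunt (BLT) and 2-nt 3' overhang
#' (3ovr) dsRNA termini, computes the 3ovr : BLT fold ratio for each step,
#' and labels the step with the largest half-life as rate-limiting.
#'
#' @param t_half data frame with columns `step` (character), `termini`
#'   (`"BLT"` or `"3ovr"`) and `t_half` (s); or a named list of
#'   `"exp_fit"` records via [cycle_table_from_fits()].
#' @param required optional character vector of step names that must be
#'   present; missing ones are reported by name.
#' @return Object of class `"cycle_summary"`: a data frame of `step`,
#'   `t_half_blt`, `t_half_3ovr`, `fold_ratio`, with the rate-limiting
#'   step as attribute `rate_limiting`.
#' @examples
#' tab <- data.frame(
#'   step = rep(c("unwinding", "cleavage/release"), each = 2),
#'   termini = rep(c("BLT", "3ovr"), 2),
#'   t_half = c(0.5, 1.0, 43.2, 83.8))
#' summarize_cycle(tab)
#' @export
summarize_cycle <- function(t_half, required = NULL) {
  stopifnot(is.data.frame(t_half),
            all(c("step", "termini", "t_half") %in% names(t_half)))
  if (!all(t_half$termini %in% c("BLT", "3ovr")))
    stop("termini must be 'BLT' or '3ovr'", call. = FALSE)
  if (!is.null(required)) {
    missing_steps <- setdiff(required, t_half$step)
    if (length(missing_steps))
      stop("missing required steps: ", paste(missing_steps, collapse = ", "),
           call. = FALSE)
  }
  steps <- unique(t_half$step)
  pick <- function(st, te) {
    v <- t_half$t_half[t_half$step == st & t_half$termini == te]
    if (length(v)) v[1] else NA_real_
  }
  out <- data.frame(
    step = steps,
    t_half_blt = vapply(steps, pick, numeric(1), te = "BLT"),
    t_half_3ovr = vapply(steps, pick, numeric(1), te = "3ovr"))
  out$fold_ratio <- out$t_half_3ovr / out$t_half_blt
  slowest <- max(c(out$t_half_blt, out$t_half_3ovr), na.rm = TRUE)
  rl <- out$step[which(out$t_half_blt == slowest | out$t_half_3ovr == slowest)]
  structure(out, rate_limiting = rl[1], class = c("cycle_summary",
                                                  "data.frame"))
}

#' Assemble a cycle table from exponential fits
#'
#' @param fits named list; names are `"step|termini"` (e.g.
#'   `"cleavage/release|BLT"`), values are `"exp_fit"` objects.
#' @param phase which phase's half-life to tabulate per entry: `"slow"`
#'   (default, the last phase) or `"fast"` (the first).
#' @return Data frame suitable for [summarize_cycle()].
#' @export
cycle_table_from_fits <- function(fits, phase = c("slow", "fast")) {
  phase <- match.arg(phase)
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("fit names must be 'step|termini': ", nm, call. = FALSE)
    f <- fits[[nm]]
    stopifnot(inherits(f, "exp_fit"))
    th <- if (phase == "slow") f$phases$t_half[f$n_phases]
          else f$phases$t_half[1]
    data.frame(step = parts[1], termini = parts[2], t_half = th)
  })
  do.call(rbind, rows)
}

#' @export
print.cycle_summary <- function(x, digits = 3, ...) {
  cat("Catalytic-cycle kinetic summary (half-lives in s)\n")
  df <- as.data.frame(x)
  df$t_half_blt <- signif(df$t_half_blt, digits)
  df$t_half_3ovr <- signif(df$t_half_3ovr, digits)
  df$fold_ratio <- signif(df$fold_ratio, digits)
  print.data.frame(df, row.names = FALSE)
  cat("rate-limiting step:", attr(x, "rate_limiting"), "\n")
  invisible(x)
}
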