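#' Write / read a stopped-flow trace as CSV
#'
#' Two numeric columns `time_s,signal_rfu` preceded by `#`-prefixed
#' metadata header lines (`# key: value`).  The round trip is stable up to
#' float formatting.
#'
#' @param trace an [sf_trace()].
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns an `"sf_trace"`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- trace$metadata
  scalars <- vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))
  for (nm in names(meta)[scalars])
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  writeLines("time_s,signal_rfu", con)
  writeLines(sprintf("%.12g,%.12g", trace$time, trace$signal), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else val
  }
  body <- lines[!is_meta]
  if (length(body) && grepl("time", body[1], ignore.case = TRUE))
    body <- body[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  vals <- suppressWarnings(
    lapply(parts, function(p) as.numeric(p[1:2])))
  bad <- union(bad, which(vapply(vals, anyNA, logical(1))))
  if (length(bad)) {
    lineno <- which(!is_meta)[-1][bad]  # account for header row
    stop("non-numeric or malformed rows at line(s): ",
         paste(lineno, collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (any(diff(m[, 1]) <= 0)) {
    off <- which(diff(m[, 1]) <= 0)[1] + 1L
    stop("time column not strictly increasing at data row ", off,
         call. = FALSE)
  }
  sf_trace(m[, 1], m[, 2], meta)
}

#' Write / read a polarized decay as 2-column ASCII
#'
#' Each channel is stored as a tab-separated `bin_ps<TAB>counts` file
#' (`vv.txt`, `vh.txt`) plus a JSON sidecar `metadata.json` with the
#' instrument ground truth, mirroring the ASCII export of TCSPC modules.
#' Integer counts are preserved exactly.
#'
#' @param decay a [polarized_decay()].
#' @param dir directory (created if missing).
#' @return `write_tcspc_ascii` returns `dir` invisibly; `read_tcspc_ascii`
#'   returns a `"polarized_decay"`.
#' @export
write_tcspc_ascii <- function(decay, dir) {
  stopifnot(inherits(decay, "polarized_decay"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wchan <- function(x, f)
    writeLines(sprintf("%.6g\t%.10g", decay$bin_ps, x), file.path(dir, f))
  wchan(decay$i_vv, "vv.txt")
  wchan(decay$i_vh, "vh.txt")
  meta <- decay$metadata
  meta$bin_width_ps <- decay$bin_width_ps
  meta$instrument <- if (!is.null(meta$instrument))
    unclass(meta$instrument)
  meta$model <- if (!is.null(meta$model)) {
    m <- unclass(meta$model)
    m
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_tcspc_ascii
#' @export
read_tcspc_ascii <- function(dir) {
  rchan <- function(f) {
    m <- as.matrix(read.csv(file.path(dir, f), sep = "\t", header = FALSE))
    list(bins = m[, 1], counts = m[, 2])
  }
  vv <- rchan("vv.txt")
  vh <- rchan("vh.txt")
  if (length(vv$bins) != length(vh$bins) ||
      any(abs(vv$bins - vh$bins) > 1e-9))
    stop("channel bin grids do not match", call. = FALSE)
  frac <- function(x) any(abs(x - round(x)) > 1e-9)
  if (frac(vv$counts) || frac(vh$counts))
    stop("fractional counts in raw channel files", call. = FALSE)
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  bw <- meta$bin_width_ps %||% diff(vv$bins[1:2])
  meta$bin_width_ps <- NULL
  polarized_decay(vv$bins, as.integer(round(vv$counts)),
                  as.integer(round(vh$counts)), bw, metadata = meta)
}

# -- workflow runner ---------------------------------------------------------

.config_scheme <- function(cfg) {
  kinetic_scheme(cfg$scheme, rates = unlist(cfg$rates),
                 options = cfg$options %||% list())
}

#' Run a named analysis workflow from a config
#'
#' Wires the package's stages into the three experiment workflows.
#' `config` is a named list (or path to a JSON file) with a `workflow`
#' field and workflow-specific parameters; every stochastic workflow
#' requires an explicit `seed`.  Supported workflows:
#'
#' * `"simulate_sf"`: scheme name, `rates` (named, s^-1 or M^-1 s^-1),
#'   optional `init`, `sigma`, `seed`, `out` (trace CSV path).
#' * `"fit_sf"`: `trace` (CSV path) or inline trace, optional `n_phases`
#'   (absent = minimal-terms selection), optional `out` (JSON path).
#' * `"derive"`: `k_off_fast`, `k_off_slow` and/or two-step rates; returns
#'   residence time, Eyring activation energies, apparent Kd.
#' * `"simulate_tcspc"`: `model` (`"cy3_nhs"` or `"dsrna_free"`),
#'   instrument overrides, `seed`, `out` (directory).
#' * `"anisotropy"`: `dir` (sample ASCII directory), optional
#'   `control_dir`; runs the full chain.
#' * `"cycle_report"`: `table` (data frame / list with step, termini,
#'   t_half); returns the cycle summary.
#'
#' @param config named list or path to a JSON config.
#' @return Object of class `"result_report"`: `workflow`, `results`, and
#'   a `provenance` block (full config echo, seed, package version) that
#'   suffices to regenerate the report.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$workflow))
  wf <- match.arg(config$workflow,
                  c("simulate_sf", "fit_sf", "derive", "simulate_tcspc",
                    "anisotropy", "cycle_report"))
  results <- switch(wf,
    simulate_sf = {
      if (is.null(config$seed)) stop("simulate_sf requires a seed",
                                     call. = FALSE)
      sch <- .config_scheme(config)
      init <- if (!is.null(config$init)) unlist(config$init)
              else default_init(sch)
      tr <- simulate_sf_trace(sch, seed = config$seed,
                              sigma = config$sigma %||% 0.02, init = init)
      if (!is.null(config$out)) write_trace_csv(tr, config$out)
      list(trace = as.data.frame(tr), metadata = tr$metadata)
    },
    fit_sf = {
      tr <- if (is.character(config$trace)) read_trace_csv(config$trace)
            else sf_trace(config$trace$time_s, config$trace$signal_rfu)
      fit <- if (is.null(config$n_phases)) select_model(tr)
             else fit_exponentials(tr, config$n_phases)
      rec <- list(n_phases = fit$n_phases,
                  phases = fit$phases,
                  offset = fit$offset, chi2_red = fit$chi2_red,
                  runs_p = fit$runs_p)
      if (!is.null(config$out))
        jsonlite::write_json(rec, config$out, auto_unbox = TRUE,
                             digits = NA, dataframe = "rows")
      rec
    },
    derive = {
      out <- list()
      if (!is.null(config$k_off_slow)) {
        out$residence_time_s <- residence_time(config$k_off_slow)
        out$dg_slow_kcal <- as.numeric(eyring_dg(config$k_off_slow))
      }
      if (!is.null(config$k_off_fast))
        out$dg_fast_kcal <- as.numeric(eyring_dg(config$k_off_fast))
      if (!is.null(config$rates) &&
          all(c("k1", "k_minus1", "k2", "k_minus2") %in%
                names(config$rates))) {
        r <- config$rates
        out$kd_app_M <- two_step_kd(r$k1, r$k_minus1, r$k2,
                                    r$k_minus2)$kd_app
      }
      out
    },
    simulate_tcspc = {
      if (is.null(config$seed)) stop("simulate_tcspc requires a seed",
                                     call. = FALSE)
      model <- switch(config$model %||% "cy3_nhs",
                      cy3_nhs = cy3_nhs_control(),
                      dsrna_free = dsrna_free_model())
      inst_args <- config$instrument %||% list()
      inst <- do.call(instrument_model, inst_args)
      d <- simulate_decay(model, inst, seed = config$seed)
      if (!is.null(config$out)) write_tcspc_ascii(d, config$out)
      list(total_vv = sum(d$i_vv), total_vh = sum(d$i_vh),
           n_bins = length(d$bin_ps))
    },
    anisotropy = {
      d <- read_tcspc_ascii(config$dir)
      ctrl <- if (!is.null(config$control_dir))
        read_tcspc_ascii(config$control_dir)
      an <- process_decay(d, control = ctrl)
      list(g = an$g,
           lifetime = an$lifetime$components,
           mean_lifetime_ns = an$lifetime$mean_lifetime_ns,
           anisotropy = an$anisotropy$phases,
           r0 = an$anisotropy$r0, r_inf = an$anisotropy$r_inf,
           delta_r = an$anisotropy$delta_r,
           fast_refit = if (!is.null(an$fast_refit))
             list(phi_ns = an$fast_refit$phi_ns,
                  amplitude = an$fast_refit$amplitude))
    },
    cycle_report = {
      tab <- as.data.frame(config$table)
      cs <- summarize_cycle(tab, required = config$required)
      list(summary = as.data.frame(cs),
           rate_limiting = attr(cs, "rate_limiting"))
    })

  report <- structure(list(
    workflow = wf, results = results,
    provenance = list(config = config, seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("transkin")))),
    class = "result_report")
  if (!is.null(config$report_out))
    jsonlite::write_json(unclass(report), config$report_out,
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", force = TRUE)
  report
}

#' @export
print.result_report <- function(x, ...) {
  cat("Workflow:", x$workflow, "\n")
  utils::str(x$results, max.level = 2, give.attr = FALSE)
  invisible(x)
}
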