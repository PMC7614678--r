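#' Load and validate a run configuration
#'
#' Reads a structured key-value configuration (JSON or YAML; the format is
#' chosen by trying JSON first, then YAML) describing one sample-size run:
#' \preformatted{
#' scenario: config3_RWI          # exactly one of: builtin label,
#' summaries: sources.csv         #   CSV path, or
#' sources:                       #   inline summaries
#'   - {label: k1, mean: -0.26, variance: 0.25, w: 0.15}
#' prior: {a01: 2, b01: 2, a02: 18, b02: 3, s0: 0.05}   # optional
#' criterion: {type: acc, l0: 0.65, alpha: 0.05}        # or alc: l, alpha0
#' variance: {mode: known, sigma0_sq: 0.35}             # or: mode: unknown, c: 5
#' allocation: 1                  # optional, n_B / n_A
#' step: 1                        # optional ALC search granularity
#' seed: 20220328                 # optional, for the MC check
#' evaluate: {reps: 100000}       # optional MC verification block
#' output: {json: report.json, csv: report.csv}         # optional
#' }
#' Defaults applied: Gamma(2,2)/Gamma(18,3), `s0 = 0.05`, allocation 1,
#' `alpha = alpha0 = 0.05`. A known-mode variance block naming `c`, or an
#' unknown-mode block naming `sigma0_sq`, is a validation error.
#'
#' @param path Path to the configuration file.
#' @return A validated object of class `cpssd_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) yaml::read_yaml(path))
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg A nested list as produced by [load_config()] (exposed so
#'   programmatic configurations can be validated too).
#' @return A `cpssd_config` with defaults applied.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  }
  src_fields <- c("scenario", "summaries", "sources")
  present <- src_fields[src_fields %in% names(cfg)]
  if (length(present) != 1L) {
    fail(paste(src_fields, collapse = "/"),
         "exactly one scenario source must be given")
  }
  prior <- cfg$prior
  defaults <- list(a01 = 2, b01 = 2, a02 = 18, b02 = 3, s0 = 0.05)
  for (nm in names(defaults)) {
    if (is.null(prior[[nm]])) prior[[nm]] <- defaults[[nm]]
  }
  spec <- do.call(commensurate_spec, prior)

  sources <- switch(present,
    scenario = {
      sc <- get_scenario(cfg$scenario)
      sc$sources
    },
    summaries = read_summaries(cfg$summaries),
    sources = {
      s <- cfg$sources
      if (is.data.frame(s)) as_historical_summaries(s)
      else as_historical_summaries(do.call(rbind, lapply(s, as.data.frame)))
    })

  cr <- cfg$criterion
  if (is.null(cr$type) || !cr$type %in% c("acc", "alc", "apvc")) {
    fail("criterion.type", "must be one of acc, alc, apvc")
  }
  if (cr$type == "acc" && is.null(cr$l0)) fail("criterion.l0", "required for acc")
  if (cr$type == "alc" && is.null(cr$l)) fail("criterion.l", "required for alc")
  if (cr$type == "apvc" && is.null(cr$eps0)) fail("criterion.eps0", "required for apvc")
  if (is.null(cr$alpha)) cr$alpha <- 0.05
  if (is.null(cr$alpha0)) cr$alpha0 <- 0.05

  vb <- cfg$variance
  if (is.null(vb$mode) || !vb$mode %in% c("known", "unknown")) {
    fail("variance.mode", "must be 'known' or 'unknown'")
  }
  if (vb$mode == "known") {
    if (!is.null(vb$c)) fail("variance.c", "not allowed in known mode")
    if (is.null(vb$sigma0_sq) || vb$sigma0_sq <= 0) {
      fail("variance.sigma0_sq", "required and positive in known mode")
    }
  } else {
    if (!is.null(vb$sigma0_sq)) fail("variance.sigma0_sq",
                                     "not allowed in unknown mode")
    if (is.null(vb$c) || vb$c <= 0) fail("variance.c",
                                         "required and positive in unknown mode")
  }

  structure(list(
    scenario_source = present,
    scenario_label = if (present == "scenario") cfg$scenario else NA_character_,
    sources = sources, spec = spec, criterion = cr, variance = vb,
    allocation = if (is.null(cfg$allocation)) 1 else cfg$allocation,
    step = if (is.null(cfg$step)) 1L else as.integer(cfg$step),
    seed = if (is.null(cfg$seed)) 20220328L else as.integer(cfg$seed),
    evaluate = cfg$evaluate,
    output = cfg$output),
    class = "cpssd_config")
}

#' Execute a configured sample-size run
#'
#' Builds the collective prior, solves the configured criterion, optionally
#' verifies the returned design by Monte Carlo, and assembles a report that
#' echoes all inputs. The report is written to the JSON and/or CSV paths
#' named in the configuration's `output` block (JSON at full precision).
#' Progress (prior variance, synthesis weights, expected variance, solver
#' outcome) is logged with [message()] unless `quiet = TRUE`.
#'
#' @param config A `cpssd_config` from [load_config()] /
#'   [validate_config()], or a path to a configuration file.
#' @param quiet Suppress log messages (default FALSE).
#' @return The report, an object of class `cpssd_report` (a nested list),
#'   invisibly written to the configured outputs.
#' @export
run_ssd <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "cpssd_config"))
  log <- function(...) if (!quiet) message(sprintf(...))

  prior <- collective_prior(config$sources, config$spec)
  log("collective prior: N(%.4f, %.4f)", prior$mean, prior$variance)
  log("synthesis weights: %s", paste(sprintf("%.3f", prior$components$p),
                                     collapse = " "))
  vb <- config$variance
  vp <- if (vb$mode == "known") {
    variance_prior("known", sigma0_sq = vb$sigma0_sq)
  } else {
    variance_prior_from_collective(prior, vb$c)
  }
  if (vb$mode == "unknown" && vb$c > 2) {
    log("E[sigma0^2] = %.4f (c = %g)", .e_sigma0_sq(vp), vb$c)
  }
  cr <- config$criterion
  res <- ssd_solve(prior, cr$type, vp, l0 = cr$l0, alpha = cr$alpha,
                   l = cr$l, alpha0 = cr$alpha0, eps0 = cr$eps0,
                   ratio = config$allocation, step = config$step)
  if (res$binding) {
    log("%s: prior alone meets the target (no new observations required)",
        toupper(cr$type))
  } else {
    log("%s total: continuous %s, integer %d", toupper(cr$type),
        if (is.na(res$continuous_total)) "-" else
          sprintf("%.1f", res$continuous_total),
        as.integer(res$integer_total))
  }

  mc <- NULL
  if (!is.null(config$evaluate)) {
    ev <- config$evaluate
    n_total <- if (!is.null(ev$n_total)) ev$n_total else
      max(res$integer_total, 2)
    mc <- simulate_average_properties(
      prior, design_spec(n_total / (1 + config$allocation),
                         n_total * config$allocation / (1 + config$allocation)),
      vp,
      l0 = if (!is.null(cr$l0)) cr$l0 else if (!is.null(cr$l)) cr$l else 0.65,
      alpha0 = cr$alpha0,
      reps = if (!is.null(ev$reps)) ev$reps else 1e5,
      seed = config$seed)
    log("MC check at total %g: coverage %.4f, length %.4f, post. var %.5f",
        n_total, mc$avg_coverage, mc$avg_length, mc$avg_posterior_variance)
  }

  report <- structure(list(
    inputs = list(
      scenario_source = config$scenario_source,
      scenario_label = config$scenario_label,
      sources = {
        d <- prior$components[, c("label", "lambda", "w")]
        d$variance <- vapply(config$sources, `[[`, numeric(1), "variance")
        names(d)[names(d) == "lambda"] <- "mean"
        d[, c("label", "mean", "variance", "w")]
      },
      spec = unclass(config$spec),
      criterion = config$criterion,
      variance = config$variance,
      allocation = config$allocation, step = config$step,
      seed = config$seed),
    prior = list(mean = prior$mean, variance = prior$variance,
                 p = prior$components$p, xi2 = prior$components$xi2),
    variance_prior = unclass(vp),
    result = list(criterion = res$criterion,
                  continuous_total = res$continuous_total,
                  continuous_per_group = as.list(res$continuous_per_group),
                  integer_total = res$integer_total,
                  integer_per_group = as.list(res$integer_per_group),
                  binding = res$binding,
                  diagnostics = res$diagnostics),
    mc = if (is.null(mc)) NULL else unclass(mc)[c(
      "reps", "seed", "avg_coverage", "se_coverage", "avg_length",
      "se_length", "avg_posterior_variance", "se_posterior_variance")]),
    class = "cpssd_report")

  out <- config$output
  if (!is.null(out$json)) write_report_json(report, out$json)
  if (!is.null(out$csv)) write_report_csv(report, out$csv)
  report
}

#' @export
print.cpssd_report <- function(x, ...) {
  cat("Sample-size report\n")
  cat(sprintf("  prior: N(%.4f, %.4f)\n", x$prior$mean, x$prior$variance))
  r <- x$result
  if (r$binding) {
    cat(sprintf("  %s: prior alone meets the target\n", toupper(r$criterion)))
  } else {
    cat(sprintf("  %s total: %s (continuous), %d (integer)\n",
                toupper(r$criterion),
                if (is.na(r$continuous_total)) "-" else
                  sprintf("%.1f", r$continuous_total),
                as.integer(r$integer_total)))
  }
  if (!is.null(x$mc)) {
    cat(sprintf("  MC: coverage %.4f, length %.4f, posterior variance %.5f\n",
                x$mc$avg_coverage, x$mc$avg_length,
                x$mc$avg_posterior_variance))
  }
  invisible(x)
}

#' Write a report as JSON (full precision)
#'
#' @param report A `cpssd_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write the flat result row of a report as CSV
#'
#' @param report A `cpssd_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  r <- report$result
  df <- data.frame(
    criterion = r$criterion,
    variance = report$inputs$variance$mode,
    prior_mean = report$prior$mean,
    prior_variance = report$prior$variance,
    continuous_total = r$continuous_total,
    integer_total = r$integer_total,
    n_A = r$integer_per_group$n_A,
    n_B = r$integer_per_group$n_B,
    binding = r$binding)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
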