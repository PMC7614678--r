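# Built-in evaluation scenarios: a five-expert elicited-opinion example
# (log-odds-ratio scale, rare-disease trial setting) and four hypothetical
# historical-data configurations, each under two sets of robust weights.

.table1 <- function() {
  m12 <- c(-0.260, -0.240, -0.370, -0.340, -0.320)
  m34 <- c(-0.260, -0.170, -0.440, -0.150, 0.120)
  list(
    config1 = list(m = m12, s2 = c(0.250, 0.230, 0.220, 0.360, 0.260),
                   wI = c(0.103, 0.175, 0.081, 0.143, 0.077),
                   wII = c(0.252, 0.319, 0.140, 0.306, 0.149)),
    config2 = list(m = m12, s2 = rep(0.100, 5),
                   wI = c(0.103, 0.175, 0.081, 0.143, 0.077),
                   wII = c(0.252, 0.319, 0.140, 0.306, 0.149)),
    config3 = list(m = m34, s2 = c(0.250, 0.640, 0.970, 1.540, 0.590),
                   wI = c(0.101, 0.219, 0.385, 0.385, 0.304),
                   wII = c(0.325, 0.203, 0.171, 0.180, 0.272)),
    config4 = list(m = m34, s2 = c(0.250, 0.150, 0.400, 0.890, 0.220),
                   wI = c(0.066, 0.303, 0.459, 0.355, 0.115),
                   wII = c(0.537, 0.306, 0.054, 0.220, 0.350))
  )
}

#' Built-in evaluation scenarios
#'
#' Returns the package's standard test bed: the five-expert elicited-prior
#' example (`expert5`: summaries N(-0.26, 0.25), N(-0.24, 0.23),
#' N(-0.37, 0.22), N(-0.34, 0.36), N(-0.32, 0.26) with weights 0.15, 0.20,
#' 0.17, 0.13, 0.20) and four hypothetical historical-data configurations,
#' each paired with robust weight sets I and II (`config1_RWI`,
#' `config1_RWII`, ..., `config4_RWII`). All scenarios use the default
#' [commensurate_spec()].
#'
#' @return A named list of scenarios; each scenario is a list with
#'   `label`, `sources` (list of [historical_summary()]) and `spec`.
#' @export
builtin_scenarios <- function() {
  spec <- commensurate_spec()
  mk <- function(label, m, s2, w) {
    list(label = label,
         sources = as_historical_summaries(
           data.frame(label = paste0("k", seq_along(m)),
                      mean = m, variance = s2, w = w)),
         spec = spec)
  }
  out <- list(expert5 = mk("expert5",
                           c(-0.26, -0.24, -0.37, -0.34, -0.32),
                           c(0.25, 0.23, 0.22, 0.36, 0.26),
                           c(0.15, 0.20, 0.17, 0.13, 0.20)))
  t1 <- .table1()
  for (cf in names(t1)) {
    out[[paste0(cf, "_RWI")]] <- mk(paste0(cf, "_RWI"), t1[[cf]]$m,
                                    t1[[cf]]$s2, t1[[cf]]$wI)
    out[[paste0(cf, "_RWII")]] <- mk(paste0(cf, "_RWII"), t1[[cf]]$m,
                                     t1[[cf]]$s2, t1[[cf]]$wII)
  }
  out
}

#' Fetch one built-in scenario by label
#'
#' @param label One of the names of [builtin_scenarios()], e.g.
#'   `"expert5"` or `"config3_RWI"`.
#' @return A scenario list (`label`, `sources`, `spec`).
#' @export
get_scenario <- function(label) {
  sc <- builtin_scenarios()
  if (!label %in% names(sc)) {
    stop(sprintf("unknown scenario '%s'; available: %s", label,
                 paste(names(sc), collapse = ", ")), call. = FALSE)
  }
  sc[[label]]
}

#' Monte-Carlo check of the average posterior properties
#'
#' Simulates the design-stage experiment at a fixed design: per replicate,
#' draw the common variance from its prior (unknown mode) or use the fixed
#' value (known mode), draw the difference in sample means from the
#' predictive distribution, form the conditional-normal posterior, and
#' record (i) the coverage of the length-`l0` HPD interval centred at the
#' posterior mean, (ii) the length of the `1 - alpha0` credible interval
#' and (iii) the posterior variance. Averages of these three quantities
#' estimate the criteria the ACC, ALC and APVC sample sizes control, with
#' Monte-Carlo standard errors (sample SD / sqrt(reps)). The same seed and
#' inputs give a bit-identical report.
#'
#' Coverage is evaluated under the conditional-normal posterior given the
#' drawn variance, the representation the closed-form criteria are derived
#' from; set `marginal = TRUE` to instead integrate the marginal
#' (variance-integrated) posterior over the HPD interval by quadrature
#' (slower; cross-check only).
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param design A [design_spec()], group size(s), or a total (scalar,
#'   split per equal allocation).
#' @param vp A [variance_prior()] (either mode).
#' @param l0 HPD interval length for the coverage criterion.
#' @param alpha0 One minus the credible-interval coverage for the length
#'   criterion (default 0.05).
#' @param reps Number of Monte-Carlo replicates (default 1e5).
#' @param seed RNG seed (default 20220328).
#' @param marginal Use the marginal posterior for coverage (default FALSE).
#' @return An object of class `cpssd_mc`: `avg_coverage`, `avg_length`,
#'   `avg_posterior_variance`, their `se_*` companions, `reps`, `seed`,
#'   and per-quantity ranges.
#' @export
simulate_average_properties <- function(prior, design, vp, l0,
                                        alpha0 = 0.05, reps = 1e5,
                                        seed = 20220328, marginal = FALSE) {
  pr <- .as_prior(prior)
  design <- .as_design(design)
  stopifnot(inherits(vp, "cpssd_varprior"))
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  .check_targets(l0 = l0, alpha = alpha0)
  V <- pr$variance
  e <- design$effective
  z <- .zq(alpha0)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  sigma2 <- if (vp$mode == "known") rep(vp$sigma0_sq, reps) else
    1 / stats::rgamma(reps, shape = vp$c / 2, rate = vp$scale)
  # predictive draw of the difference in sample means given sigma0^2
  xbar <- stats::rnorm(reps, pr$mean, sqrt(sigma2 / e + V))
  post_var <- 1 / (1 / V + e / sigma2)
  post_sd <- sqrt(post_var)
  if (marginal) {
    coverage <- vapply(seq_len(reps), function(i) {
      dens <- marginal_posterior_unknown_variance(pr, xbar[i], design, vp)
      mu_n <- (pr$mean / V + xbar[i] * e / sigma2[i]) / (1 / V + e / sigma2[i])
      stats::integrate(dens, mu_n - l0 / 2, mu_n + l0 / 2,
                       abs.tol = 1e-8)$value
    }, numeric(1))
  } else {
    coverage <- 2 * stats::pnorm(l0 / (2 * post_sd)) - 1
  }
  lens <- 2 * z * post_sd
  se <- function(x) if (reps > 1) stats::sd(x) / sqrt(reps) else NA_real_
  structure(list(
    reps = reps, seed = seed,
    avg_coverage = mean(coverage), se_coverage = se(coverage),
    avg_length = mean(lens), se_length = se(lens),
    avg_posterior_variance = mean(post_var), se_posterior_variance = se(post_var),
    range_coverage = range(coverage), range_length = range(lens),
    range_posterior_variance = range(post_var),
    design = design, l0 = l0, alpha0 = alpha0, marginal = marginal),
    class = "cpssd_mc")
}

#' @export
print.cpssd_mc <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo average posterior properties (%d reps, seed %d)\n",
              x$reps, x$seed))
  cat(sprintf("  design: n_A = %g, n_B = %g\n", x$design$n_A, x$design$n_B))
  cat(sprintf("  avg coverage of length-%.3g HPD: %.4f (SE %.2g)\n",
              x$l0, x$avg_coverage, x$se_coverage))
  cat(sprintf("  avg %.3g%% interval length:     %.4f (SE %.2g)\n",
              100 * (1 - x$alpha0), x$avg_length, x$se_length))
  cat(sprintf("  avg posterior variance:        %.5f (SE %.2g)\n",
              x$avg_posterior_variance, x$se_posterior_variance))
  invisible(x)
}

#' Sensitivity sweep of a sample-size criterion
#'
#' Evaluates one criterion for a scenario over a grid of design settings
#' and returns a tidy table, one row per grid cell with all inputs echoed.
#' Sweepable settings: degrees of freedom `c`, coverage `alpha`/`alpha0`,
#' length targets `l0`/`l`, variance target `eps0`, and the borrowing
#' Gamma component `(a02, b02)` (supplied as a two-column matrix or a list
#' of pairs).
#'
#' @param scenario A scenario list (see [builtin_scenarios()]) or a label.
#' @param criterion `"acc"`, `"alc"` or `"apvc"`.
#' @param c Vector of degrees of freedom (unknown variance; use
#'   `sigma0_sq` instead for known variance).
#' @param sigma0_sq Optional vector of known variances.
#' @param l0,alpha,l,alpha0,eps0 Vectors of criterion targets (defaults:
#'   single values `l0 = 0.65`, `alpha = 0.05`, `l = 0.65`,
#'   `alpha0 = 0.05`, `eps0 = 0.03`).
#' @param gamma2 Optional borrowing-component settings: a list of
#'   `c(a02, b02)` pairs or a two-column matrix.
#' @param ratio,step Passed to the solvers.
#' @return A data frame; columns echo the grid and report
#'   `prior_mean`, `prior_variance`, `continuous_total`, `integer_total`.
#' @export
sensitivity_sweep <- function(scenario, criterion = c("acc", "alc", "apvc"),
                              c = NULL, sigma0_sq = NULL,
                              l0 = 0.65, alpha = 0.05, l = 0.65,
                              alpha0 = 0.05, eps0 = 0.03,
                              gamma2 = NULL, ratio = 1, step = 1L) {
  criterion <- match.arg(criterion)
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  if (is.null(c) && is.null(sigma0_sq)) {
    stop("supply 'c' (unknown variance) or 'sigma0_sq' (known)", call. = FALSE)
  }
  if (is.null(gamma2)) {
    gamma2 <- list(c(scenario$spec$a02, scenario$spec$b02))
  } else if (is.matrix(gamma2)) {
    gamma2 <- lapply(seq_len(nrow(gamma2)), function(i) gamma2[i, ])
  }
  var_grid <- if (!is.null(c)) {
    data.frame(mode = "unknown", par = c)
  } else {
    data.frame(mode = "known", par = sigma0_sq)
  }
  targets <- switch(criterion,
    acc = expand.grid(l_target = l0, alpha_target = alpha),
    alc = expand.grid(l_target = l, alpha_target = alpha0),
    apvc = expand.grid(l_target = NA_real_, alpha_target = NA_real_,
                       eps_target = eps0))
  if (criterion != "apvc") targets$eps_target <- NA_real_
  rows <- list()
  for (g in seq_along(gamma2)) {
    sp <- commensurate_spec(scenario$spec$a01, scenario$spec$b01,
                            gamma2[[g]][1], gamma2[[g]][2], scenario$spec$s0)
    pr <- collective_prior(scenario$sources, sp)
    for (vi in seq_len(nrow(var_grid))) {
      vp <- if (var_grid$mode[vi] == "unknown") {
        variance_prior_from_collective(pr, var_grid$par[vi])
      } else {
        variance_prior("known", sigma0_sq = var_grid$par[vi])
      }
      for (ti in seq_len(nrow(targets))) {
        res <- ssd_solve(pr, criterion, vp,
                         l0 = targets$l_target[ti],
                         alpha = targets$alpha_target[ti],
                         l = targets$l_target[ti],
                         alpha0 = targets$alpha_target[ti],
                         eps0 = targets$eps_target[ti],
                         ratio = ratio, step = step)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scenario$label, criterion = criterion,
          a02 = gamma2[[g]][1], b02 = gamma2[[g]][2],
          variance = var_grid$mode[vi],
          c = if (var_grid$mode[vi] == "unknown") var_grid$par[vi] else NA_real_,
          sigma0_sq = if (var_grid$mode[vi] == "known") var_grid$par[vi] else NA_real_,
          l_target = targets$l_target[ti],
          alpha_target = targets$alpha_target[ti],
          eps_target = targets$eps_target[ti],
          prior_mean = pr$mean, prior_variance = pr$variance,
          continuous_total = res$continuous_total,
          integer_total = res$integer_total,
          binding = res$binding)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
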