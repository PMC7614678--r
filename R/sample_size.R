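#' Effective size of a two-group design
#'
#' The precision-relevant function of the two group sizes,
#' `n_A * n_B / (n_A + n_B)`; under equal allocation with total `N` it
#' equals `N/4`. All closed-form sample-size inequalities bound this
#' quantity.
#'
#' @param n_A,n_B Positive group sizes (real-valued allowed).
#' @return The effective size.
#' @export
effective_size <- function(n_A, n_B) {
  if (any(n_A <= 0) || any(n_B <= 0)) stop("group sizes must be positive",
                                           call. = FALSE)
  n_A * n_B / (n_A + n_B)
}

#' Group sizes achieving a given effective size
#'
#' Inverts [effective_size()] under an allocation ratio `R = n_B / n_A`:
#' `n_A = e * (1 + R) / R`, `n_B = e * (1 + R)`, so the total is
#' `e * (1 + R)^2 / R` (i.e. `4 * e` when `R = 1`).
#'
#' @param e Effective size; non-negative.
#' @param ratio Allocation ratio `n_B / n_A`; positive (default 1).
#' @return A list with `n_A`, `n_B` and `total`.
#' @export
groups_from_effective <- function(e, ratio = 1) {
  if (e < 0) stop("'e' must be non-negative", call. = FALSE)
  if (ratio <= 0) stop("'ratio' must be positive", call. = FALSE)
  list(n_A = e * (1 + ratio) / ratio, n_B = e * (1 + ratio),
       total = e * (1 + ratio)^2 / ratio)
}

# effective size of an integer-ish total N split per the allocation ratio
.effective_of_total <- function(N, ratio = 1) {
  N * ratio / (1 + ratio)^2
}

.zq <- function(alpha) stats::qnorm(1 - alpha / 2)

# assemble a sample-size result from a continuous effective-size bound
.ssd_result <- function(criterion, e_req, ratio, diagnostics = list(),
                        integer_total = NULL) {
  binding <- e_req <= 0
  e_req <- max(e_req, 0)
  g <- groups_from_effective(e_req, ratio)
  if (is.null(integer_total)) {
    ni <- if (binding) list(n_A = 0, n_B = 0) else
      lapply(groups_from_effective(e_req, ratio)[c("n_A", "n_B")], ceiling)
    integer_total <- ni$n_A + ni$n_B
  } else {
    ni <- if (binding) list(n_A = 0, n_B = 0) else
      list(n_A = integer_total / (1 + ratio), n_B = integer_total * ratio / (1 + ratio))
  }
  structure(list(criterion = criterion,
                 continuous_total = if (binding) 0 else g$total,
                 continuous_per_group = c(n_A = if (binding) 0 else g$n_A,
                                          n_B = if (binding) 0 else g$n_B),
                 integer_total = as.numeric(integer_total),
                 integer_per_group = c(n_A = as.numeric(ni$n_A),
                                       n_B = as.numeric(ni$n_B)),
                 binding = binding, ratio = ratio,
                 diagnostics = diagnostics),
            class = "cpssd_result")
}

#' @export
print.cpssd_result <- function(x, ...) {
  cat(sprintf("%s sample size (allocation ratio %g):\n", toupper(x$criterion),
              x$ratio))
  if (x$binding) {
    cat("  prior alone already meets the target; no new observations required\n")
  } else if (is.na(x$continuous_total)) {
    cat(sprintf("  total (integer search): %d  (n_A = %g, n_B = %g)\n",
                as.integer(x$integer_total), x$integer_per_group["n_A"],
                x$integer_per_group["n_B"]))
  } else {
    cat(sprintf("  continuous total: %.1f  (n_A = %.2f, n_B = %.2f)\n",
                x$continuous_total, x$continuous_per_group["n_A"],
                x$continuous_per_group["n_B"]))
    cat(sprintf("  integer total:    %d  (n_A = %g, n_B = %g)\n",
                as.integer(x$integer_total), x$integer_per_group["n_A"],
                x$integer_per_group["n_B"]))
  }
  invisible(x)
}

#' ACC sample size, known variance
#'
#' Smallest design whose fixed-length HPD interval, centred at the
#' posterior mean, attains average coverage `1 - alpha` over the predictive
#' distribution of the data: the effective size must satisfy
#' `e >= (4*z^2/l0^2 - 1/V) * sigma0_sq` with `z = qnorm(1 - alpha/2)` and
#' `V` the prior variance. When the right-hand side is non-positive the
#' prior alone meets the target (`binding`).
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param l0 Target HPD interval length; positive.
#' @param alpha One minus the target average coverage; in (0, 1).
#' @param sigma0_sq Known common variance; positive.
#' @param ratio Allocation ratio `n_B / n_A` (default 1).
#' @return A `cpssd_result`.
#' @export
acc_known <- function(prior, l0, alpha, sigma0_sq, ratio = 1) {
  pr <- .as_prior(prior)
  .check_targets(l0 = l0, alpha = alpha)
  if (sigma0_sq <= 0) stop("'sigma0_sq' must be positive", call. = FALSE)
  V <- pr$variance
  e_req <- (4 * .zq(alpha)^2 / l0^2 - 1 / V) * sigma0_sq
  .ssd_result("acc", e_req, ratio,
              diagnostics = list(V = V, sigma0_sq = sigma0_sq,
                                 z = .zq(alpha), variance = "known"))
}

#' ALC sample size, known variance
#'
#' With known variance the credible-interval length is deterministic given
#' the design, so the average length criterion coincides with the average
#' coverage criterion: the solution equals [acc_known()] with targets
#' `(l, alpha0)`.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param l Target average credible-interval length; positive.
#' @param alpha0 One minus the interval coverage; in (0, 1).
#' @param sigma0_sq Known common variance; positive.
#' @param ratio Allocation ratio (default 1).
#' @return A `cpssd_result` (criterion flagged `"alc"`).
#' @export
alc_known <- function(prior, l, alpha0, sigma0_sq, ratio = 1) {
  out <- acc_known(prior, l0 = l, alpha = alpha0, sigma0_sq = sigma0_sq,
                   ratio = ratio)
  out$criterion <- "alc"
  out
}

#' APVC sample size, known variance
#'
#' Smallest design whose average posterior variance is at most `eps0`:
#' the effective size must satisfy `e >= (1/eps0 - 1/V) * sigma0_sq`.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param eps0 Target average posterior variance; positive.
#' @param sigma0_sq Known common variance; positive.
#' @param ratio Allocation ratio (default 1).
#' @return A `cpssd_result`.
#' @export
apvc_known <- function(prior, eps0, sigma0_sq, ratio = 1) {
  pr <- .as_prior(prior)
  .check_targets(eps0 = eps0)
  if (sigma0_sq <= 0) stop("'sigma0_sq' must be positive", call. = FALSE)
  V <- pr$variance
  e_req <- (1 / eps0 - 1 / V) * sigma0_sq
  .ssd_result("apvc", e_req, ratio,
              diagnostics = list(V = V, sigma0_sq = sigma0_sq,
                                 variance = "known"))
}

#' ACC sample size, unknown variance
#'
#' The known-variance ACC bound averaged over the inverse-gamma variance
#' prior: `sigma0_sq` is replaced by its prior mean `E[sigma0_sq] =
#' c*V/(c-2)` (for a prior anchored to the collective prior), which
#' requires `c > 2`.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param l0,alpha ACC targets as in [acc_known()].
#' @param vp A [variance_prior()] in unknown mode with `c > 2`.
#' @param ratio Allocation ratio (default 1).
#' @return A `cpssd_result`.
#' @export
acc_unknown <- function(prior, l0, alpha, vp, ratio = 1) {
  pr <- .as_prior(prior)
  .check_targets(l0 = l0, alpha = alpha)
  es <- .check_unknown_vp(vp)
  V <- pr$variance
  e_req <- (4 * .zq(alpha)^2 / l0^2 - 1 / V) * es
  .ssd_result("acc", e_req, ratio,
              diagnostics = list(V = V, E_sigma0_sq = es, c = vp$c,
                                 z = .zq(alpha), variance = "unknown"))
}

#' APVC sample size, unknown variance
#'
#' As [apvc_known()] with `sigma0_sq` replaced by the prior mean
#' `E[sigma0_sq]`; requires `c > 2`.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param eps0 Target average posterior variance; positive.
#' @param vp A [variance_prior()] in unknown mode with `c > 2`.
#' @param ratio Allocation ratio (default 1).
#' @return A `cpssd_result`.
#' @export
apvc_unknown <- function(prior, eps0, vp, ratio = 1) {
  pr <- .as_prior(prior)
  .check_targets(eps0 = eps0)
  es <- .check_unknown_vp(vp)
  V <- pr$variance
  e_req <- (1 / eps0 - 1 / V) * es
  .ssd_result("apvc", e_req, ratio,
              diagnostics = list(V = V, E_sigma0_sq = es, c = vp$c,
                                 variance = "unknown"))
}

.check_unknown_vp <- function(vp) {
  stopifnot(inherits(vp, "cpssd_varprior"))
  if (vp$mode != "unknown") stop("'vp' must be an unknown-mode variance prior",
                                 call. = FALSE)
  .e_sigma0_sq(vp)  # errors for c <= 2, naming the moment condition
}

.check_targets <- function(l0 = NULL, alpha = NULL, eps0 = NULL) {
  if (!is.null(l0) && (!is.numeric(l0) || l0 <= 0)) {
    stop("interval length target must be positive", call. = FALSE)
  }
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1)) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(eps0) && (!is.numeric(eps0) || eps0 <= 0)) {
    stop("posterior-variance target must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

# Expected posterior SD at effective size e, averaged over the variance
# prior. Substituting the precision u = 1/sigma0^2 ~ Gamma(c/2, rate = scale)
# bounds the integrand by sqrt(V); integrating over the probability scale
# (u = qgamma(p)) keeps the quadrature well-behaved for all c > 0, including
# near-degenerate priors with very large c.
.expected_posterior_sd <- function(V, e, vp, abs.tol = 1e-10) {
  f <- function(p) {
    u <- stats::qgamma(p, shape = vp$c / 2, rate = vp$scale)
    (1 / V + e * u)^(-0.5)
  }
  stats::integrate(f, 0, 1, abs.tol = abs.tol, subdivisions = 500L)$value
}

#' ALC sample size, unknown variance
#'
#' Finds the smallest integer total `N` such that the average
#' credible-interval length `2 * z * E[sigma_N]` is at most `l`, where
#' `sigma_N^2 = (1/V + e/sigma0_sq)^{-1}`, `e` is the effective size of the
#' split of `N` under the allocation ratio, and the expectation is over the
#' inverse-gamma variance prior (computed by adaptive quadrature after
#' substituting the precision, which makes the integrand bounded). There is
#' no closed form; the left side is strictly decreasing in `N`, so the
#' search bisects over admissible totals, bracketed above by the ACC
#' solution when `c > 2` (the ALC total never exceeds it) and by geometric
#' expansion otherwise.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param l Target average credible-interval length; positive.
#' @param alpha0 One minus the interval coverage; in (0, 1).
#' @param vp A [variance_prior()] in unknown mode (any `c > 0`).
#' @param ratio Allocation ratio (default 1).
#' @param step Granularity of the total-sample-size search: 1 (default)
#'   searches every integer total; 2 restricts to totals with integer
#'   per-group sizes under equal allocation.
#' @param n_max Largest total considered before the search aborts.
#' @return A `cpssd_result` with `continuous_total = NA` (integer-only
#'   criterion); diagnostics include the average length at the returned
#'   total and at the preceding admissible total.
#' @export
alc_unknown <- function(prior, l, alpha0, vp, ratio = 1, step = 1L,
                        n_max = 1e6) {
  pr <- .as_prior(prior)
  .check_targets(l0 = l, alpha = alpha0)
  stopifnot(inherits(vp, "cpssd_varprior"))
  if (vp$mode != "unknown") stop("'vp' must be an unknown-mode variance prior",
                                 call. = FALSE)
  if (!step %in% c(1L, 2L)) stop("'step' must be 1 or 2", call. = FALSE)
  V <- pr$variance
  z <- .zq(alpha0)
  avg_len <- function(N) {
    2 * z * .expected_posterior_sd(V, .effective_of_total(N, ratio), vp)
  }
  # prior alone: e = 0 gives average length 2 z sqrt(V)
  if (2 * z * sqrt(V) <= l) {
    return(.ssd_result("alc", 0, ratio,
                       diagnostics = list(V = V, c = vp$c, z = z,
                                          variance = "unknown",
                                          avg_length_at_zero = 2 * z * sqrt(V))))
  }
  # upper bracket
  hi <- if (vp$c > 2) {
    acc <- acc_unknown(pr, l0 = l, alpha = alpha0, vp = vp, ratio = ratio)
    max(step, as.integer(ceiling(acc$continuous_total / step)) * step)
  } else {
    h <- step
    while (avg_len(h) > l && h < n_max) h <- h * 2
    h
  }
  while (avg_len(hi) > l) {
    hi <- hi * 2
    if (hi > n_max) {
      stop(sprintf("ALC target l = %g unreachable within n_max = %g (average length %.4g at N = %g)",
                   l, n_max, avg_len(n_max), n_max), call. = FALSE)
    }
  }
  lo <- 0L  # criterion fails at 0 (checked above); holds at hi
  while (hi - lo > step) {
    mid <- lo + floor((hi - lo) / (2 * step)) * step
    if (mid == lo) mid <- lo + step
    if (avg_len(mid) <= l) hi <- mid else lo <- mid
  }
  N <- hi
  res <- .ssd_result("alc", .effective_of_total(N, ratio), ratio,
                     integer_total = N,
                     diagnostics = list(
                       V = V, c = vp$c, z = z, variance = "unknown",
                       step = step,
                       avg_length_at_N = avg_len(N),
                       avg_length_below = if (N > step) avg_len(N - step) else NA_real_))
  res$continuous_total <- NA_real_
  res$continuous_per_group <- c(n_A = NA_real_, n_B = NA_real_)
  res$integer_per_group <- c(n_A = N / (1 + ratio) * 1,
                             n_B = N * ratio / (1 + ratio))
  res
}

#' Solve a sample-size criterion
#'
#' Dispatcher over the six closed-form / search solvers, convenient for
#' sweeps and configuration-driven runs.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param criterion `"acc"`, `"alc"` or `"apvc"`.
#' @param vp A [variance_prior()] (known or unknown mode).
#' @param l0 HPD length target (ACC).
#' @param alpha One minus average coverage (ACC).
#' @param l Average length target (ALC).
#' @param alpha0 One minus interval coverage (ALC).
#' @param eps0 Average posterior-variance target (APVC).
#' @param ratio Allocation ratio (default 1).
#' @param step ALC search granularity (default 1).
#' @return A `cpssd_result`.
#' @export
ssd_solve <- function(prior, criterion = c("acc", "alc", "apvc"), vp,
                      l0 = NULL, alpha = 0.05, l = NULL, alpha0 = 0.05,
                      eps0 = NULL, ratio = 1, step = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(vp, "cpssd_varprior"))
  known <- vp$mode == "known"
  switch(criterion,
    acc = {
      if (is.null(l0)) stop("ACC requires 'l0'", call. = FALSE)
      if (known) acc_known(prior, l0, alpha, vp$sigma0_sq, ratio)
      else acc_unknown(prior, l0, alpha, vp, ratio)
    },
    alc = {
      if (is.null(l)) stop("ALC requires 'l'", call. = FALSE)
      if (known) alc_known(prior, l, alpha0, vp$sigma0_sq, ratio)
      else alc_unknown(prior, l, alpha0, vp, ratio, step = step)
    },
    apvc = {
      if (is.null(eps0)) stop("APVC requires 'eps0'", call. = FALSE)
      if (known) apvc_known(prior, eps0, vp$sigma0_sq, ratio)
      else apvc_unknown(prior, eps0, vp, ratio)
    })
}

#' Compare borrowing strategies for one scenario
#'
#' Recomputes one criterion under the standard comparison modes:
#' \describe{
#'   \item{robust}{the commensurate synthesis with the given weights;}
#'   \item{no_robustification}{all incommensurability weights set to 0
#'     (full borrowing through the informative Gamma component);}
#'   \item{no_borrowing}{all weights set to 1, so the synthesis weights are
#'     uniform and each source is maximally inflated;}
#'   \item{single_source}{the most informative source's normal summary
#'     `N(m_k, s_k^2)` used directly as the prior, no inflation;}
#'   \item{optimal}{the benchmark of perfect commensurability: the known
#'     variance is set equal to the robust collective prior variance `V`
#'     (known mode), or the variance prior is anchored to `V` with a very
#'     large `c` (unknown mode).}
#' }
#' In unknown-variance mode each strategy anchors its inverse-gamma prior
#' to its own prior variance (`Inv-Gamma(c/2, c*V_mode/2)`), so "no
#' borrowing" forgoes pre-experimental information through the variance
#' too.
#'
#' @param sources List of [historical_summary()] objects.
#' @param spec A [commensurate_spec()].
#' @param criterion `"acc"`, `"alc"` or `"apvc"`.
#' @param variance `"known"` or `"unknown"`.
#' @param sigma0_sq Known common variance (known mode).
#' @param c Degrees of freedom (unknown mode).
#' @param l0,alpha,l,alpha0,eps0,ratio,step Criterion targets as in
#'   [ssd_solve()].
#' @param c_optimal Degrees of freedom used for the unknown-mode optimal
#'   benchmark (default `1e6`).
#' @return A data frame with one row per mode: prior mean and variance,
#'   continuous and integer totals, and the binding flag.
#' @export
comparison_modes <- function(sources, spec = commensurate_spec(),
                             criterion = c("acc", "alc", "apvc"),
                             variance = c("known", "unknown"),
                             sigma0_sq = NULL, c = NULL,
                             l0 = NULL, alpha = 0.05, l = NULL, alpha0 = 0.05,
                             eps0 = NULL, ratio = 1, step = 1L,
                             c_optimal = 1e6) {
  criterion <- match.arg(criterion)
  variance <- match.arg(variance)
  if (is.data.frame(sources)) sources <- as_historical_summaries(sources)
  reweight <- function(w) {
    lapply(sources, function(s) historical_summary(s$mean, s$variance, w, s$label))
  }
  robust <- collective_prior(sources, spec)
  s2 <- vapply(sources, `[[`, numeric(1), "variance")
  best <- sources[[which.min(s2)]]
  priors <- list(
    robust = robust,
    no_robustification = collective_prior(reweight(0), spec),
    no_borrowing = collective_prior(reweight(1), spec),
    single_source = list(mean = best$mean, variance = best$variance)
  )
  solve_mode <- function(pr, vp) {
    ssd_solve(pr, criterion, vp, l0 = l0, alpha = alpha, l = l,
              alpha0 = alpha0, eps0 = eps0, ratio = ratio, step = step)
  }
  rows <- lapply(names(priors), function(nm) {
    pr <- .as_prior(priors[[nm]])
    vp <- if (variance == "known") {
      variance_prior("known", sigma0_sq = sigma0_sq)
    } else {
      variance_prior_from_collective(pr, c)
    }
    cbind(mode = nm, .result_row(pr, solve_mode(pr, vp)))
  })
  # optimal benchmark: perfect commensurability with the robust prior
  pr <- .as_prior(robust)
  vp_opt <- if (variance == "known") {
    variance_prior("known", sigma0_sq = pr$variance)
  } else {
    variance_prior_from_collective(pr, c_optimal)
  }
  rows <- c(rows, list(cbind(mode = "optimal",
                             .result_row(pr, solve_mode(pr, vp_opt)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.result_row <- function(pr, res) {
  data.frame(prior_mean = pr$mean, prior_variance = pr$variance,
             continuous_total = res$continuous_total,
             integer_total = res$integer_total,
             binding = res$binding)
}
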