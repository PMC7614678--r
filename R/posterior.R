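#' Design specification for a two-group experiment
#'
#' Group sizes may be real-valued so that continuous sample-size solutions
#' can be represented before rounding.
#'
#' @param n_A,n_B Positive group sizes; `n_B` defaults to `n_A` (equal
#'   allocation).
#' @return An object of class `cpssd_design` with fields `n_A`, `n_B`,
#'   `ratio` (`n_B/n_A`) and `effective` (`n_A*n_B/(n_A+n_B)`).
#' @export
design_spec <- function(n_A, n_B = n_A) {
  if (n_A <= 0 || n_B <= 0) stop("group sizes must be positive", call. = FALSE)
  structure(list(n_A = n_A, n_B = n_B, ratio = n_B / n_A,
                 effective = effective_size(n_A, n_B)),
            class = "cpssd_design")
}

.as_design <- function(design) {
  if (inherits(design, "cpssd_design")) return(design)
  if (is.numeric(design) && length(design) %in% 1:2) {
    return(design_spec(design[1], design[length(design)]))
  }
  stop("'design' must be a design_spec() or group size(s)", call. = FALSE)
}

#' Prior for the common sampling variance
#'
#' In `"known"` mode the common variance of the new experiment is fixed at
#' `sigma0_sq`. In `"unknown"` mode it carries an inverse-gamma prior
#' `Inv-Gamma(c/2, scale)`, equivalently `c * (2*scale/c) / sigma0_sq ~
#' chi^2(c)`; the prior mean `E[sigma0_sq] = 2*scale / (c - 2)` exists for
#' `c > 2`. Use [variance_prior_from_collective()] to anchor the scale to a
#' collective prior.
#'
#' @param mode `"known"` or `"unknown"`.
#' @param sigma0_sq Fixed variance (known mode).
#' @param c Degrees of freedom of the chi-square link (unknown mode);
#'   positive.
#' @param scale Inverse-gamma scale (unknown mode); positive.
#' @return An object of class `cpssd_varprior`.
#' @export
variance_prior <- function(mode = c("known", "unknown"), sigma0_sq = NULL,
                           c = NULL, scale = NULL) {
  mode <- match.arg(mode)
  if (mode == "known") {
    if (is.null(sigma0_sq) || sigma0_sq <= 0) {
      stop("known mode requires a positive 'sigma0_sq'", call. = FALSE)
    }
    out <- list(mode = "known", sigma0_sq = as.numeric(sigma0_sq))
  } else {
    if (is.null(c) || c <= 0 || is.null(scale) || scale <= 0) {
      stop("unknown mode requires positive 'c' and 'scale'", call. = FALSE)
    }
    out <- list(mode = "unknown", c = as.numeric(c), scale = as.numeric(scale))
  }
  structure(out, class = "cpssd_varprior")
}

#' Anchor the variance prior to a collective prior
#'
#' Builds the inverse-gamma prior `Inv-Gamma(c/2, c*V/2)` for the unknown
#' common variance, where `V` is the collective prior variance; this is the
#' chi-square specification `c*V / sigma0_sq ~ chi^2(c)`. Larger `c` ties
#' the variance more tightly to `V`: `E[sigma0_sq] = c*V/(c-2)` for `c > 2`,
#' decreasing to `V` as `c -> Inf`.
#'
#' @param prior A [collective_prior()] (or anything with mean/variance
#'   accepted by the solvers).
#' @param c Degrees of freedom; positive.
#' @return A [variance_prior()] in unknown mode.
#' @examples
#' # V = 0.154, c = 5 gives Inv-Gamma(2.5, 0.385)
#' @export
variance_prior_from_collective <- function(prior, c) {
  pr <- .as_prior(prior)
  if (c <= 0) stop("'c' must be positive", call. = FALSE)
  variance_prior("unknown", c = c, scale = c * pr$variance / 2)
}

#' @export
print.cpssd_varprior <- function(x, digits = 4, ...) {
  if (x$mode == "known") {
    cat(sprintf("Known common variance: sigma0^2 = %s\n",
                format(x$sigma0_sq, digits = digits)))
  } else {
    cat(sprintf("Unknown common variance: sigma0^2 ~ Inv-Gamma(%s, %s)  [c = %s]\n",
                format(x$c / 2, digits = digits),
                format(x$scale, digits = digits),
                format(x$c, digits = digits)))
    if (x$c > 2) {
      cat(sprintf("  E[sigma0^2] = %s\n",
                  format(2 * x$scale / (x$c - 2), digits = digits)))
    }
  }
  invisible(x)
}

# prior mean of sigma0^2; errors for c <= 2 where the mean does not exist
.e_sigma0_sq <- function(vp) {
  stopifnot(inherits(vp, "cpssd_varprior"))
  if (vp$mode == "known") return(vp$sigma0_sq)
  if (vp$c <= 2) {
    stop("E[sigma0^2] requires c > 2: the Inv-Gamma(c/2, .) prior has no ",
         "finite mean otherwise", call. = FALSE)
  }
  2 * vp$scale / (vp$c - 2)
}

#' Posterior of the mean difference under known variance
#'
#' Conjugate normal update of the collective prior by the observed
#' difference in sample means `xbar_delta`: posterior precision is the
#' prior precision `1/V` plus the data precision
#' `1/((1/n_A + 1/n_B) * sigma0_sq)`; the posterior mean is the
#' precision-weighted average of the prior mean and `xbar_delta`.
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param xbar_delta Observed difference in sample means.
#' @param design A [design_spec()] or group size(s).
#' @param sigma0_sq Known common variance; positive.
#' @return An object of class `cpssd_posterior` with `mean`, `variance` and
#'   the inputs echoed.
#' @export
posterior_known_variance <- function(prior, xbar_delta, design, sigma0_sq) {
  pr <- .as_prior(prior)
  design <- .as_design(design)
  if (sigma0_sq <= 0) stop("'sigma0_sq' must be positive", call. = FALSE)
  data_prec <- design$effective / sigma0_sq   # 1 / ((1/nA + 1/nB) sigma0^2)
  prec <- 1 / pr$variance + data_prec
  mean <- (pr$mean / pr$variance + xbar_delta * data_prec) / prec
  structure(list(mean = mean, variance = 1 / prec,
                 prior = pr, xbar_delta = xbar_delta,
                 design = design, sigma0_sq = sigma0_sq),
            class = "cpssd_posterior")
}

#' @export
print.cpssd_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior: mu_Delta | data ~ N(%s, %s)\n",
              format(x$mean, digits = digits),
              format(x$variance, digits = digits)))
  invisible(x)
}

#' Fixed-length HPD interval of a normal posterior
#'
#' The posterior is unimodal and symmetric, so the highest-posterior-density
#' interval of length `length` is centred at the posterior mean. Also
#' reports the posterior probability content of the interval.
#'
#' @param posterior A `cpssd_posterior`.
#' @param length Interval length; positive.
#' @return A list with `lower`, `upper`, `length` and `coverage`.
#' @export
hpd_interval <- function(posterior, length) {
  stopifnot(inherits(posterior, "cpssd_posterior"), length > 0)
  s <- sqrt(posterior$variance)
  list(lower = posterior$mean - length / 2,
       upper = posterior$mean + length / 2,
       length = length,
       coverage = 2 * stats::pnorm(length / (2 * s)) - 1)
}

#' Equal-tailed (= HPD) credible interval of a normal posterior
#'
#' @param posterior A `cpssd_posterior`.
#' @param level Coverage probability in (0, 1).
#' @return A list with `lower`, `upper`, `length` and `level`.
#' @export
credible_interval <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "cpssd_posterior"), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- sqrt(posterior$variance)
  list(lower = posterior$mean - z * s, upper = posterior$mean + z * s,
       length = 2 * z * s, level = level)
}

#' Predictive distribution of the difference in sample means
#'
#' The marginal (pre-posterior) distribution of the difference-in-sample-
#' means statistic, unconditional on the mean difference:
#' `N(prior mean, (1/n_A + 1/n_B) * sigma0_sq + V)`. In unknown-variance
#' mode a conditioning value of `sigma0_sq` must be supplied (the joint
#' predictive is sampled by first drawing `sigma0_sq` from its prior).
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param design A [design_spec()] or group size(s).
#' @param sigma0_sq The (known or conditioning) common variance; positive.
#' @return A list with `mean` and `variance`.
#' @export
predictive_distribution <- function(prior, design, sigma0_sq) {
  pr <- .as_prior(prior)
  design <- .as_design(design)
  if (sigma0_sq <= 0) stop("'sigma0_sq' must be positive", call. = FALSE)
  list(mean = pr$mean, variance = sigma0_sq / design$effective + pr$variance)
}

#' Marginal posterior of the mean difference under unknown variance
#'
#' With the inverse-gamma variance prior integrated out, the marginal
#' posterior density is proportional to the product of the normal prior
#' kernel and a nonstandardized t kernel with location `xbar_delta`,
#' squared scale `(1/n_A + 1/n_B) * V` and `c` degrees of freedom, where
#' `V` is the prior variance. There is no closed form for the normalizing
#' constant, which is computed by adaptive quadrature on a window of
#' +/- 15 combined scales around the two locations (absolute tolerance
#' 1e-10).
#'
#' @param prior A [collective_prior()] (or `c(mean, variance)`).
#' @param xbar_delta Observed difference in sample means.
#' @param design A [design_spec()] or group size(s).
#' @param vp A [variance_prior()] in unknown mode.
#' @return A function `f(x)` evaluating the normalized density, with
#'   attributes `normalizing_constant` and `support` (the quadrature
#'   window).
#' @export
marginal_posterior_unknown_variance <- function(prior, xbar_delta, design, vp) {
  pr <- .as_prior(prior)
  design <- .as_design(design)
  stopifnot(inherits(vp, "cpssd_varprior"))
  if (vp$mode != "unknown") stop("'vp' must be an unknown-mode variance prior",
                                 call. = FALSE)
  V <- pr$variance
  t_scale <- sqrt(V / design$effective)
  kernel <- function(x) {
    stats::dnorm(x, pr$mean, sqrt(V)) *
      stats::dt((x - xbar_delta) / t_scale, df = vp$c) / t_scale
  }
  s_all <- sqrt(V) + t_scale
  lo <- min(pr$mean, xbar_delta) - 15 * s_all
  hi <- max(pr$mean, xbar_delta) + 15 * s_all
  nc <- tryCatch(
    stats::integrate(kernel, lo, hi, abs.tol = 1e-10,
                     subdivisions = 500L)$value,
    error = function(e) {
      stop("quadrature for the marginal posterior failed to converge: ",
           conditionMessage(e), call. = FALSE)
    })
  if (!is.finite(nc) || nc <= 0) {
    stop("marginal posterior normalization is not finite; check inputs",
         call. = FALSE)
  }
  out <- function(x) kernel(x) / nc
  attr(out, "normalizing_constant") <- nc
  attr(out, "support") <- c(lo, hi)
  out
}

#' Evaluate a posterior density on a grid and write it to CSV
#'
#' @param density A function `f(x)` (e.g. from
#'   [marginal_posterior_unknown_variance()]).
#' @param grid Numeric vector of evaluation points.
#' @param path Optional CSV path; when `NULL`, the data frame is returned
#'   only.
#' @return A data frame with columns `x` and `density`.
#' @export
density_to_csv <- function(density, grid, path = NULL) {
  df <- data.frame(x = grid, density = density(grid))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
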