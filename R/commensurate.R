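#' Commensurate predictive prior specification
#'
#' Hyperparameters of the two-component Gamma mixture prior on the
#' commensurate precision of each source, plus the concentration parameter
#' of the softmax synthesis weights. For source k with incommensurability
#' weight `w_k`, the precision `nu_k` has prior
#' `w_k * Gamma(a01, b01) + (1 - w_k) * Gamma(a02, b02)` (shape/rate).
#' Component 1 should sit on small precisions (strong down-weighting) and
#' component 2 on large precisions (strong borrowing), i.e.
#' `b01/(a01 - 1) > b02/(a02 - 1)`; if that ordering is violated a warning
#' is issued because the interpretation of the two components inverts.
#' Both shapes must exceed 1 so the predictive variance inflation
#' `w*b01/(a01-1) + (1-w)*b02/(a02-1)` is finite.
#'
#' Defaults are a weakly informative down-weighting component Gamma(2, 2)
#' and a borrowing component Gamma(18, 3), with synthesis concentration
#' `s0 = 0.05`.
#'
#' @param a01,b01 Shape and rate of the down-weighting Gamma component.
#' @param a02,b02 Shape and rate of the borrowing Gamma component.
#' @param s0 Concentration parameter of the synthesis weights; positive.
#' @return An object of class `cpssd_spec`.
#' @export
commensurate_spec <- function(a01 = 2, b01 = 2, a02 = 18, b02 = 3, s0 = 0.05) {
  for (nm in c("a01", "b01", "a02", "b02", "s0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  if (a01 <= 1 || a02 <= 1) {
    stop("Gamma shapes a01 and a02 must exceed 1 (otherwise the moment-matched ",
         "predictive variance is infinite)", call. = FALSE)
  }
  if (b01 / (a01 - 1) <= b02 / (a02 - 1)) {
    warning("component 1 (a01, b01) is not more diffuse than component 2 ",
            "(a02, b02): the down-weighting/borrowing interpretation of the ",
            "mixture weights inverts", call. = FALSE)
  }
  structure(list(a01 = a01, b01 = b01, a02 = a02, b02 = b02, s0 = s0),
            class = "cpssd_spec")
}

#' @export
print.cpssd_spec <- function(x, ...) {
  cat(sprintf("Commensurate prior: nu ~ w Gamma(%g, %g) + (1-w) Gamma(%g, %g); s0 = %g\n",
              x$a01, x$b01, x$a02, x$b02, x$s0))
  cat(sprintf("  variance inflation: w in {1, 0} adds {%.4g, %.4g}\n",
              x$b01 / (x$a01 - 1), x$b02 / (x$a02 - 1)))
  invisible(x)
}

.check_spec <- function(spec) {
  if (!inherits(spec, "cpssd_spec")) stop("'spec' must be a commensurate_spec()",
                                          call. = FALSE)
  invisible(spec)
}

#' Predictive variance inflation of one source
#'
#' The variance added to a source's sampling variance when its location is
#' projected to the new experiment through the commensurate predictive
#' distribution: `w * b01/(a01 - 1) + (1 - w) * b02/(a02 - 1)`. This is the
#' exact variance of the two-component t-mixture predictive distribution
#' (see [predictive_density()]), which the moment-matched normal
#' approximation adopts.
#'
#' @param w Incommensurability weight(s) in \[0, 1\]; vectorized.
#' @param spec A [commensurate_spec()].
#' @return Positive inflation value(s), same length as `w`.
#' @export
predictive_inflation <- function(w, spec = commensurate_spec()) {
  .check_spec(spec)
  if (any(w < 0 | w > 1)) stop("'w' must lie in [0, 1]", call. = FALSE)
  w * spec$b01 / (spec$a01 - 1) + (1 - w) * spec$b02 / (spec$a02 - 1)
}

#' Commensurate predictive density (t mixture)
#'
#' Density of the projected effect given a source's location: a
#' two-component mixture of nonstandardized t distributions with common
#' location, mixture weights `(w, 1 - w)`, degrees of freedom `2*a01` and
#' `2*a02`, and scale parameters `sqrt(b01/a01)` and `sqrt(b02/a02)`. This
#' is the marginal of `N(location, 1/nu)` after integrating the Gamma
#' mixture prior on the precision `nu`.
#'
#' @param x Evaluation point(s).
#' @param location The source's effect location (theta_k).
#' @param w Incommensurability weight in \[0, 1\].
#' @param spec A [commensurate_spec()].
#' @return Density values at `x`.
#' @export
predictive_density <- function(x, location, w, spec = commensurate_spec()) {
  .check_spec(spec)
  if (w < 0 || w > 1) stop("'w' must lie in [0, 1]", call. = FALSE)
  s1 <- sqrt(spec$b01 / spec$a01)
  s2 <- sqrt(spec$b02 / spec$a02)
  w * stats::dt((x - location) / s1, df = 2 * spec$a01) / s1 +
    (1 - w) * stats::dt((x - location) / s2, df = 2 * spec$a02) / s2
}

# CDF of the predictive t mixture (used by the approximation diagnostic)
.predictive_cdf <- function(x, location, w, spec) {
  s1 <- sqrt(spec$b01 / spec$a01)
  s2 <- sqrt(spec$b02 / spec$a02)
  w * stats::pt((x - location) / s1, df = 2 * spec$a01) +
    (1 - w) * stats::pt((x - location) / s2, df = 2 * spec$a02)
}

#' Accuracy of the normal approximation to the predictive t mixture
#'
#' Compares the exact two-component t-mixture predictive density with its
#' moment-matched normal approximation `N(location, predictive_inflation(w))`
#' on a dense grid (location +/- 12 combined scales, 4001 points, locally
#' refined around the largest discrepancy). Reports the sup-norm distance
#' between the densities and the Kolmogorov distance between the CDFs.
#'
#' @param w Incommensurability weight in \[0, 1\].
#' @param spec A [commensurate_spec()].
#' @param location Common location of both distributions (does not affect
#'   the distances; default 0).
#' @param n_grid Number of grid points (default 4001).
#' @return A list with elements `sup_norm`, `kolmogorov`, `grid_range` and
#'   `n_grid`.
#' @export
normal_approximation_error <- function(w, spec = commensurate_spec(),
                                       location = 0, n_grid = 4001) {
  .check_spec(spec)
  if (w < 0 || w > 1) stop("'w' must lie in [0, 1]", call. = FALSE)
  v <- predictive_inflation(w, spec)
  half <- 12 * sqrt(max(v, spec$b01 / spec$a01, spec$b02 / spec$a02))
  grid <- seq(location - half, location + half, length.out = n_grid)
  dens_gap <- function(x) {
    abs(predictive_density(x, location, w, spec) -
          stats::dnorm(x, location, sqrt(v)))
  }
  cdf_gap <- function(x) {
    abs(.predictive_cdf(x, location, w, spec) -
          stats::pnorm(x, location, sqrt(v)))
  }
  refine <- function(gap) {
    g <- gap(grid)
    i <- which.max(g)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, n_grid)]
    max(g, gap(seq(lo, hi, length.out = 201L)))
  }
  list(sup_norm = refine(dens_gap), kolmogorov = refine(cdf_gap),
       grid_range = range(grid), n_grid = n_grid)
}

#' Synthesis weights from incommensurability weights
#'
#' Softmax-type weights `p_k = exp(-w_k^2 / s0) / sum_j exp(-w_j^2 / s0)`
#' that set the relative importance of each source in the collective prior.
#' They are strictly decreasing in `w_k`: sources believed more
#' incommensurate are discounted more. As `s0 -> Inf` all `p_k -> 1/K`; as
#' `s0 -> 0+` the source(s) with the smallest `w_k` take all the weight
#' (ties split equally).
#'
#' @param w Numeric vector of incommensurability weights in \[0, 1\].
#' @param s0 Concentration parameter; positive.
#' @return A weight vector of the same length summing to 1.
#' @examples
#' synthesis_weights(c(0.15, 0.20, 0.17, 0.13, 0.20), s0 = 0.05)
#' @export
synthesis_weights <- function(w, s0 = 0.05) {
  if (length(w) < 1L) stop("'w' must have at least one element", call. = FALSE)
  if (any(w < 0 | w > 1)) stop("'w' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0) {
    stop("'s0' must be a single positive number", call. = FALSE)
  }
  # subtract the max exponent for numerical stability at tiny s0
  e <- -w^2 / s0
  e <- exp(e - max(e))
  e / sum(e)
}

#' Collective prior for the mean difference
#'
#' Synthesizes K commensurate predictive priors into the normal collective
#' prior `N(sum p_k * lambda_k, sum p_k^2 * xi_k^2)` for the mean
#' difference in the new experiment, with `lambda_k = m_k`,
#' `xi_k^2 = s_k^2 + predictive_inflation(w_k)` and `p_k` from
#' [synthesis_weights()].
#'
#' @param sources A list of [historical_summary()] objects (K >= 1), or a
#'   data frame accepted by [as_historical_summaries()].
#' @param spec A [commensurate_spec()].
#' @return An object of class `cpssd_collective` with elements `mean`,
#'   `variance` and `components` (a data frame with one row per source:
#'   `label`, `w`, `p`, `lambda`, `xi2`).
#' @examples
#' src <- as_historical_summaries(data.frame(
#'   mean = c(-0.26, -0.24, -0.37, -0.34, -0.32),
#'   variance = c(0.25, 0.23, 0.22, 0.36, 0.26),
#'   w = c(0.15, 0.20, 0.17, 0.13, 0.20)))
#' collective_prior(src)  # N(-0.309, 0.154)
#' @export
collective_prior <- function(sources, spec = commensurate_spec()) {
  .check_spec(spec)
  if (is.data.frame(sources)) sources <- as_historical_summaries(sources)
  if (inherits(sources, "cpssd_summary")) sources <- list(sources)
  if (length(sources) < 1L) stop("need at least one source", call. = FALSE)
  if (!all(vapply(sources, inherits, logical(1), "cpssd_summary"))) {
    stop("'sources' must be historical_summary objects", call. = FALSE)
  }
  m <- vapply(sources, `[[`, numeric(1), "mean")
  s2 <- vapply(sources, `[[`, numeric(1), "variance")
  w <- vapply(sources, `[[`, numeric(1), "weight")
  lab <- vapply(sources, `[[`, character(1), "label")
  p <- synthesis_weights(w, spec$s0)
  xi2 <- s2 + predictive_inflation(w, spec)
  structure(
    list(mean = sum(p * m), variance = sum(p^2 * xi2),
         components = data.frame(label = lab, w = w, p = p,
                                 lambda = m, xi2 = xi2),
         spec = spec),
    class = "cpssd_collective"
  )
}

#' @export
print.cpssd_collective <- function(x, digits = 3, ...) {
  cat(sprintf("Collective prior: mu_Delta ~ N(%s, %s)  [K = %d sources]\n",
              format(x$mean, digits = digits),
              format(x$variance, digits = digits),
              nrow(x$components)))
  print(format(x$components, digits = digits), ...)
  invisible(x)
}

# accept either a cpssd_collective or a plain (mean, variance) prior
.as_prior <- function(prior) {
  if (inherits(prior, "cpssd_collective")) {
    return(list(mean = prior$mean, variance = prior$variance))
  }
  if (is.list(prior) && all(c("mean", "variance") %in% names(prior))) {
    if (prior$variance <= 0) stop("prior variance must be positive", call. = FALSE)
    return(list(mean = prior$mean, variance = prior$variance))
  }
  if (is.numeric(prior) && length(prior) == 2L) {
    if (prior[2] <= 0) stop("prior variance must be positive", call. = FALSE)
    return(list(mean = prior[1], variance = prior[2]))
  }
  stop("'prior' must be a collective_prior(), a list(mean=, variance=) or c(mean, variance)",
       call. = FALSE)
}

#' Export a collective prior as a JSON record
#'
#' @param prior A `cpssd_collective` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
collective_prior_json <- function(prior, path = NULL) {
  stopifnot(inherits(prior, "cpssd_collective"))
  rec <- list(mean = prior$mean, variance = prior$variance,
              components = prior$components,
              spec = unclass(prior$spec))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
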