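test_that("predictive inflation matches single-component and moment-matched values", {
  spec <- commensurate_spec(2, 2, 18, 3)
  expect_equal(predictive_inflation(1, spec), 2.0)
  expect_equal(predictive_inflation(0, spec), 3 / 17)
  expect_equal(predictive_inflation(0.15, spec), 0.45)
})

test_that("inflation equals the exact variance of the predictive t mixture", {
  spec <- commensurate_spec(2, 2, 18, 3)
  for (w in c(0, 0.15, 0.5, 1)) {
    m2 <- integrate(function(x) x^2 * predictive_density(x, 0, w, spec),
                    -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(m2, predictive_inflation(w, spec), tolerance = 1e-7)
  }
})

test_that("predictive t-mixture density is symmetric, normalized and matches its generative model", {
  spec <- commensurate_spec(2, 2, 18, 3)
  theta <- -0.3
  w <- 0.4
  delta <- c(0.1, 0.7, 2.3)
  expect_equal(predictive_density(theta + delta, theta, w, spec),
               predictive_density(theta - delta, theta, w, spec))
  expect_lt(abs(integrate(function(x) predictive_density(x, theta, w, spec),
                          -Inf, Inf, rel.tol = 1e-9)$value - 1), 1e-6)
  # simulation oracle: theta_tilde ~ N(theta, 1/nu), nu ~ Gamma mixture
  set.seed(42)
  n <- 1e6
  comp <- runif(n) < w
  nu <- ifelse(comp, rgamma(n, spec$a01, rate = spec$b01),
               rgamma(n, spec$a02, rate = spec$b02))
  draws <- rnorm(n, theta, 1 / sqrt(nu))
  # decile bin edges of the analytic mixture; each bin should hold 10%
  qs <- sapply(seq(0.1, 0.9, by = 0.1), function(p) {
    uniroot(function(x) {
      integrate(function(y) predictive_density(y, theta, w, spec),
                -Inf, x, rel.tol = 1e-9)$value - p
    }, c(theta - 60, theta + 60), tol = 1e-10)$root
  })
  obs <- diff(c(0, ecdf(draws)(qs), 1))
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(max(abs(obs - 0.1)), 3 * se)
})

test_that("synthesis weights reproduce the printed five-source weights", {
  p <- synthesis_weights(c(0.15, 0.20, 0.17, 0.13, 0.20), s0 = 0.05)
  expect_equal(round(p, 2), c(0.23, 0.16, 0.20, 0.25, 0.16))
  p1 <- synthesis_weights(c(0.103, 0.175, 0.081, 0.143, 0.077), s0 = 0.05)
  expect_equal(round(p1, 3), c(0.214, 0.143, 0.232, 0.176, 0.235))
})

test_that("synthesis weights: symmetry, monotonicity and s0 limits", {
  expect_equal(synthesis_weights(rep(0.3, 4), s0 = 0.7), rep(0.25, 4))
  w <- c(0.1, 0.4, 0.25)
  p <- synthesis_weights(w, s0 = 0.05)
  expect_equal(sum(p), 1)
  expect_true(all(diff(p[order(w)]) < 0))       # smaller w -> larger p
  expect_equal(synthesis_weights(w, s0 = 1e9), rep(1 / 3, 3), tolerance = 1e-6)
  p0 <- synthesis_weights(w, s0 = 1e-6)
  expect_equal(p0[1], 1, tolerance = 1e-9)      # arg-min w dominates
  pt <- synthesis_weights(c(0.2, 0.2, 0.9), s0 = 1e-6)
  expect_equal(pt[1:2], c(0.5, 0.5), tolerance = 1e-9)  # ties split equally
})

test_that("collective prior reproduces the five-expert synthesis", {
  pr <- collective_prior(expert5_sources())
  expect_equal(round(pr$mean, 3), -0.309)
  expect_equal(round(pr$variance, 3), 0.154)
  expect_equal(sum(pr$components$p), 1, tolerance = 1e-12)
  expect_equal(sum(pr$components$p^2 * pr$components$xi2), pr$variance,
               tolerance = 1e-12)
  expect_true(all(pr$components$xi2 >=
                    vapply(expert5_sources(), `[[`, numeric(1), "variance")))
})

test_that("single-source collective prior with w = 0 adds only the borrowing inflation", {
  spec <- commensurate_spec(2, 2, 18, 3)
  pr <- collective_prior(list(historical_summary(0.5, 0.2, weight = 0)), spec)
  expect_equal(pr$mean, 0.5)
  expect_equal(pr$variance, 0.2 + 3 / 17)
})

test_that("per-source predictive variances are bounded by the two component inflations", {
  spec <- commensurate_spec(2, 2, 18, 3)
  lo <- min(2, 3 / 17); hi <- max(2, 3 / 17)
  for (w in seq(0, 1, by = 0.25)) {
    pr <- collective_prior(list(historical_summary(0, 0.3, weight = w)), spec)
    xi2 <- pr$components$xi2
    expect_gte(xi2, 0.3 + lo - 1e-12)
    expect_lte(xi2, 0.3 + hi + 1e-12)
  }
  expect_equal(collective_prior(list(historical_summary(0, 0.3, weight = 1)),
                                spec)$components$xi2, 0.3 + 2)
  expect_equal(collective_prior(list(historical_summary(0, 0.3, weight = 0)),
                                spec)$components$xi2, 0.3 + 3 / 17)
})

test_that("robust weight set II inflates the collective variance over set I in every configuration", {
  priors <- all_config_priors()
  for (cf in paste0("config", 1:4)) {
    expect_gt(priors[[paste0(cf, "_RWII")]]$variance,
              priors[[paste0(cf, "_RWI")]]$variance)
  }
})

test_that("hyperparameter validation: shapes must exceed 1; inverted components warn", {
  expect_error(commensurate_spec(a01 = 1), "exceed 1")
  expect_error(commensurate_spec(a02 = 0.5), "exceed 1")
  expect_error(commensurate_spec(b01 = -1), "positive")
  expect_warning(commensurate_spec(2, 0.1, 18, 3), "inverts")
})

test_that("Hellinger distance matches its closed form and quadrature", {
  a <- c(0, 1); b <- c(1, 1)
  expect_equal(hellinger_distance(a, a), 0)
  expect_equal(hellinger_distance(a, b), hellinger_distance(b, a))
  expect_equal(hellinger_distance(a, b), sqrt(1 - exp(-1 / 8)))
  # quadrature oracle: H^2 = 1 - int sqrt(f g)
  pairs <- list(list(c(0, 1), c(1, 1)), list(c(-0.3, 0.25), c(0.1, 0.6)),
                list(c(2, 4), c(2, 0.5)))
  for (pp in pairs) {
    bc <- integrate(function(x) {
      sqrt(dnorm(x, pp[[1]][1], sqrt(pp[[1]][2])) *
             dnorm(x, pp[[2]][1], sqrt(pp[[2]][2])))
    }, -Inf, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(hellinger_distance(pp[[1]], pp[[2]]) - sqrt(1 - bc)), 1e-8)
  }
  m <- hellinger_matrix(expert5_sources())
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 5), ignore_attr = TRUE)
})

test_that("normal approximation diagnostic shrinks as the t components approach normality", {
  spec_heavy <- commensurate_spec(2, 2, 18, 3)
  d_heavy <- normal_approximation_error(0.5, spec_heavy)
  expect_gte(d_heavy$sup_norm, 0)
  expect_gte(d_heavy$kolmogorov, 0)
  # dof -> Inf limit: Gamma(50, 50 v) components are near-degenerate
  spec_light <- commensurate_spec(50, 50 * 2, 60, 60 * 0.2)
  d_light <- normal_approximation_error(1, spec_light)
  expect_lt(d_light$kolmogorov, d_heavy$kolmogorov)
  expect_lt(d_light$kolmogorov, 0.01)
})

test_that("normal approximation diagnostic agrees with an independent dense-grid oracle", {
  spec <- commensurate_spec(2, 2, 18, 3)
  d <- normal_approximation_error(0.5, spec)
  v <- predictive_inflation(0.5, spec)
  grid <- seq(-25, 25, length.out = 200001)
  s1 <- sqrt(2 / 2); s2 <- sqrt(3 / 18)
  ft <- 0.5 * dt(grid / s1, 4) / s1 + 0.5 * dt(grid / s2, 36) / s2
  Ft <- 0.5 * pt(grid / s1, 4) + 0.5 * pt(grid / s2, 36)
  expect_lt(abs(d$sup_norm - max(abs(ft - dnorm(grid, 0, sqrt(v))))), 1e-6)
  expect_lt(abs(d$kolmogorov - max(abs(Ft - pnorm(grid, 0, sqrt(v))))), 1e-6)
})
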