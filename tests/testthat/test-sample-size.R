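test_that("effective size and its inversion under an allocation ratio", {
  expect_equal(effective_size(21, 21), 10.5)
  expect_equal(effective_size(10, 30), 7.5)
  for (e in c(3.7, 10.5, 48)) for (R in c(0.5, 1, 2.4)) {
    g <- groups_from_effective(e, R)
    expect_equal(effective_size(g$n_A, g$n_B), e, tolerance = 1e-12)
    expect_equal(g$n_B / g$n_A, R, tolerance = 1e-12)
  }
  expect_error(effective_size(0, 5), "positive")
})

test_that("known-variance ACC reproduces the five-expert total and its limits", {
  pr <- collective_prior(expert5_sources())
  res <- acc_known(pr, l0 = 0.65, alpha = 0.05, sigma0_sq = 0.35)
  expect_equal(round(res$continuous_total, 1), 41.8)
  expect_false(res$binding)
  # prior informative enough: zero with binding flag
  tight <- list(mean = 0, variance = 0.001)
  res0 <- acc_known(tight, 0.65, 0.05, 0.35)
  expect_true(res0$binding)
  expect_equal(res0$continuous_total, 0)
  # vague-prior limit recovers the classical CI-width formula
  vague <- list(mean = 0, variance = 1e12)
  resv <- acc_known(vague, 0.65, 0.05, 0.35)
  expect_equal(resv$continuous_total, 16 * qnorm(0.975)^2 * 0.35 / 0.65^2,
               tolerance = 1e-6)
})

test_that("known-variance ALC delegates exactly to the ACC", {
  set.seed(3)
  for (i in 1:3) {
    pr <- list(mean = rnorm(1), variance = runif(1, 0.05, 0.5))
    l <- runif(1, 0.3, 1); a <- runif(1, 0.01, 0.2); s2 <- runif(1, 0.2, 1)
    R <- sample(c(0.5, 1, 2), 1)
    acc <- acc_known(pr, l, a, s2, R)
    alc <- alc_known(pr, l, a, s2, R)
    expect_identical(alc$continuous_total, acc$continuous_total)
    expect_identical(alc$integer_total, acc$integer_total)
    expect_identical(alc$criterion, "alc")
  }
})

test_that("known-variance APVC matches a root-finding oracle and scales linearly in the variance", {
  pr <- collective_prior(expert5_sources())
  V <- pr$variance
  res <- apvc_known(pr, eps0 = 0.03, sigma0_sq = 0.35)
  expect_equal(res$continuous_total, 4 * 0.35 * (1 / 0.03 - 1 / V),
               tolerance = 1e-12)
  # oracle: solve posterior variance(N) = eps0 numerically
  oracle <- uniroot(function(N) {
    posterior_known_variance(pr, 0, design_spec(N / 2), 0.35)$variance - 0.03
  }, c(1, 1e4), tol = 1e-10)$root
  expect_equal(res$continuous_total, oracle, tolerance = 1e-6)
  expect_equal(apvc_known(pr, 0.03, 0.70)$continuous_total,
               2 * res$continuous_total, tolerance = 1e-12)
  expect_true(apvc_known(pr, eps0 = V + 0.01, sigma0_sq = 0.35)$binding)
})

test_that("variance prior anchored to the collective prior has the stated inverse-gamma form", {
  pr <- collective_prior(expert5_sources())
  vp <- variance_prior_from_collective(pr, 5)
  expect_equal(vp$c / 2, 2.5)
  expect_equal(round(vp$scale, 3), 0.385)
  expect_equal(cpssd:::.e_sigma0_sq(variance_prior_from_collective(pr, 3)),
               3 * pr$variance)
  expect_equal(cpssd:::.e_sigma0_sq(variance_prior_from_collective(pr, 1e9)),
               pr$variance, tolerance = 1e-6)
})

test_that("unknown-variance ACC reproduces the printed totals and the c -> Inf limit", {
  pr <- collective_prior(expert5_sources())
  res <- acc_unknown(pr, 0.65, 0.05, variance_prior_from_collective(pr, 5))
  expect_equal(round(res$continuous_total, 1), 30.7)
  tab <- config_table()
  pr3 <- collective_prior(sources_from(tab$config3$m, tab$config3$s2,
                                       tab$config3$wI))
  res3 <- acc_unknown(pr3, 0.65, 0.05, variance_prior_from_collective(pr3, 3))
  expect_lt(abs(res3$continuous_total - 116.8), 0.2)
  # degenerate variance prior recovers the known-variance solution at V
  lim <- acc_unknown(pr, 0.65, 0.05, variance_prior_from_collective(pr, 1e6))
  ref <- acc_known(pr, 0.65, 0.05, pr$variance)
  expect_equal(lim$continuous_total, ref$continuous_total, tolerance = 1e-4)
  expect_error(acc_unknown(pr, 0.65, 0.05,
                           variance_prior_from_collective(pr, 2)), "c > 2")
})

test_that("unknown-variance ALC search returns the smallest admissible total", {
  pr <- collective_prior(expert5_sources())
  vp5 <- variance_prior_from_collective(pr, 5)
  res <- alc_unknown(pr, 0.65, 0.05, vp5)
  expect_equal(res$integer_total, 24)
  # boundary: criterion holds at N, fails at N - step
  expect_lte(res$diagnostics$avg_length_at_N, 0.65)
  expect_gt(res$diagnostics$avg_length_below, 0.65)
  tab <- config_table()
  pr3 <- collective_prior(sources_from(tab$config3$m, tab$config3$s2,
                                       tab$config3$wI))
  expect_equal(alc_unknown(pr3, 0.65, 0.05,
                           variance_prior_from_collective(pr3, 3))$integer_total,
               65)
  # near-degenerate variance prior: within one step of the known-variance ACC
  lim <- alc_unknown(pr, 0.65, 0.05, variance_prior_from_collective(pr, 1e6))
  ref <- acc_known(pr, 0.65, 0.05, pr$variance)
  expect_lte(abs(lim$integer_total - ceiling(ref$continuous_total)), 1)
})

test_that("unknown-variance APVC reproduces the printed total and its limits", {
  pr <- collective_prior(expert5_sources())
  res <- apvc_unknown(pr, 0.03, variance_prior_from_collective(pr, 5))
  expect_equal(round(res$continuous_total, 1), 27.6)
  expect_true(apvc_unknown(pr, pr$variance + 0.01,
                           variance_prior_from_collective(pr, 5))$binding)
  lim <- apvc_unknown(pr, 0.03, variance_prior_from_collective(pr, 1e6))
  ref <- apvc_known(pr, 0.03, pr$variance)
  expect_equal(lim$continuous_total, ref$continuous_total, tolerance = 1e-4)
})

test_that("continuous totals respond monotonically to the targets", {
  pr <- collective_prior(expert5_sources())
  vp <- variance_prior_from_collective(pr, 5)
  acc_l <- sapply(c(0.5, 0.65, 0.8), function(l0) {
    acc_unknown(pr, l0, 0.05, vp)$continuous_total
  })
  expect_true(all(diff(acc_l) < 0))
  acc_a <- sapply(c(0.10, 0.05, 0.025), function(a) {
    acc_unknown(pr, 0.65, a, vp)$continuous_total
  })
  expect_true(all(diff(acc_a) > 0))            # higher coverage, more subjects
  apvc_e <- sapply(c(0.02, 0.03, 0.05), function(e0) {
    apvc_unknown(pr, e0, vp)$continuous_total
  })
  expect_true(all(diff(apvc_e) < 0))
})

test_that("unknown-variance totals decrease in the variance-prior degrees of freedom", {
  priors <- all_config_priors()
  cs <- c(3, 5, 10, 20, 40)
  for (nm in c("config1_RWI", "config3_RWII")) {
    pr <- priors[[nm]]
    acc <- sapply(cs, function(cc) {
      acc_unknown(pr, 0.65, 0.05,
                  variance_prior_from_collective(pr, cc))$continuous_total
    })
    expect_true(all(diff(acc) < 0))
    alc <- sapply(cs, function(cc) {
      alc_unknown(pr, 0.65, 0.05,
                  variance_prior_from_collective(pr, cc))$integer_total
    })
    expect_true(all(diff(alc) <= 0))
  }
})

test_that("the ALC total never exceeds the ACC total at matching targets (unknown variance)", {
  priors <- all_config_priors()
  for (pr in priors) for (cc in c(3, 5)) {
    vp <- variance_prior_from_collective(pr, cc)
    acc <- acc_unknown(pr, 0.65, 0.05, vp)
    alc <- alc_unknown(pr, 0.65, 0.05, vp)
    expect_lte(alc$integer_total, ceiling(acc$continuous_total))
  }
})

test_that("robust totals are bounded by no-robustification and no-borrowing", {
  tab <- config_table()
  for (cf in names(tab)) for (ws in c("wI", "wII")) {
    src <- sources_from(tab[[cf]]$m, tab[[cf]]$s2, tab[[cf]][[ws]])
    cm <- comparison_modes(src, criterion = "acc", variance = "unknown",
                           c = 3, l0 = 0.65, alpha = 0.05)
    tot <- setNames(cm$continuous_total, cm$mode)
    expect_gte(tot["robust"], tot["no_robustification"])
    expect_lte(tot["robust"], tot["no_borrowing"])
  }
})

test_that("comparison modes reproduce the no-borrowing and benchmark totals", {
  tab <- config_table()
  src <- sources_from(tab$config3$m, tab$config3$s2, tab$config3$wI)
  cm <- comparison_modes(src, criterion = "acc", variance = "unknown",
                         c = 3, l0 = 0.65, alpha = 0.05)
  tot <- setNames(cm$continuous_total, cm$mode)
  expect_lt(abs(tot["no_borrowing"] - 232.2), 0.2)
  expect_lt(abs(tot["robust"] - 116.8), 0.2)
  # known-variance optimal mode equals acc_known at sigma0^2 = V
  cmk <- comparison_modes(src, criterion = "acc", variance = "known",
                          sigma0_sq = 0.35, l0 = 0.65, alpha = 0.05)
  pr <- collective_prior(src)
  expect_equal(cmk$continuous_total[cmk$mode == "optimal"],
               acc_known(pr, 0.65, 0.05, pr$variance)$continuous_total)
})
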