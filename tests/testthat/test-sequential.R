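# Bayes factor, sequential Bayesian checker, SPRT baseline

# independent oracle: the partial prior-weighted likelihood integrals of
# the Bayes factor, by adaptive quadrature
bf_quadrature <- function(n, z, theta, eps1, eps2, a = 1, b = 1) {
  integrand <- function(u) u^z * (1 - u)^(n - z) * stats::dbeta(u, a, b)
  num <- stats::integrate(integrand, theta + eps2, 1,
                          rel.tol = 1e-11, abs.tol = 0)$value
  den <- stats::integrate(integrand, 0, theta - eps1,
                          rel.tol = 1e-11, abs.tol = 0)$value
  num / den
}

test_that("closed-form Bayes factor matches quadrature and known values", {
  # I_x(k, 1) = x^k gives B = (1 - 0.6^7) / 0.4^7 for six straight successes
  expect_equal(bayes_factor(6, 6, 0.5, 0.1, 0.1), (1 - 0.6^7) / 0.4^7,
               tolerance = 1e-12)
  expect_equal(bayes_factor(6, 6, 0.5, 0.1, 0.1), 593.2656,
               tolerance = 1e-6)
  # no data splits the prior mass at the region boundaries
  expect_equal(bayes_factor(0, 0, 0.5, 1e-9, 1e-9), 1, tolerance = 1e-6)
  # spot grid against the quadrature oracle
  for (n in c(3, 11, 30)) for (z in unique(c(0, n %/% 2, n)))
    for (ab in list(c(1, 1), c(2, 2), c(5, 1)))
      expect_equal(bayes_factor(n, z, 0.4, 0.05, 0.1, beta_prior(ab[1], ab[2])),
                   bf_quadrature(n, z, 0.4, 0.05, 0.1, ab[1], ab[2]),
                   tolerance = 1e-8)
  expect_error(bayes_factor(3, 4, 0.5, 0.1, 0.1))
})

test_that("Bayes factor is strictly increasing in the success count", {
  for (n in c(5, 18, 30)) {
    bs <- vapply(0:n, function(z)
      bayes_factor(n, z, 0.5, 0.1, 0.1, log10 = TRUE), numeric(1))
    expect_true(all(diff(bs) > 0))
  }
})

test_that("degenerate indifference bounds flag vacuous hypotheses", {
  b_inf <- bayes_factor(4, 2, 0.05, 0.05, 0.05)   # theta - eps1 = 0
  expect_identical(as.numeric(b_inf), Inf)
  expect_true(attr(b_inf, "vacuous"))
  b_zero <- bayes_factor(4, 2, 0.95, 0.05, 0.05)  # theta + eps2 = 1
  expect_identical(as.numeric(b_zero), 0)
  # a vacuous alternative forces immediate acceptance in the checker
  res <- bsmc_verify(bernoulli_sampler(0.5), pbltl_spec("a", 0.05),
                     eps = indifference(0.05), seed = 1)
  expect_identical(res$decision, "accept_H0")
  expect_identical(res$n, 1L)
  expect_true(res$vacuous)
})

test_that("tabulated priors reproduce the conjugate computation", {
  grid <- seq(0, 1, length.out = 4001)
  tab <- tabulated_prior(grid, stats::dbeta(grid, 2, 2))
  for (nz in list(c(8, 5), c(20, 9))) {
    expect_equal(
      bayes_factor(nz[1], nz[2], 0.5, 0.1, 0.1, tab),
      bayes_factor(nz[1], nz[2], 0.5, 0.1, 0.1, beta_prior(2, 2)),
      tolerance = 1e-4)
  }
  expect_error(tabulated_prior(c(0, 1), c(0, 0)), "zero mass")
})

test_that("sequential stopping matches the closed-form trajectories", {
  spec <- pbltl_spec("a", 0.5)
  # all-satisfying: B_n = (1 - 0.6^(n+1)) / 0.4^(n+1) first exceeds 100
  # at n = 5 (B_4 = 90.06, B_5 = 232.75)
  res <- bsmc_verify(function(s) TRUE, spec, L = 100,
                     eps = indifference(0.1), seed = 1)
  expect_identical(res$decision, "accept_H0")
  expect_identical(c(res$n, res$z), c(5L, 5L))
  expect_equal(res$trajectory,
               log10((1 - 0.6^(1:5 + 1)) / 0.4^(1:5 + 1)), tolerance = 1e-10)
  expect_true(res$satisfied)

  # never-satisfying mirrors it: B_n = 0.4^(n+1) / (1 - 0.6^(n+1))
  res0 <- bsmc_verify(function(s) FALSE, spec, L = 100,
                      eps = indifference(0.1), seed = 1)
  expect_identical(res0$decision, "reject_H0")
  expect_identical(c(res0$n, res0$z), c(5L, 0L))
  expect_false(res0$satisfied)
})

test_that("SPRT stopping matches the hand-iterated likelihood ratio", {
  spec <- pbltl_spec("a", 0.5)
  # Lambda_n = (2/3)^n crosses beta/(1-alpha) = 1/99 first at n = 12
  res <- sprt_verify(function(s) TRUE, spec, eps = indifference(0.1),
                     alpha = 0.01, beta = 0.01, seed = 1)
  expect_identical(res$decision, "accept_H0")
  expect_identical(res$n, 12L)
  expect_equal(res$trajectory, (1:12) * log10(2 / 3), tolerance = 1e-10)
  # symmetric bound for the never-satisfying sampler at the same n
  res0 <- sprt_verify(function(s) FALSE, spec, eps = indifference(0.1),
                      alpha = 0.01, beta = 0.01, seed = 1)
  expect_identical(res0$decision, "reject_H0")
  expect_identical(res0$n, 12L)
  expect_error(sprt_verify(function(s) TRUE, pbltl_spec("a", 0.05),
                           eps = indifference(0.05)), "SPRT needs")
})

test_that("budget exhaustion is a distinct outcome, never a decision", {
  res <- bsmc_verify(bernoulli_sampler(0.5), pbltl_spec("a", 0.5),
                     eps = indifference(0.01), max_samples = 30, seed = 4)
  expect_identical(res$decision, "budget_exhausted")
  expect_true(is.na(res$satisfied))
  expect_identical(res$n, 30L)
  expect_length(res$trajectory, 30)
})

test_that("checker runs are reproducible from the master seed", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.7)
  sampler <- trace_sampler(fx$model, c(p = 0.8), 1)
  a <- bsmc_verify(sampler, spec, eps = indifference(0.05), seed = 31)
  b <- bsmc_verify(sampler, spec, eps = indifference(0.05), seed = 31)
  expect_identical(a[c("decision", "n", "z", "trajectory")],
                   b[c("decision", "n", "z", "trajectory")])
  d <- bsmc_verify(sampler, spec, eps = indifference(0.05), seed = 32)
  expect_false(identical(a$trajectory, d$trajectory))
})

test_that("checker monitors real traces end to end", {
  fx <- build_fixture("bernoulli")
  res <- bsmc_verify(trace_sampler(fx$model, c(p = 1), 1),
                     pbltl_spec(fx$formula, 0.5), L = 100,
                     eps = indifference(0.1), seed = 2)
  expect_identical(res$decision, "accept_H0")
  expect_identical(res$n, 5L)
  expect_identical(res$z, 5L)
})

test_that("decisions are correct when u is well outside the region", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.7)
  runs <- 60
  acc <- vapply(seq_len(runs), function(s)
    bsmc_verify(trace_sampler(fx$model, c(p = 0.9), 1), spec,
                eps = indifference(0.05), seed = s * 13L)$decision,
    character(1))
  expect_gte(mean(acc == "accept_H0"), 0.95)
  rej <- vapply(seq_len(runs), function(s)
    bsmc_verify(trace_sampler(fx$model, c(p = 0.5), 1), spec,
                eps = indifference(0.05), seed = s * 13L)$decision,
    character(1))
  expect_gte(mean(rej == "reject_H0"), 0.95)
})

test_that("sample-count profiles report grid, truth and decision mix", {
  fx <- build_fixture("bernoulli")
  prof <- sample_count_profile(fx, 0.5, c(0.2, 0.5, 0.8), runs = 25,
                               max_samples = 200, seed = 6)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$u, c(0.2, 0.5, 0.8))
  expect_true(all(c("mean_n", "sd_n", "accept_frac", "budget_frac") %in%
                    names(prof)))
  # the near-threshold point costs the most samples
  expect_identical(which.max(prof$mean_n), 2L)
  # budget exhaustion concentrates at u = theta when the region is tiny
  tight <- sample_count_profile(fx, 0.5, c(0.2, 0.5, 0.8), runs = 20,
                                eps = indifference(0.01), max_samples = 80,
                                seed = 7)
  expect_identical(which.max(tight$budget_frac), 2L)
})

test_that("raising the stopping threshold never cheapens the test", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.5)
  sampler <- trace_sampler(fx$model, c(p = 0.75), 1)
  n_at <- function(L) mean(vapply(1:60, function(s)
    bsmc_verify(sampler, spec, L = L, eps = indifference(0.1),
                seed = s * 11L)$n, numeric(1)))
  expect_gte(n_at(200), n_at(100))
})
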