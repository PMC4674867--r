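# simulated-annealing parameter search over checker sample counts

test_that("annealing schedules are strictly decreasing and validated", {
  sch <- annealing_schedule(t_start = 10, t_stop = 1, gamma = 0.9)
  temps <- vapply(1:30, sch$Tfun, numeric(1))
  expect_true(all(diff(temps) < 0))
  expect_error(annealing_schedule(t_start = 0), "t_start > 0")
  expect_error(annealing_schedule(10, 20))
  expect_error(annealing_schedule(cooling = function(k) k), "decreasing")
  custom <- annealing_schedule(5, 1, cooling = function(k) 5 / (k + 1))
  expect_equal(custom$Tfun(4), 1)
})

test_that("neighbors stay in bounds and follow the Gaussian kernel", {
  sp <- parameter_space("x", 0, 1)
  # degenerate scale: the neighbor is the point itself
  expect_equal(neighbor(c(x = 0.37), sp, neighborhood_policy(scale = 0)),
               c(x = 0.37))
  # moment check of the perturbation kernel at scale 0.1
  set.seed(408)
  draws <- replicate(1e4, neighbor(c(x = 0.5), sp,
                                   neighborhood_policy(scale = 0.1))[["x"]])
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.1 / sqrt(1e4))
  expect_lt(abs(sd(draws) - 0.1), 0.01)
  # boundary points clip back into the box
  set.seed(409)
  lo <- replicate(500, neighbor(c(x = 0), sp,
                                neighborhood_policy(scale = 0.3))[["x"]])
  expect_true(all(lo >= 0 & lo <= 1))
  # one-coordinate mode leaves the other coordinates untouched
  sp2 <- parameter_space(c("x", "y"), c(0, 0), c(1, 1))
  set.seed(410)
  moved <- replicate(200, {
    nb <- neighbor(c(x = 0.5, y = 0.5), sp2,
                   neighborhood_policy(scale = 0.1, mode = "one"))
    sum(nb != c(0.5, 0.5))
  })
  expect_true(all(moved <= 1))
})

test_that("move acceptance is greedy uphill and Metropolis downhill", {
  expect_true(accept_move(30, 50, temperature = 1e-9))
  # ties are accepted with probability exp(0) = 1
  set.seed(411)
  expect_true(all(replicate(100, accept_move(40, 40, 5))))
  # downhill acceptance frequency matches exp(-(n - n') / t)
  set.seed(412)
  frac <- mean(replicate(1e4, accept_move(100, 80, 10)))
  p <- exp(-2)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1e4))
  # hotter temperatures tolerate worse moves more often
  set.seed(413)
  cold <- mean(replicate(2000, accept_move(100, 80, 4)))
  hot <- mean(replicate(2000, accept_move(100, 80, 40)))
  expect_gt(hot, cold)
})

test_that("a family satisfying the spec everywhere is found immediately", {
  fx <- build_fixture("bernoulli")
  sat_family <- list(space = fx$space,
                     sample = function(omega, horizon, seed) TRUE)
  fit <- synthesize(sat_family, pbltl_spec(fx$formula, 0.5),
                    eps = indifference(0.1), seed = 5)
  expect_identical(fit$status, "found")
  expect_identical(fit$checker_calls, 1L)
  expect_identical(nrow(fit$trajectory), 1L)
})

test_that("an unsatisfiable spec ends not_found with only rejections", {
  fx <- build_fixture("bernoulli")
  null_family <- list(space = fx$space,
                      sample = function(omega, horizon, seed) FALSE)
  fit <- synthesize(null_family, pbltl_spec(fx$formula, 0.9),
                    schedule = annealing_schedule(5, 1, gamma = 0.8),
                    eps = indifference(0.05), seed = 6)
  expect_identical(fit$status, "not_found")
  expect_null(fit$omega)
  expect_true(all(fit$trajectory$decision == "reject_H0"))
})

test_that("the trajectory log records every checker call, cooling as it goes", {
  fx <- build_fixture("bernoulli")
  fit <- synthesize(fx, pbltl_spec(fx$formula, 0.995),
                    schedule = annealing_schedule(10, 1, gamma = 0.8),
                    eps = indifference(0.004), max_samples = 50, seed = 7)
  expect_identical(nrow(fit$trajectory), fit$checker_calls)
  temps <- fit$trajectory$temperature[-1]   # initial check carries no temperature
  expect_true(all(diff(temps) < 0))
  # budget-exhausted calls contribute the cap as fitness, logged distinctly
  exhausted <- fit$trajectory$decision == "budget_exhausted"
  if (any(exhausted)) expect_true(all(fit$trajectory$n[exhausted] == 50))
})

test_that("synthesis is reproducible from its master seed", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.6)
  a <- synthesize(fx, spec, seed = 9, max_samples = 150)
  b <- synthesize(fx, spec, seed = 9, max_samples = 150)
  expect_identical(a$omega, b$omega)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("checker effort rises toward the threshold (the fitness premise)", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.8)
  mean_n <- function(p) {
    mean(vapply(1:200, function(s)
      bsmc_verify(trace_sampler(fx$model, c(p = p), 1), spec,
                  eps = indifference(0.05), max_samples = 500,
                  seed = s * 17L)$n, numeric(1)))
  }
  expect_gt(mean_n(0.7), mean_n(0.2))
})

test_that("found points re-verify on fresh seeds when truly satisfying", {
  fx <- build_fixture("bernoulli")
  spec <- pbltl_spec(fx$formula, 0.6)
  checked <- 0
  for (s in 101:120) {
    fit <- synthesize(fx, spec, seed = s, max_samples = 150)
    if (fit$status != "found" || fit$omega[["p"]] < 0.65) next
    checked <- checked + 1
    acc <- mean(vapply(1:20, function(r)
      bsmc_verify(trace_sampler(fx$model, fit$omega, 1), spec,
                  eps = indifference(0.05),
                  seed = 9000L + r)$decision == "accept_H0", logical(1)))
    expect_gte(acc, 0.9)
    if (checked >= 5) break
  }
  expect_gte(checked, 3)   # the family must actually produce such points
})

test_that("joint multi-spec synthesis requires every spec to accept", {
  fx <- build_fixture("bernoulli")
  specs <- list(pbltl_spec(fx$formula, 0.6),
                pbltl_spec("!success & success", 0.5))  # unsatisfiable partner
  fit <- synthesize(fx, specs,
                    schedule = annealing_schedule(5, 1, gamma = 0.7),
                    max_samples = 100, seed = 11)
  expect_identical(fit$status, "not_found")
  # both per-spec decisions are logged for every call
  expect_true(all(grepl("\\+", fit$trajectory$decision)))
})

test_that("synthesis results print, summarize and expose coefficients", {
  fx <- build_fixture("bernoulli")
  fit <- synthesize(fx, pbltl_spec(fx$formula, 0.6), seed = 42,
                    max_samples = 150)
  expect_identical(coef(fit), fit$omega)
  expect_output(print(fit), "parameter synthesis")
  expect_output(print(summary(fit)), "checker call")
})
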