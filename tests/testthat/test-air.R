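# acute inflammatory response demo: parameters, dynamics, specifications

test_that("the parameter roster has exactly the 28 canonical names", {
  nm <- air_parameter_names()
  expect_length(nm, 28)
  expect_false(anyDuplicated(nm) > 0)
  b <- air_default_bounds()
  expect_identical(b$names, nm)
  expect_true(all(b$lower < b$upper))
  expect_length(air_example_params(), 28)
  # evaporation fractions are genuine fractions over the whole box
  evap <- c("LPS-evap", "damage-evap", "anti-evap", "pro-evap")
  expect_true(all(b$upper[evap] <= 1))
})

test_that("the simulator rejects structurally invalid parameter vectors", {
  om <- air_example_params()
  expect_error(simulate_air(om[-1], 5), "lacks dimension")
  om_bad <- om; om_bad[["pro-evap"]] <- -0.1
  expect_error(simulate_air(om_bad, 5), "nonnegative")
  om_bad <- om; om_bad[["LPS-evap"]] <- 1.2
  expect_error(simulate_air(om_bad, 5), "\\[0, 1\\]")
})

test_that("zero dosing with zero insult keeps every observable at zero", {
  om <- air_example_params()
  om[grep("amount", names(om))] <- 0
  for (ex in 1:4) {
    tr <- as.data.frame(simulate_air(om, 40, experiment = ex, seed = 3))
    expect_identical(max(tr$LPS, tr$mac, tr$pro, tr$anti, tr$dam), 0)
    expect_false(any(tr$I))
  }
})

test_that("endotoxin decays geometrically once dosing and activation stop", {
  om <- air_example_params()
  om[c("mac-act-LPS", "mac-act-pro", "mac-act-dam")] <- 0
  tr <- as.data.frame(simulate_air(om, 30, experiment = 1,
                                   deterministic = TRUE))
  after <- (max(which(tr$dose > 0)) + 1):31
  lps <- tr$LPS[after]
  expect_equal(lps[-1], lps[-length(lps)] * (1 - om[["LPS-evap"]]),
               tolerance = 1e-9)
})

test_that("a larger dose never lowers the peak response (deterministic)", {
  peaks <- vapply(seq(2, 20, by = 2), function(amount) {
    om <- air_example_params()
    om[["exp1-dose-amount"]] <- amount
    max(as.data.frame(simulate_air(om, 40, experiment = 1,
                                   deterministic = TRUE))$pro)
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-9))
})

test_that("seeded runs are identical; deterministic mode ignores the seed", {
  om <- air_example_params()
  expect_identical(simulate_air(om, 20, seed = 9), simulate_air(om, 20, seed = 9))
  expect_identical(
    as.data.frame(simulate_air(om, 20, deterministic = TRUE, seed = 1)),
    as.data.frame(simulate_air(om, 20, deterministic = TRUE, seed = 2)))
})

test_that("spec thresholds validate their ordering constraints", {
  expect_error(spec_thresholds(dose_low = 60, dose_high = 50))
  expect_error(spec_thresholds(IL_level = 30, IH_level = 20))
  expect_error(spec_thresholds(delta = c(1, 2)))
  th <- spec_thresholds()
  expect_length(air_propositions(th), 7)
})

test_that("exactly the four behavioral specifications are encoded", {
  th <- spec_thresholds()
  specs <- encode_specs(th, theta = 0.8)
  expect_length(specs, 4)
  d <- th$delta
  expect_identical(specs[[1]]$formula,
                   parse_formula(sprintf("D_L -> F[%d](I & F[%d] N)",
                                         d[1], d[2])))
  expect_identical(specs[[2]]$formula,
                   parse_formula(sprintf("D_H -> F[%d](G[%d] I_H)",
                                         d[3], d[4])))
  # horizon of the third follows the nesting recursion: d5 + d6 + d7
  expect_identical(required_horizon(specs[[3]]$formula),
                   as.integer(d[5] + d[6] + d[7]))
  expect_equal(vapply(specs, function(s) s$theta, numeric(1)), rep(0.8, 4))
})

test_that("dose propositions classify administered doses by magnitude", {
  th <- spec_thresholds(dose_low = 10, dose_high = 30)
  props <- air_propositions(th)
  names(props) <- vapply(props, function(p) p$name, character(1))
  s_none <- list(dose = 0, pro = 0)
  s_low <- list(dose = 5, pro = 0)
  s_high <- list(dose = 40, pro = 0)
  expect_false(props[["D"]]$predicate(s_none))
  expect_true(props[["D"]]$predicate(s_low))
  expect_true(props[["D_L"]]$predicate(s_low))
  expect_false(props[["D_L"]]$predicate(s_high))
  expect_true(props[["D_H"]]$predicate(s_high))
  # inflammation atoms are nested: I_H implies I_L
  s_inflamed <- list(dose = 0, pro = th$IH_level + 1)
  expect_true(props[["I_L"]]$predicate(s_inflamed))
  expect_true(props[["I_H"]]$predicate(s_inflamed))
})

test_that("non-vacuous chronic inflammation is unreachable without dosing", {
  # with dosing forced to zero the antecedent-free reading of the
  # non-resolving property (a dose followed by persistent high
  # inflammation) can never hold, so synthesis must fail
  b <- air_default_bounds()
  th <- spec_thresholds()
  zero_family <- list(
    space = b,
    sample = function(omega, horizon, seed) {
      om <- omega
      om[grep("amount", names(om))] <- 0
      simulate_air(om, horizon, experiment = 2, thresholds = th, seed = seed)
    })
  d <- th$delta
  hard <- pbltl_spec(sprintf("F[%d](G[%d] I_H)", d[3], d[4]), 0.8)
  fit <- synthesize(zero_family, hard,
                    schedule = annealing_schedule(5, 1, gamma = 0.7),
                    max_samples = 60, seed = 21)
  expect_identical(fit$status, "not_found")
  expect_true(all(fit$trajectory$decision == "reject_H0"))
})

test_that("the reduced-budget case study finds and re-verifies a point", {
  out <- run_case_study(specs = 1, seed = 3, verify_traces = 30)
  expect_named(out, "spec1")
  fit <- out$spec1$fit
  expect_identical(nrow(fit$trajectory), fit$checker_calls)
  if (fit$status == "found") {
    expect_gte(out$spec1$verified_frac, 0.8 - 2 * 0.05)
    expect_true(all(coef(fit) >= air_default_bounds()$lower - 1e-12))
  }
})

test_that("case study outputs land on disk when a directory is given", {
  out_dir <- withr::local_tempdir()
  out <- run_case_study(specs = 1, seed = 1, verify_traces = 10,
                        schedule = annealing_schedule(4, 1, gamma = 0.6),
                        out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "spec1_trajectory.csv")))
  expect_true(file.exists(file.path(out_dir, "spec1_result.json")))
  res <- jsonlite::read_json(file.path(out_dir, "spec1_result.json"))
  expect_identical(res$status, out$spec1$fit$status)
  traj <- utils::read.csv(file.path(out_dir, "spec1_trajectory.csv"))
  expect_identical(nrow(traj), out$spec1$fit$checker_calls)
})
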