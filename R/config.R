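#' Run configuration files
#'
#' A run is described by a YAML file with the sections
#' \preformatted{
#' model: bernoulli | logistic-bernoulli | small-chain | air
#' spec:
#'   formula: "F[1] success"     # or specs: [1, 3] for the AIR demo
#'   theta: 0.7
#' omega: {p: 0.9}               # cmd_check only
#' checker:
#'   method: bayes | sprt
#'   L: 100
#'   epsilon1: 0.05
#'   epsilon2: 0.05
#'   prior: {a: 1, b: 1}
#'   alpha: 0.01                 # sprt only
#'   beta: 0.01
#'   max_samples: 1000
#' annealing:                    # cmd_synthesize only
#'   t_start: 20
#'   t_stop: 1
#'   gamma: 0.9
#'   max_iterations: 200
#' neighborhood: {scale: 0.1, mode: one}
#' seed: 1
#' out_dir: results/run1
#' }
#' Validation reports every missing or ill-typed key by its path before
#' any computation runs; the fully resolved configuration (defaults
#' filled in) is written next to the outputs so a run can be reproduced
#' bit-for-bit from its output directory.
#'
#' @param path path to a YAML configuration file.
#' @return the validated configuration as a named list with all defaults
#'   resolved.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

config_defaults <- function() {
  list(checker = list(method = "bayes", L = 100, epsilon1 = 0.05,
                      epsilon2 = 0.05, prior = list(a = 1, b = 1),
                      alpha = 0.01, beta = 0.01, max_samples = 1000),
       annealing = list(t_start = 20, t_stop = 1, gamma = 0.95,
                        max_iterations = 200),
       neighborhood = list(scale = 0.2, mode = "one"),
       seed = 1)
}

#' @rdname read_run_config
#' @param config a configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  need <- function(cond, path_str, what) {
    if (!isTRUE(cond)) problems <<- c(problems, paste0(path_str, ": ", what))
  }
  config <- utils::modifyList(config_defaults(), config)

  need(is.character(config$model) && length(config$model) == 1L,
       "model", "must name a model")
  known <- c("bernoulli", "logistic-bernoulli", "small-chain", "air")
  if (is.character(config$model) && !config$model %in% known)
    problems <- c(problems, paste0("model: unknown model '", config$model,
                                   "' (use ", paste(known, collapse = ", "), ")"))

  if (identical(config$model, "air")) {
    if (is.null(config$spec$specs))
      need(!is.null(config$spec$theta), "spec.theta", "is required")
  } else {
    need(is.character(config$spec$formula), "spec.formula", "is required")
    need(is.numeric(config$spec$theta), "spec.theta", "is required")
  }
  if (!is.null(config$spec$theta))
    need(config$spec$theta >= 0 && config$spec$theta <= 1,
         "spec.theta", "must lie in [0, 1]")
  ch <- config$checker
  need(ch$method %in% c("bayes", "sprt"), "checker.method",
       "must be 'bayes' or 'sprt'")
  need(is.numeric(ch$L) && ch$L > 1, "checker.L", "must be > 1")
  need(is.numeric(ch$epsilon1) && ch$epsilon1 > 0, "checker.epsilon1",
       "must be > 0")
  need(is.numeric(ch$epsilon2) && ch$epsilon2 > 0, "checker.epsilon2",
       "must be > 0")
  need(is.numeric(ch$max_samples) && ch$max_samples >= 1,
       "checker.max_samples", "must be >= 1")
  an <- config$annealing
  need(is.numeric(an$t_start) && an$t_start > 0, "annealing.t_start",
       "must be > 0")
  need(is.numeric(an$t_stop) && an$t_stop > 0 && an$t_stop <= an$t_start,
       "annealing.t_stop", "must be in (0, t_start]")
  need(is.numeric(an$gamma) && an$gamma > 0 && an$gamma < 1,
       "annealing.gamma", "must be in (0, 1)")
  need(config$neighborhood$mode %in% c("one", "all"), "neighborhood.mode",
       "must be 'one' or 'all'")
  need(is.numeric(config$seed) && length(config$seed) == 1L,
       "seed", "must be a single integer")

  if (length(problems))
    stop("invalid run configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  config
}

config_spec <- function(config) {
  pbltl_spec(config$spec$formula, config$spec$theta)
}

config_family <- function(config) {
  if (identical(config$model, "air")) air_family()
  else build_fixture(config$model)
}

write_resolved_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$package_version <- as.character(utils::packageVersion("smcsynth"))
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
}

#' Run a single model-checking query from a configuration
#'
#' Loads the model and specification named by the configuration, runs
#' the Bayesian checker (or the SPRT when `checker.method: sprt`), and,
#' when `out_dir` is set, writes `result.json`, the per-step statistic
#' trajectory CSV and the resolved configuration there.
#'
#' @param config a configuration list or path to a YAML file.
#' @return the `"bsmc_test"` result, invisibly when writing files.
#' @export
cmd_check <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- validate_run_config(config)
  fam <- config_family(config)
  spec <- config_spec(config)
  if (is.null(config$omega))
    stop("invalid run configuration:\n  omega: is required for cmd_check",
         call. = FALSE)
  omega <- unlist(config$omega)
  ch <- config$checker
  sampler <- function(seed)
    fam$sample(omega, required_horizon(spec$formula), seed)
  res <- if (ch$method == "bayes")
    bsmc_verify(sampler, spec, L = ch$L,
                prior = beta_prior(ch$prior$a, ch$prior$b),
                eps = indifference(ch$epsilon1, ch$epsilon2),
                max_samples = ch$max_samples, seed = config$seed)
  else
    sprt_verify(sampler, spec, eps = indifference(ch$epsilon1, ch$epsilon2),
                alpha = ch$alpha, beta = ch$beta,
                max_samples = ch$max_samples, seed = config$seed)
  if (!is.null(config$out_dir)) {
    write_resolved_config(config, config$out_dir)
    jsonlite::write_json(
      list(decision = res$decision, satisfied = res$satisfied, n = res$n,
           z = res$z, log10_bf = res$log10_bf, method = res$method,
           seed = config$seed),
      file.path(config$out_dir, "result.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(data.frame(sample = seq_along(res$trajectory),
                                log10_statistic = res$trajectory),
                     file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Run a parameter-synthesis search from a configuration
#'
#' For fixture models this anneals over the fixture's parameter space;
#' for `model: air` it dispatches to [run_case_study()] on the requested
#' specification indices.  When `out_dir` is set, writes `result.json`,
#' the trajectory CSV and the resolved configuration.
#'
#' @inheritParams cmd_check
#' @return the `"smc_synthesis"` result (or `run_case_study()`'s list
#'   for the AIR demo), invisibly when writing files.
#' @export
cmd_synthesize <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- validate_run_config(config)
  ch <- config$checker
  an <- config$annealing
  nb <- config$neighborhood
  if (identical(config$model, "air")) {
    res <- run_case_study(
      specs = if (is.null(config$spec$specs)) 1 else unlist(config$spec$specs),
      theta = config$spec$theta,
      eps = indifference(ch$epsilon1, ch$epsilon2), L = ch$L,
      schedule = annealing_schedule(an$t_start, an$t_stop, gamma = an$gamma),
      policy = neighborhood_policy(nb$scale, nb$mode),
      max_samples = ch$max_samples, seed = config$seed,
      out_dir = config$out_dir)
    if (!is.null(config$out_dir)) write_resolved_config(config, config$out_dir)
    return(res)
  }
  fam <- build_fixture(config$model)
  spec <- config_spec(config)
  fit <- synthesize(fam, spec,
                    schedule = annealing_schedule(an$t_start, an$t_stop,
                                                  gamma = an$gamma),
                    L = ch$L, eps = indifference(ch$epsilon1, ch$epsilon2),
                    policy = neighborhood_policy(nb$scale, nb$mode),
                    max_samples = ch$max_samples, seed = config$seed,
                    max_iterations = an$max_iterations)
  if (!is.null(config$out_dir)) {
    write_resolved_config(config, config$out_dir)
    jsonlite::write_json(
      list(status = fit$status,
           omega = if (!is.null(fit$omega)) as.list(fit$omega),
           checker_calls = fit$checker_calls, seed = config$seed),
      file.path(config$out_dir, "result.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(fit$trajectory,
                     file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    return(invisible(fit))
  }
  fit
}
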