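#' Annealing schedule
#'
#' Temperature program for the simulated-annealing parameter search: the
#' loop starts at `t_start`, updates the temperature after each iteration
#' through the strictly decreasing cooling function, and stops when it
#' falls below `t_stop`.  The default geometric schedule
#' `T(k) = t_start * gamma^k` runs for about
#' `log(t_stop / t_start) / log(gamma)` iterations.
#'
#' @param t_start starting temperature, `> 0`.
#' @param t_stop stopping temperature, `0 < t_stop <= t_start`.
#' @param cooling `"geometric"` (only built-in family) or a custom
#'   strictly decreasing `function(k)` mapping the iteration count to a
#'   temperature.
#' @param gamma geometric cooling factor in `(0, 1)`.
#' @return an object of class `"annealing_schedule"`.
#' @export
annealing_schedule <- function(t_start = 20, t_stop = 1,
                               cooling = "geometric", gamma = 0.95) {
  stopifnot(t_start > 0, t_stop > 0, t_stop <= t_start)
  if (is.function(cooling)) {
    Tfun <- cooling
    if (!(Tfun(2) < Tfun(1)))
      stop("cooling function must be strictly decreasing", call. = FALSE)
  } else {
    cooling <- match.arg(cooling, "geometric")
    stopifnot(gamma > 0, gamma < 1)
    force(t_start); force(gamma)
    Tfun <- function(k) t_start * gamma^k
  }
  structure(list(t_start = t_start, t_stop = t_stop, Tfun = Tfun,
                 cooling = if (is.function(cooling)) "custom" else cooling,
                 gamma = gamma),
            class = "annealing_schedule")
}

#' Neighborhood policy for the annealing search
#'
#' Candidate moves perturb the current parameter point with a Gaussian
#' step whose standard deviation is `scale` times each dimension's range;
#' `mode = "one"` perturbs a single randomly chosen coordinate per move,
#' `"all"` perturbs every coordinate.  Proposals are clipped to the
#' bounds, so a neighbor of an in-bounds point is always in-bounds.
#'
#' @param scale step scale as a fraction of each dimension's range
#'   (default 0.2; 0 gives degenerate identity moves).
#' @param mode `"one"` or `"all"`.
#' @return an object of class `"neighborhood_policy"`.
#' @export
neighborhood_policy <- function(scale = 0.2, mode = c("one", "all")) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0)
  structure(list(scale = scale, mode = match.arg(mode)),
            class = "neighborhood_policy")
}

#' Draw a random neighbor of a parameter point
#'
#' @param omega current point (named or positional numeric).
#' @param space a [parameter_space()].
#' @param policy a [neighborhood_policy()].
#' @return an in-bounds parameter point.
#' @export
neighbor <- function(omega, space, policy = neighborhood_policy()) {
  omega <- check_point(omega, space)
  sd <- policy$scale * (space$upper - space$lower)
  if (policy$mode == "one") {
    j <- sample.int(space$dim, 1L)
    omega[j] <- omega[j] + stats::rnorm(1L, 0, sd[j])
  } else {
    omega <- omega + stats::rnorm(space$dim, 0, sd)
  }
  pmin(pmax(omega, space$lower), space$upper)
}

#' Metropolis acceptance rule on checker sample counts
#'
#' The search's fitness is the number of traces the sequential checker
#' consumed: points where the checker works harder lie closer to the
#' satisfying region.  Moves to a strictly larger sample count are always
#' taken; otherwise the move is taken with probability
#' `exp(-(n_current - n_candidate) / temperature)`, so ties are always
#' accepted and higher temperatures tolerate worse moves more readily.
#'
#' @param n_current,n_candidate checker sample counts at the incumbent
#'   and candidate points.
#' @param temperature current annealing temperature, `> 0`.
#' @return `TRUE` to move to the candidate.
#' @export
accept_move <- function(n_current, n_candidate, temperature) {
  stopifnot(temperature > 0)
  if (n_candidate > n_current) return(TRUE)
  stats::runif(1) < exp(-(n_current - n_candidate) / temperature)
}

#' Parameter synthesis by simulated annealing over checker sample counts
#'
#' Searches a bounded parameter space for a point `omega` at which the
#' model satisfies the probabilistic specification, i.e.
#' `M(omega) |= P_>=theta(phi)`.  Each candidate is submitted to the
#' Bayesian sequential checker; the search returns immediately on the
#' first accepting verdict.  Otherwise it anneals on the checker's
#' sample count `n` as fitness — the count grows as the candidate's true
#' satisfaction probability approaches the threshold, so larger `n`
#' signals proximity to the satisfying region — using [accept_move()]
#' and the cooling schedule, and reports failure when the temperature
#' falls below the stopping value without any acceptance.
#'
#' @param family model family: a [build_fixture()] result, or any list
#'   with `space` (a [parameter_space()]) and `sample`, a
#'   `function(omega, horizon, seed)` returning an `"smc_trace"` (or a
#'   logical satisfaction outcome directly).
#' @param spec a [pbltl_spec()], or a list of them for multi-spec
#'   synthesis.
#' @param schedule an [annealing_schedule()].
#' @param priors prior family `h`: a `function(omega)` returning the
#'   prior used when checking that point (default: uniform Beta(1, 1)
#'   everywhere).
#' @param L,eps,max_samples checker settings, as in [bsmc_verify()].
#' @param policy a [neighborhood_policy()].
#' @param mode for a list of specifications: `"joint"` checks every
#'   specification at each candidate and accepts only when all accept
#'   (fitness is the summed sample count); `"per-spec"` is provided by
#'   calling `synthesize()` once per specification.
#' @param seed master seed; the full run is reproducible from it.
#' @param max_iterations hard guard on annealing iterations.
#' @return an object of class `"smc_synthesis"`: `status` (`"found"` /
#'   `"not_found"`), `omega` (if found), the per-checker-call
#'   `trajectory` log, and the total number of checker calls.
#' @examples
#' fx <- build_fixture("bernoulli")
#' fit <- synthesize(fx, pbltl_spec(fx$formula, 0.6), seed = 42,
#'                   max_samples = 500)
#' coef(fit)
#' @export
synthesize <- function(family, spec,
                       schedule = annealing_schedule(),
                       priors = function(omega) beta_prior(1, 1),
                       L = 100, eps = indifference(0.05),
                       policy = neighborhood_policy(),
                       max_samples = 1000, mode = c("joint", "per-spec"),
                       seed = 1, max_iterations = 500) {
  mode <- match.arg(mode)
  specs <- if (inherits(spec, "pbltl_spec")) list(spec) else spec
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "pbltl_spec")),
            L > 1)
  space <- family$space
  stopifnot(inherits(space, "param_space"), is.function(family$sample))
  horizons <- vapply(specs, function(s) required_horizon(s$formula), integer(1))

  log_rows <- list()
  ncalls <- 0L

  check_point_at <- function(omega, call_seed) {
    # joint mode: every spec must accept; fitness is the summed n
    results <- lapply(seq_along(specs), function(j) {
      sampler <- function(s) family$sample(omega, horizons[j], s)
      bsmc_verify(sampler, specs[[j]], L = L, prior = priors(omega),
                  eps = eps, max_samples = max_samples,
                  seed = trace_seed(call_seed, j))
    })
    list(accept = all(vapply(results, function(r)
           identical(r$decision, "accept_H0"), logical(1))),
         n = sum(vapply(results, `[[`, numeric(1), "n")),
         decisions = vapply(results, `[[`, character(1), "decision"))
  }

  log_call <- function(iter, omega, res, temperature, accepted) {
    row <- as.data.frame(as.list(omega))
    row$iteration <- iter
    row$n <- res$n
    row$decision <- paste(res$decisions, collapse = "+")
    row$temperature <- temperature
    row$accepted <- accepted
    log_rows[[length(log_rows) + 1L]] <<- row
  }

  finish <- function(status, omega, checker_calls) {
    traj <- do.call(rbind, log_rows)
    structure(list(status = status, omega = omega,
                   trajectory = traj, checker_calls = checker_calls,
                   specs = specs, space = space, mode = mode,
                   settings = list(schedule = schedule, L = L, eps = eps,
                                   policy = policy, max_samples = max_samples,
                                   seed = seed)),
              class = "smc_synthesis")
  }

  set.seed(as.integer(seed))
  omega <- stats::setNames(
    stats::runif(space$dim, space$lower, space$upper), space$names)
  ncalls <- ncalls + 1L
  res <- check_point_at(omega, trace_seed(seed, 500000L + ncalls))
  log_call(0L, omega, res, NA_real_, TRUE)
  if (res$accept) return(finish("found", omega, ncalls))

  t <- schedule$t_start
  lcount <- 0L
  n <- res$n
  while (t >= schedule$t_stop && lcount < max_iterations) {
    lcount <- lcount + 1L
    # optimizer randomness gets its own stream: the checker re-seeds the
    # global RNG per trace, so neighbor/acceptance draws are seeded per
    # iteration to stay independent of checker internals
    set.seed(trace_seed(seed, 900000L + lcount))
    omega_c <- neighbor(omega, space, policy)
    ncalls <- ncalls + 1L
    res_c <- check_point_at(omega_c, trace_seed(seed, 500000L + ncalls))
    if (res_c$accept) {
      log_call(lcount, omega_c, res_c, t, TRUE)
      return(finish("found", omega_c, ncalls))
    }
    set.seed(trace_seed(seed, 700000L + lcount))
    moved <- accept_move(n, res_c$n, t)
    log_call(lcount, omega_c, res_c, t, moved)
    if (moved) {
      omega <- omega_c
      n <- res_c$n
    }
    t <- schedule$Tfun(lcount)
  }
  finish("not_found", NULL, ncalls)
}

#' @export
print.smc_synthesis <- function(x, ...) {
  cat("\n\tparameter synthesis by annealed statistical model checking\n\n")
  for (s in x$specs)
    cat(sprintf("  specification: P>=%g( %s )\n", s$theta, unparse(s$formula)))
  cat("  status:", x$status, "\n")
  if (x$status == "found") {
    cat("  parameter point:\n")
    print(round(x$omega, 6))
  } else {
    cat("  (temperature fell below the stopping value with no accepting",
        "verdict)\n")
  }
  cat("  checker calls:", x$checker_calls, "\n")
  invisible(x)
}

#' @export
coef.smc_synthesis <- function(object, ...) object$omega

#' @export
summary.smc_synthesis <- function(object, ...) {
  tr <- object$trajectory
  structure(list(status = object$status, omega = object$omega,
                 checker_calls = object$checker_calls,
                 n_range = range(tr$n),
                 accepted_moves = sum(tr$accepted) - 1L,   # initial row is not a move
                 iterations = max(tr$iteration),
                 specs = object$specs),
            class = "summary.smc_synthesis")
}

#' @export
print.summary.smc_synthesis <- function(x, ...) {
  cat("synthesis", x$status, "after", x$checker_calls, "checker call(s);",
      x$accepted_moves, "accepted move(s) over", x$iterations,
      "annealing iteration(s)\n")
  cat("checker sample counts ranged", x$n_range[1], "to", x$n_range[2], "\n")
  if (x$status == "found") { cat("parameter point:\n"); print(round(x$omega, 6)) }
  invisible(x)
}

#' Plot the annealing trajectory
#'
#' Draws the checker sample count (the annealing fitness) per checker
#' call, with the temperature overlaid on a second axis.
#'
#' @param x an `"smc_synthesis"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.smc_synthesis <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(seq_len(nrow(tr)), tr$n, type = "b", pch = 20,
                 col = ifelse(tr$accepted, "black", "grey60"),
                 xlab = "checker call", ylab = "samples used (fitness)", ...)
  ok <- is.finite(tr$temperature)
  if (any(ok)) {
    graphics::par(new = TRUE)
    graphics::plot(seq_len(nrow(tr))[ok], tr$temperature[ok], type = "l",
                   col = "red3", axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "red3")
    graphics::mtext("temperature", 4, line = 2, col = "red3", cex = 0.9)
  }
  invisible(x)
}
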