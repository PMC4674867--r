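#' Parameter spaces and parameter points
#'
#' A parameter space is a bounded box in R^m with named axes; candidate
#' parameter points are validated against it componentwise.
#'
#' @param names character vector of axis names (unique).
#' @param lower,upper numeric vectors of bounds, `lower < upper`.
#' @return an object of class `"param_space"`.
#' @examples
#' parameter_space("p", 0, 1)
#' @export
parameter_space <- function(names, lower, upper) {
  stopifnot(is.character(names), length(names) >= 1L,
            !anyDuplicated(names),
            length(lower) == length(names), length(upper) == length(names),
            is.numeric(lower), is.numeric(upper), all(lower < upper))
  structure(list(names = names, lower = stats::setNames(as.numeric(lower), names),
                 upper = stats::setNames(as.numeric(upper), names),
                 dim = length(names)),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat("parameter space,", x$dim, "dimension(s):\n")
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

check_point <- function(omega, space) {
  omega <- as.numeric_point(omega, space)
  bad <- omega < space$lower - 1e-12 | omega > space$upper + 1e-12
  if (any(bad))
    stop("parameter point out of bounds in dimension(s): ",
         paste(space$names[bad], collapse = ", "), call. = FALSE)
  omega
}

as.numeric_point <- function(omega, space) {
  if (!is.null(names(omega))) {
    missing <- setdiff(space$names, names(omega))
    if (length(missing))
      stop("parameter point lacks dimension(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    omega <- omega[space$names]
  } else if (length(omega) != space$dim) {
    stop("parameter point has length ", length(omega),
         ", expected ", space$dim, call. = FALSE)
  }
  stats::setNames(as.numeric(omega), space$names)
}

#' Parameterized discrete-time Markov chains
#'
#' A ParDTMC couples a countable state set with an initial distribution
#' and a transition kernel whose rows depend on a real parameter vector.
#' States here are explicit (the class targets desk-scale fixtures and
#' exact oracles); production-scale models enter the framework through
#' the trace-sampler contract instead, since the checker only ever needs
#' sampled executions.
#'
#' @param states character vector of state names.
#' @param init named numeric initial distribution over `states`
#'   (sums to 1 within 1e-12).
#' @param transition function `(state, omega)` returning a named
#'   probability vector over `states` (each row sums to 1 within 1e-12).
#' @param values data.frame of per-state variable valuations, one row per
#'   state (row order matches `states`); used for labeling.
#' @param props list of [proposition()] objects (the labeling function).
#' @param space a [parameter_space()].
#' @param name model identifier.
#' @return an object of class `"pardtmc"`.
#' @export
pardtmc <- function(states, init, transition, values, props, space,
                    name = "pardtmc") {
  stopifnot(is.character(states), length(states) >= 1L, !anyDuplicated(states),
            is.function(transition), inherits(space, "param_space"))
  init <- init[states]
  init[is.na(init)] <- 0
  names(init) <- states
  if (abs(sum(init) - 1) > 1e-12)
    stop("initial distribution must sum to 1", call. = FALSE)
  values <- as.data.frame(values)
  if (nrow(values) != length(states))
    stop("'values' needs one row per state", call. = FALSE)
  rownames(values) <- states
  structure(list(states = states, init = init, transition = transition,
                 values = values, props = check_prop_registry(props),
                 space = space, name = name),
            class = "pardtmc")
}

#' @export
print.pardtmc <- function(x, ...) {
  cat("ParDTMC '", x$name, "': ", length(x$states), " states, ",
      x$space$dim, " parameter(s), ", length(x$props),
      " proposition(s)\n", sep = "")
  invisible(x)
}

transition_row <- function(model, state, omega) {
  p <- model$transition(state, omega)
  p <- p[model$states]
  p[is.na(p)] <- 0
  if (abs(sum(p) - 1) > 1e-12)
    stop("transition row for state '", state, "' sums to ", sum(p),
         ", not 1 (model bug)", call. = FALSE)
  p
}

#' Sample a labeled execution trace from a model
#'
#' Draws `s_0` from the initial distribution and each successive state
#' from the transition kernel at the supplied parameter point, producing
#' a trace of `horizon + 1` states.  Sampling is reproducible: the same
#' `(model, omega, horizon, seed)` always yields the same trace.
#'
#' @param model a `"pardtmc"`.
#' @param omega parameter point (named or positional numeric).
#' @param horizon number of transitions to simulate (`>= 0`).
#' @param seed integer seed for this trace's private RNG stream.
#' @return an `"smc_trace"` whose values are the per-state valuations plus
#'   a `state` column.
#' @export
sample_trace <- function(model, omega, horizon, seed = NULL) {
  stopifnot(inherits(model, "pardtmc"), horizon >= 0)
  omega <- check_point(omega, model$space)
  if (!is.null(seed)) set.seed(as.integer(seed))
  horizon <- as.integer(horizon)
  idx <- integer(horizon + 1L)
  s <- sample.int(length(model$states), 1L, prob = model$init)
  idx[1L] <- s
  if (horizon > 0L) for (t in seq_len(horizon)) {
    p <- transition_row(model, model$states[s], omega)
    s <- sample.int(length(model$states), 1L, prob = p)
    idx[t + 1L] <- s
  }
  vals <- model$values[idx, , drop = FALSE]
  rownames(vals) <- NULL
  vals$state <- model$states[idx]
  smc_trace(vals, props = model$props,
            meta = list(model = model$name, omega = omega, seed = seed))
}

#' Exhaustive path enumeration (small-instance oracle)
#'
#' Enumerates every length-`horizon` execution prefix with positive
#' probability and its exact probability, by multiplying transition
#' probabilities along each path.  This realizes, at desk scale, the
#' exhaustive alternative to statistical checking; it refuses instances
#' whose path count would exceed `cap` rather than run unbounded.
#'
#' @inheritParams sample_trace
#' @param cap maximum number of paths to enumerate (default 1e6).
#' @return an object of class `"path_distribution"`: a list with `paths`
#'   (list of state-name vectors) and `prob` (numeric, sums to 1).
#' @export
enumerate_paths <- function(model, omega, horizon, cap = 1e6) {
  stopifnot(inherits(model, "pardtmc"), horizon >= 0)
  omega <- check_point(omega, model$space)
  paths <- list()
  probs <- numeric(0)
  count <- 0L
  recurse <- function(prefix, prob, steps_left) {
    if (steps_left == 0L) {
      count <<- count + 1L
      if (count > cap)
        stop("path enumeration exceeds cap of ", cap,
             " paths; this oracle is for small instances only", call. = FALSE)
      paths[[count]] <<- prefix
      probs[count] <<- prob
      return(invisible())
    }
    row <- transition_row(model, prefix[length(prefix)], omega)
    for (s in model$states[row > 0])
      recurse(c(prefix, s), prob * row[[s]], steps_left - 1L)
  }
  for (s0 in model$states[model$init > 0])
    recurse(s0, model$init[[s0]], as.integer(horizon))
  structure(list(paths = paths, prob = probs, horizon = horizon),
            class = "path_distribution")
}

#' @export
print.path_distribution <- function(x, ...) {
  cat("exact path distribution:", length(x$prob), "paths, horizon",
      x$horizon, "\n")
  invisible(x)
}

#' Exact satisfaction probability (small-instance oracle)
#'
#' Computes the probability `u` with which the model satisfies a formula
#' (the `u` in `M |= P_=u(phi)`) by enumerating all paths of length
#' [required_horizon()] and summing the probability of those whose trace
#' satisfies the formula at position 0.  Intended as a ground-truth oracle
#' for fixtures; the production decision procedure is [bsmc_verify()].
#'
#' @inheritParams sample_trace
#' @param formula a `"bltl"` object.
#' @param cap passed to [enumerate_paths()].
#' @return a probability in `[0, 1]`.
#' @export
exact_satisfaction_probability <- function(model, omega, formula, cap = 1e6) {
  pd <- enumerate_paths(model, omega, required_horizon(formula), cap = cap)
  sat <- vapply(pd$paths, function(p) {
    vals <- model$values[p, , drop = FALSE]
    rownames(vals) <- NULL
    vals$state <- p
    satisfies(smc_trace(vals, props = model$props), formula)
  }, logical(1))
  sum(pd$prob[sat])
}

## ---- fixtures -------------------------------------------------------------

#' Built-in ParDTMC fixtures with known satisfaction probabilities
#'
#' Three small parameterized chains whose exact satisfaction probability
#' for a canonical formula has a documented closed form, used throughout
#' the tests and as targets for the synthesizer:
#' \describe{
#'   \item{`bernoulli`}{one start state branching to absorbing success /
#'     failure states with probability `p`; canonical formula
#'     `F[1] success` has `u(p) = p`.}
#'   \item{`logistic-bernoulli`}{same chain but the branch probability is
#'     `plogis(w1 + w2)` of a 2-D parameter on `[-3, 3]^2`; at the
#'     midpoint `(0, 0)`, `u = 0.5`.}
#'   \item{`small-chain`}{a fixed 3-state chain with kernel rows
#'     `(0.5, 0.5, 0)`, `(0, 0.2, 0.8)`, `(0, 0, 1)` started in state
#'     `s1`; canonical formula `F[2] absorbed` has
#'     `u = 0.4` (the probability of reaching `s3` within 2 steps).}
#' }
#'
#' @param name one of `"bernoulli"`, `"logistic-bernoulli"`,
#'   `"small-chain"`.
#' @return a list with components `model` (a [pardtmc()]), `space`,
#'   `formula` (canonical `"bltl"`), `true_prob` (function of omega
#'   giving the closed-form satisfaction probability), and `sample`
#'   (the family's trace-sampler `function(omega, horizon, seed)`).
#' @export
build_fixture <- function(name) {
  switch(name,
    "bernoulli" = {
      space <- parameter_space("p", 0, 1)
      bernoulli_like(space, function(omega) omega[["p"]], "bernoulli")
    },
    "logistic-bernoulli" = {
      space <- parameter_space(c("w1", "w2"), c(-3, -3), c(3, 3))
      bernoulli_like(space, function(omega) stats::plogis(omega[["w1"]] + omega[["w2"]]),
                     "logistic-bernoulli")
    },
    "small-chain" = small_chain_fixture(),
    stop("unknown fixture '", name, "'; available: bernoulli, ",
         "logistic-bernoulli, small-chain", call. = FALSE)
  )
}

bernoulli_like <- function(space, pfun, name) {
  # bounds may touch 0/1: allow degenerate branch probabilities
  states <- c("start", "succ", "fail")
  values <- data.frame(success = c(0, 1, 0))
  props <- list(proposition("success", function(s) s$success == 1))
  transition <- function(state, omega) {
    p <- pfun(omega)
    switch(state,
      start = c(start = 0, succ = p, fail = 1 - p),
      succ  = c(start = 0, succ = 1, fail = 0),
      fail  = c(start = 0, succ = 0, fail = 1))
  }
  model <- pardtmc(states, c(start = 1, succ = 0, fail = 0), transition,
                   values, props, space, name = name)
  formula <- parse_formula("F[1] success")
  list(model = model, space = space, formula = formula, true_prob = pfun,
       sample = function(omega, horizon, seed = NULL)
         sample_trace(model, omega, horizon, seed),
       name = name)
}

small_chain_fixture <- function() {
  space <- parameter_space("unused", 0, 1)
  states <- c("s1", "s2", "s3")
  kernel <- rbind(c(0.5, 0.5, 0), c(0, 0.2, 0.8), c(0, 0, 1))
  dimnames(kernel) <- list(states, states)
  values <- data.frame(sidx = 1:3)
  props <- list(proposition("absorbed", function(s) s$sidx == 3))
  model <- pardtmc(states, c(s1 = 1, s2 = 0, s3 = 0),
                   function(state, omega) kernel[state, ],
                   values, props, space, name = "small-chain")
  formula <- parse_formula("F[2] absorbed")
  list(model = model, space = space, formula = formula,
       true_prob = function(omega) 0.4,
       sample = function(omega, horizon, seed = NULL)
         sample_trace(model, omega, horizon, seed),
       name = "small-chain", kernel = kernel)
}

## ---- agent-based models ---------------------------------------------------

#' Toy agent-based model and its induced Markov chain
#'
#' A two-agent model in which each agent carries one binary activity
#' variable: an inactive agent activates with probability `omega` and an
#' active agent deactivates with probability `q_off`, independently per
#' step.  Because the update rule is a function of the joint state and
#' fresh randomness only, the induced joint-state process is a ParDTMC
#' whose kernel factorizes over agents; `kernel(omega)` tabulates it
#' exactly, and `step()` simulates the agent-level rule.  The pair is
#' used to demonstrate (and test) the ABM-to-Markov-chain reduction.
#'
#' @param q_off per-step deactivation probability (default 0.3).
#' @return a list with `space`, `states` (joint states `"00"`, `"01"`,
#'   `"10"`, `"11"`), `step(state, omega)` (one stochastic update),
#'   `kernel(omega)` (exact 4x4 transition matrix) and `as_pardtmc()`.
#' @export
toy_agent_model <- function(q_off = 0.3) {
  stopifnot(q_off >= 0, q_off <= 1)
  space <- parameter_space("omega", 0, 1)
  states <- c("00", "01", "10", "11")
  agent_step <- function(v, omega) {
    if (v == 0L) stats::rbinom(1L, 1L, omega) else 1L - stats::rbinom(1L, 1L, q_off)
  }
  step <- function(state, omega) {
    v <- as.integer(strsplit(state, "")[[1]])
    paste(vapply(v, agent_step, integer(1), omega = omega), collapse = "")
  }
  per_agent <- function(from, to, omega) {
    if (from == 0L) { if (to == 1L) omega else 1 - omega }
    else            { if (to == 0L) q_off else 1 - q_off }
  }
  kernel <- function(omega) {
    omega <- check_point(omega, space)[["omega"]]
    K <- matrix(0, 4, 4, dimnames = list(states, states))
    for (a in states) for (b in states) {
      va <- as.integer(strsplit(a, "")[[1]])
      vb <- as.integer(strsplit(b, "")[[1]])
      K[a, b] <- per_agent(va[1], vb[1], omega) * per_agent(va[2], vb[2], omega)
    }
    K
  }
  as_pardtmc <- function() {
    values <- data.frame(n_active = c(0, 1, 1, 2))
    props <- list(proposition("all_active", function(s) s$n_active == 2))
    pardtmc(states, c("00" = 1, "01" = 0, "10" = 0, "11" = 0),
            function(state, omega) kernel(omega)[state, ],
            values, props, space, name = "toy-abm")
  }
  list(space = space, states = states, step = step, kernel = kernel,
       as_pardtmc = as_pardtmc, q_off = q_off)
}
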