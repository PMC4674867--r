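#' Probabilistic BLTL specifications
#'
#' A PBLTL specification `P_>=theta(phi)` pairs a BLTL formula with a
#' probability threshold: a stochastic model satisfies it when at least a
#' `theta` fraction of its executions satisfy `phi`.
#'
#' @param formula a `"bltl"` object or formula text to parse.
#' @param theta probability threshold in `[0, 1]`.
#' @return an object of class `"pbltl_spec"`.
#' @examples
#' pbltl_spec("F[1] success", theta = 0.7)
#' @export
pbltl_spec <- function(formula, theta) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "bltl"),
            is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1)
  structure(list(formula = formula, theta = theta), class = "pbltl_spec")
}

#' @export
print.pbltl_spec <- function(x, ...) {
  cat(sprintf("PBLTL specification: P>=%g( %s )\n", x$theta, unparse(x$formula)))
  invisible(x)
}

#' Indifference region around the threshold
#'
#' The sequential tests do not distinguish satisfaction probabilities
#' inside `[theta - eps1, theta + eps2]`; either answer is acceptable
#' there.  The region is entered as the two half-widths, exactly as the
#' checker consumes them.
#'
#' @param eps1,eps2 strictly positive half-widths below/above `theta`.
#' @return an object of class `"indifference"`.
#' @export
indifference <- function(eps1, eps2 = eps1) {
  stopifnot(is.numeric(eps1), is.numeric(eps2), eps1 > 0, eps2 > 0)
  structure(list(eps1 = eps1, eps2 = eps2), class = "indifference")
}

check_region <- function(eps, theta) {
  if (is.numeric(eps)) eps <- if (length(eps) == 1L) indifference(eps)
                              else indifference(eps[1], eps[2])
  stopifnot(inherits(eps, "indifference"))
  if (theta - eps$eps1 < -1e-12 || theta + eps$eps2 > 1 + 1e-12)
    stop("indifference region [theta-eps1, theta+eps2] = [",
         theta - eps$eps1, ", ", theta + eps$eps2,
         "] must lie within [0, 1]", call. = FALSE)
  eps
}

#' Prior densities for the unknown satisfaction probability
#'
#' The Bayesian checker models the unknown probability `u` with which the
#' model satisfies the formula as a random variable with prior density
#' `g`.  The conjugate Beta family is the default (closed-form Bayes
#' factor); an arbitrary density may be supplied on a grid and is then
#' integrated by quadrature.
#'
#' @param a,b positive Beta shape parameters; `beta_prior(1, 1)` is the
#'   uniform default.
#' @return an object of class `"smc_prior"`.
#' @export
beta_prior <- function(a = 1, b = 1) {
  stopifnot(a > 0, b > 0)
  structure(list(type = "beta", a = a, b = b), class = "smc_prior")
}

#' @rdname beta_prior
#' @param u grid of support points in `[0, 1]` (increasing, length >= 2).
#' @param density nonnegative density values at `u`; renormalized to
#'   integrate to 1 by the trapezoid rule.
#' @export
tabulated_prior <- function(u, density) {
  stopifnot(is.numeric(u), is.numeric(density), length(u) == length(density),
            length(u) >= 2L, all(diff(u) > 0), min(u) >= 0, max(u) <= 1,
            all(density >= 0))
  mass <- trapz(u, density)
  if (mass <= 0) stop("prior density has zero mass", call. = FALSE)
  structure(list(type = "tabulated", u = u, density = density / mass),
            class = "smc_prior")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.smc_prior <- function(x, ...) {
  if (x$type == "beta") cat(sprintf("Beta(%g, %g) prior\n", x$a, x$b))
  else cat("tabulated prior on", length(x$u), "grid points\n")
  invisible(x)
}

## ---- Bayes factor ---------------------------------------------------------

#' Bayes factor for the sequential satisfaction test
#'
#' After observing `n` Bernoulli monitoring outcomes of which `z` were
#' satisfactions, the Bayes factor of `H0: u >= theta + eps2` against
#' `H1: u <= theta - eps1` is the ratio of the two partial prior-weighted
#' likelihood integrals
#' \deqn{B = \frac{\int_{\theta+\epsilon_2}^{1} u^z (1-u)^{n-z} g(u)\,du}
#'               {\int_{0}^{\theta-\epsilon_1} u^z (1-u)^{n-z} g(u)\,du}.}
#' For a Beta(`a`, `b`) prior the Beta-function normalizers cancel and
#' \eqn{B = (1 - I_{\theta+\epsilon_2}(z+a, n-z+b)) /
#' I_{\theta-\epsilon_1}(z+a, n-z+b)} with `I` the regularized incomplete
#' beta function; the computation is done in log space.  Tabulated priors
#' are integrated by trapezoidal quadrature on their grid.
#'
#' When `theta - eps1 = 0` the denominator is exactly 0 and `+Inf` is
#' returned (vacuous alternative; an attribute `"vacuous"` marks it);
#' symmetrically `theta + eps2 = 1` yields 0.
#'
#' @param n,z total and satisfying sample counts, `0 <= z <= n`.
#' @param theta threshold probability.
#' @param eps1,eps2 indifference half-widths.
#' @param prior an [beta_prior()] or [tabulated_prior()] object.
#' @param log10 if `TRUE` return the base-10 logarithm of `B`.
#' @return the Bayes factor (possibly `0` or `Inf`), or its log10.
#' @examples
#' bayes_factor(6, 6, 0.5, 0.1, 0.1)   # (1 - 0.6^7) / 0.4^7 = 593.27
#' @export
bayes_factor <- function(n, z, theta, eps1, eps2, prior = beta_prior(1, 1),
                         log10 = FALSE) {
  stopifnot(n >= 0, z >= 0, z <= n)
  eps <- check_region(indifference(eps1, eps2), theta)
  lb <- log_bayes_factor(n, z, theta, eps$eps1, eps$eps2, prior)
  out <- as.numeric(if (log10) lb / log(10) else exp(lb))
  if (isTRUE(attr(lb, "vacuous"))) attr(out, "vacuous") <- TRUE
  out
}

## natural-log Bayes factor; attribute "vacuous" flags a 0 denominator
## (theta - eps1 == 0) or 0 numerator (theta + eps2 == 1)
log_bayes_factor <- function(n, z, theta, eps1, eps2, prior) {
  ul <- theta - eps1
  ur <- theta + eps2
  if (prior$type == "beta") {
    lnum <- stats::pbeta(ur, z + prior$a, n - z + prior$b,
                         lower.tail = FALSE, log.p = TRUE)
    lden <- stats::pbeta(ul, z + prior$a, n - z + prior$b, log.p = TRUE)
  } else {
    lw <- log(prior$density) + z * log(prior$u) + (n - z) * log1p(-prior$u)
    lw[prior$density == 0] <- -Inf
    lnum <- log_trapz_restricted(prior$u, lw, ur, 1)
    lden <- log_trapz_restricted(prior$u, lw, 0, ul)
  }
  out <- lnum - lden
  if (is.nan(out)) out <- 0   # both integrals 0: no evidence either way
  attr(out, "vacuous") <- !is.finite(lden) || !is.finite(lnum)
  out
}

## log of the trapezoid integral of exp(ly) over [lo, hi], with linear
## interpolation of ly at the cut points
log_trapz_restricted <- function(x, ly, lo, hi) {
  if (hi <= lo) return(-Inf)
  xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
  if (length(xs) < 2L) return(-Inf)
  lys <- stats::approx(x, ly, xout = xs, rule = 2)$y
  m <- max(lys)
  if (!is.finite(m)) return(-Inf)
  m + log(trapz(xs, exp(lys - m)))
}

## ---- sampler plumbing -----------------------------------------------------

## derive a private, reproducible RNG seed for trace index i under a
## master seed; keeps every value inside 32-bit integer range
trace_seed <- function(master, i) {
  as.integer((as.double(master %% 2147483647L) * 48271 + i) %% 2147483647)
}

#' Trace sampler bound to a model, parameter point and horizon
#'
#' The sequential checkers consume a sampler: a function of one integer
#' seed returning either an `"smc_trace"` (monitored against the
#' formula) or directly a logical satisfaction outcome.  This helper
#' builds the usual model-backed sampler.
#'
#' @inheritParams sample_trace
#' @param horizon trace length; defaults to the checked formula's
#'   [required_horizon()] when used through [bsmc_verify()] with
#'   `horizon = NULL`.
#' @return a `function(seed)` returning an `"smc_trace"`.
#' @export
trace_sampler <- function(model, omega, horizon) {
  force(model); force(omega); force(horizon)
  function(seed) sample_trace(model, omega, horizon, seed)
}

resolve_sampler <- function(sampler, spec, horizon = NULL) {
  if (inherits(sampler, "pardtmc"))
    stop("pass trace_sampler(model, omega, horizon) or a function(seed), ",
         "not a bare model", call. = FALSE)
  stopifnot(is.function(sampler))
  sampler
}

monitor_outcome <- function(x, formula) {
  if (is.logical(x)) return(isTRUE(x))
  satisfies(x, formula)
}

## ---- Bayesian sequential checker ------------------------------------------

#' Bayesian sequential statistical model checking
#'
#' Decides `M |= P_>=theta(phi)` by drawing i.i.d. execution traces,
#' monitoring each against `phi`, and recomputing the [bayes_factor()]
#' of `H0: u >= theta + eps2` against `H1: u <= theta - eps1` after every
#' draw.  Sampling stops as soon as `B > L` (accept `H0`: the model is
#' deemed to satisfy the specification) or `B < 1/L` (reject `H0`), or
#' when `max_samples` draws have been spent, in which case the distinct
#' outcome `"budget_exhausted"` is reported rather than a fabricated
#' decision (the loop need not terminate when the true probability lies
#' inside the indifference region).
#'
#' @param sampler a `function(seed)` returning an `"smc_trace"` or a
#'   logical satisfaction outcome; see [trace_sampler()].
#' @param spec a [pbltl_spec()].
#' @param L Bayes-factor stopping threshold, `> 1`.
#' @param prior prior density of the unknown satisfaction probability.
#' @param eps an [indifference()] region (or numeric of length 1-2).
#' @param max_samples cap on the number of traces drawn.
#' @param seed master seed; each trace gets a private stream derived from
#'   it, so results are exactly reproducible.
#' @return an object of class `"bsmc_test"` with fields `decision`
#'   (`"accept_H0"`, `"reject_H0"` or `"budget_exhausted"`), `satisfied`
#'   (`TRUE`/`FALSE`/`NA`, the model-checking answer), `n`, `z`,
#'   `log10_bf`, and the per-step `trajectory` of log10 Bayes factors.
#' @examples
#' fx <- build_fixture("bernoulli")
#' res <- bsmc_verify(trace_sampler(fx$model, c(p = 0.9), 1),
#'                    pbltl_spec(fx$formula, 0.7), eps = 0.05, seed = 1)
#' res
#' @export
bsmc_verify <- function(sampler, spec, L = 100, prior = beta_prior(1, 1),
                        eps = indifference(0.05), max_samples = 1e5,
                        seed = 1) {
  stopifnot(inherits(spec, "pbltl_spec"), L > 1, max_samples >= 1)
  eps <- check_region(eps, spec$theta)
  sampler <- resolve_sampler(sampler, spec)
  logL <- log(L)
  n <- 0L; z <- 0L
  traj <- numeric(0)
  decision <- "budget_exhausted"
  vacuous <- FALSE
  repeat {
    n <- n + 1L
    x <- sampler(trace_seed(seed, n))
    if (monitor_outcome(x, spec$formula)) z <- z + 1L
    lb <- log_bayes_factor(n, z, spec$theta, eps$eps1, eps$eps2, prior)
    vacuous <- vacuous || isTRUE(attr(lb, "vacuous"))
    traj[n] <- as.numeric(lb) / log(10)
    if (lb > logL) { decision <- "accept_H0"; break }
    if (lb < -logL) { decision <- "reject_H0"; break }
    if (n >= max_samples) break
  }
  new_bsmc_test(decision, n, z, traj, spec, method = "bayes",
                settings = list(L = L, prior = prior, eps = eps, seed = seed,
                                max_samples = max_samples),
                vacuous = vacuous)
}

#' Sequential probability ratio test (SPRT) baseline checker
#'
#' Wald's SPRT for the same relaxed hypotheses as [bsmc_verify()]:
#' `H0: u >= u_r` versus `H1: u <= u_l` with `u_l = theta - eps1`,
#' `u_r = theta + eps2`.  After each monitored trace the log likelihood
#' ratio `Lambda_n = u_l^z (1-u_l)^(n-z) / (u_r^z (1-u_r)^(n-z))` is
#' updated; `H1` is accepted (i.e. `H0` rejected) when
#' `Lambda_n >= (1-beta)/alpha` and `H0` accepted when
#' `Lambda_n <= beta/(1-alpha)`.
#'
#' @inheritParams bsmc_verify
#' @param alpha,beta type-1 / type-2 error bounds in `(0, 1)`.
#' @return a `"bsmc_test"` object with `method = "sprt"`; its
#'   `trajectory` holds the per-step log10 likelihood ratio.
#' @export
sprt_verify <- function(sampler, spec, eps = indifference(0.05),
                        alpha = 0.01, beta = 0.01, max_samples = 1e5,
                        seed = 1) {
  stopifnot(inherits(spec, "pbltl_spec"),
            alpha > 0, alpha < 1, beta > 0, beta < 1, max_samples >= 1)
  eps <- check_region(eps, spec$theta)
  ul <- spec$theta - eps$eps1
  ur <- spec$theta + eps$eps2
  if (ul <= 0 || ur >= 1)
    stop("SPRT needs 0 < theta - eps1 and theta + eps2 < 1", call. = FALSE)
  sampler <- resolve_sampler(sampler, spec)
  inc1 <- log(ul / ur)               # log-LR increment for a satisfaction
  inc0 <- log((1 - ul) / (1 - ur))   # ... for a violation
  upper <- log((1 - beta) / alpha)   # accept H1 (reject H0)
  lower <- log(beta / (1 - alpha))   # accept H0
  n <- 0L; z <- 0L
  llr <- 0
  traj <- numeric(0)
  decision <- "budget_exhausted"
  repeat {
    n <- n + 1L
    x <- sampler(trace_seed(seed, n))
    if (monitor_outcome(x, spec$formula)) { z <- z + 1L; llr <- llr + inc1 }
    else llr <- llr + inc0
    traj[n] <- llr / log(10)
    if (llr >= upper) { decision <- "reject_H0"; break }
    if (llr <= lower) { decision <- "accept_H0"; break }
    if (n >= max_samples) break
  }
  new_bsmc_test(decision, n, z, traj, spec, method = "sprt",
                settings = list(alpha = alpha, beta = beta, eps = eps,
                                seed = seed, max_samples = max_samples),
                vacuous = FALSE)
}

new_bsmc_test <- function(decision, n, z, traj, spec, method, settings,
                          vacuous) {
  structure(list(
    decision = decision,
    satisfied = switch(decision, accept_H0 = TRUE, reject_H0 = FALSE, NA),
    n = n, z = z,
    log10_bf = traj[length(traj)],
    trajectory = traj,
    spec = spec, method = method, settings = settings, vacuous = vacuous),
    class = "bsmc_test")
}

#' @export
print.bsmc_test <- function(x, ...) {
  lab <- if (x$method == "bayes") "Bayesian sequential model checking"
         else "sequential probability ratio test (SPRT)"
  cat("\n\t", lab, "\n\n", sep = "")
  cat(sprintf("specification: P>=%g( %s )\n", x$spec$theta,
              unparse(x$spec$formula)))
  eps <- x$settings$eps
  cat(sprintf("indifference region: [%g, %g]\n",
              x$spec$theta - eps$eps1, x$spec$theta + eps$eps2))
  stat <- if (x$method == "bayes") "log10 Bayes factor" else "log10 LR"
  cat(sprintf("n = %d traces, z = %d satisfied, %s = %.3f\n",
              x$n, x$z, stat, x$log10_bf))
  cat("decision:", x$decision,
      if (!is.na(x$satisfied))
        sprintf("(specification %s)",
                if (x$satisfied) "satisfied" else "not satisfied") else
        "(no decision at sample budget)", "\n")
  if (x$vacuous) cat("note: degenerate hypothesis bound hit ",
                     "(indifference region touches 0 or 1)\n", sep = "")
  invisible(x)
}

#' @export
plot.bsmc_test <- function(x, ...) {
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s",
                 xlab = "samples drawn",
                 ylab = if (x$method == "bayes") "log10 Bayes factor"
                        else "log10 likelihood ratio", ...)
  if (x$method == "bayes") {
    graphics::abline(h = c(1, -1) * log10(x$settings$L), lty = 2, col = "grey40")
  } else {
    graphics::abline(h = c(log10((1 - x$settings$beta) / x$settings$alpha),
                           log10(x$settings$beta / (1 - x$settings$alpha))),
                     lty = 2, col = "grey40")
  }
  invisible(x)
}

## ---- sample-count profiles ------------------------------------------------

#' Mean sample count of the sequential tests across a parameter grid
#'
#' Runs a checker repeatedly on a fixture family at each point of a
#' parameter grid and records how many traces each decision consumed.
#' The hallmark shape is that the mean count peaks where the true
#' satisfaction probability `u(omega)` is closest to the threshold
#' `theta`, and that the Bayesian test needs fewer samples than the SPRT
#' far from the threshold.
#'
#' @param fixture a [build_fixture()] result (or any list with `model`,
#'   `formula`, `space`, `true_prob`).
#' @param theta threshold probability of the checked specification.
#' @param omega_grid list (or vector, for 1-D spaces) of parameter
#'   points.
#' @param runs independent seeded checker runs per grid point.
#' @param method `"bayes"` or `"sprt"`.
#' @param L,prior,alpha,beta,eps,max_samples checker settings.
#' @param seed master seed.
#' @return a data.frame with one row per grid point: `u` (true
#'   satisfaction probability), `mean_n`, `sd_n`, `accept_frac`,
#'   `budget_frac`, plus the parameter coordinates.
#' @export
sample_count_profile <- function(fixture, theta, omega_grid, runs = 200,
                                 method = c("bayes", "sprt"), L = 100,
                                 prior = beta_prior(1, 1),
                                 alpha = 0.01, beta = 0.01,
                                 eps = indifference(0.1),
                                 max_samples = 500, seed = 1) {
  method <- match.arg(method)
  eps <- check_region(eps, theta)
  spec <- pbltl_spec(fixture$formula, theta)
  horizon <- required_horizon(fixture$formula)
  if (!is.list(omega_grid)) omega_grid <- as.list(omega_grid)
  rows <- lapply(seq_along(omega_grid), function(g) {
    omega <- check_point(omega_grid[[g]], fixture$space)
    sampler <- trace_sampler(fixture$model, omega, horizon)
    res <- lapply(seq_len(runs), function(r) {
      s <- trace_seed(seed, g * 1000003L + r)
      if (method == "bayes")
        bsmc_verify(sampler, spec, L = L, prior = prior, eps = eps,
                    max_samples = max_samples, seed = s)
      else
        sprt_verify(sampler, spec, eps = eps, alpha = alpha, beta = beta,
                    max_samples = max_samples, seed = s)
    })
    ns <- vapply(res, `[[`, numeric(1), "n")
    dec <- vapply(res, `[[`, character(1), "decision")
    out <- as.data.frame(as.list(omega))
    out$u <- fixture$true_prob(omega)
    out$mean_n <- mean(ns)
    out$sd_n <- stats::sd(ns)
    out$accept_frac <- mean(dec == "accept_H0")
    out$budget_frac <- mean(dec == "budget_exhausted")
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  out
}
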