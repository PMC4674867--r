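# shared generators for property-style tests

# random BLTL formula over the given atom names, with temporal bounds <= 3
random_formula <- function(depth = 3, atoms = c("a", "b")) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(smcsynth:::bltl_atom(sample(atoms, 1)))
  }
  kind <- sample(c("NOT", "AND", "OR", "UNTIL", "FINALLY", "GLOBALLY"), 1)
  d <- sample(0:3, 1)
  switch(kind,
    NOT      = smcsynth:::bltl_not(random_formula(depth - 1, atoms)),
    AND      = smcsynth:::bltl_and(random_formula(depth - 1, atoms),
                                   random_formula(depth - 1, atoms)),
    OR       = smcsynth:::bltl_or(random_formula(depth - 1, atoms),
                                  random_formula(depth - 1, atoms)),
    UNTIL    = smcsynth:::bltl_until(d, random_formula(depth - 1, atoms),
                                     random_formula(depth - 1, atoms)),
    FINALLY  = smcsynth:::bltl_finally(d, random_formula(depth - 1, atoms)),
    GLOBALLY = smcsynth:::bltl_globally(d, random_formula(depth - 1, atoms)))
}

# random labeled trace over the given atoms, long enough for `formula`
random_trace_for <- function(formula, atoms = c("a", "b"), extra = 2) {
  len <- required_horizon(formula) + 1 + sample(0:extra, 1)
  labels <- matrix(stats::runif(len * length(atoms)) < 0.5, nrow = len,
                   dimnames = list(NULL, atoms))
  smcsynth:::trace_from_labels(labels)
}

# trace with the exact label matrix given as 0/1 columns
label_trace <- function(...) {
  smcsynth:::trace_from_labels(cbind(...) == 1)
}

# satisfaction sampler for a plain Bernoulli(u) outcome (no model involved)
bernoulli_sampler <- function(u) {
  force(u)
  function(seed) { set.seed(seed); stats::runif(1) < u }
}
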