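---
title: "Statistical model checking and parameter synthesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical model checking and parameter synthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcsynth)
```

This vignette records the models, algorithms and design decisions
behind `smcsynth`: what is computed, under which assumptions, which
numerical choices were made where several were defensible, and what the
shipped fixtures do and do not demonstrate about real models.

## Bounded temporal logic over finite traces

Specifications are bounded linear temporal logic (BLTL) formulas over
atomic propositions: `phi1 U[d] phi2` (bounded until), with
`F[d] phi = true U[d] phi` and `G[d] phi = !F[d] !phi` as derived
forms, plus the usual boolean connectives.  Atoms are either named
labels — predicates registered with the model and evaluated on each
state's variable valuation — or inline numeric comparisons such as
`pro > 10`, because in practice biological events are threshold
crossings on observables.

Two semantic choices deserve explicit record:

* **The until clause.**  We use the standard bounded-until semantics:
  `sigma^i |= phi1 U[d] phi2` iff there is an `l` with `0 <= l <= d`
  such that `sigma^(i+l) |= phi2` and `sigma^(i+j) |= phi1` for all
  `0 <= j < l`.  A published variant of this definition indexes the
  witness position as `i + 1`; that reading makes the bound `d`
  inert and contradicts the accompanying monitorability argument, so
  we treat it as a typographical slip and implement `i + l`.
* **The `d = 0` edge.**  `l = 0` is admitted, so `F[0] phi` is
  equivalent to `phi` and until can be discharged by its right operand
  immediately.

Every operator is bounded, so a formula's truth at position `i` depends
only on states `i` through `i + h`, where the horizon `h` follows the
recursion implemented in `required_horizon()`: 0 for atoms, the
children's maximum for connectives, `d` plus the children's maximum
for temporal nodes.  The monitor refuses traces shorter than the
horizon rather than returning a three-valued "unknown": every caller in
the package derives the simulation length from the formula, so a short
trace is a programming error, not a condition to absorb silently.

Evaluation fills a bottom-up table of truth values per (subformula,
position) — linear in formula size times trace length, which matters
when a sequential test monitors thousands of traces.  A deliberately
naive recursive evaluator is kept alongside it as an oracle; the test
suite checks the two agree exhaustively over all `4^6` joint label
sequences of a length-6 trace for an until formula, and over a thousand
random formula/trace pairs.

In the derived-operator rewriting, `true` is a first-class constant
node rather than an encoded tautology over some registered atom; this
keeps the rewrite independent of any proposition registry and preserves
horizons exactly.

## Models and the sampler contract

The checker needs nothing from a model beyond i.i.d. sampled traces.
Production models therefore enter through a sampler contract — a
function `(omega, horizon, seed) -> trace` — while the explicit
`pardtmc()` class (state list, initial distribution, parameterized
kernel rows, labeling) exists for desk-scale fixtures where exact
answers are computable.  `enumerate_paths()` and
`exact_satisfaction_probability()` multiply kernel probabilities along
every path up to the formula horizon; they refuse instances beyond a
configurable path-count cap (default `1e6`) because exhaustive
enumeration is exactly the expense that statistical checking is meant
to avoid — these functions are oracles for tests, not a verification
route.

Each sampled trace draws from a private RNG stream derived from a
master seed and the trace index, so runs are bit-reproducible and
traces are independent regardless of evaluation order.

Three fixtures with closed-form satisfaction probabilities anchor the
tests: a Bernoulli branching chain (`u(p) = p`), a logistic variant
over a 2-D parameter (`u = plogis(w1 + w2)`), and a fixed 3-state
chain whose horizon-2 path distribution was hand-multiplied before the
enumeration code was written.  A two-agent toy model with an exactly
tabulated joint kernel demonstrates the agent-based-model-to-Markov-
chain reduction: the test compares empirical transition frequencies
from `1e5` agent-level steps against the tabulated kernel cell by cell.

## The Bayesian sequential checker

To decide `M |= P>=theta(phi)` we test the relaxed hypotheses
`H0: u >= theta + eps2` against `H1: u <= theta - eps1`.  Inside the
indifference region `[theta - eps1, theta + eps2]` either answer is
acceptable by construction; the half-widths are the user's statement
of how much deviation from `theta` is scientifically meaningless.

After each monitored trace the Bayes factor of the two partial
prior-weighted likelihood integrals is recomputed.  For the conjugate
Beta(a, b) prior the Beta-function normalizers cancel and

```
B = (1 - I_{theta+eps2}(z + a, n - z + b)) / I_{theta-eps1}(z + a, n - z + b),
```

one `pbeta` call per bound, computed in log space (`B` spans many
orders of magnitude; trajectories are logged as log10).  An arbitrary
prior may be supplied as a tabulated density and is integrated by
trapezoid on its grid; the closed form is cross-checked in the tests
against adaptive quadrature of the defining integrals over roughly
2,300 parameter combinations at a relative tolerance of `1e-8`.

Degenerate bounds get explicit treatment rather than exceptions:
`theta - eps1 = 0` makes the denominator integral literally zero, so
`B = +Inf` is returned with a `vacuous` flag and the checker accepts
immediately; symmetrically `theta + eps2 = 1` yields `B = 0`.

Stopping: `B > L` accepts `H0` (the specification is reported
satisfied), `B < 1/L` rejects it.  Because the loop need not terminate
when `u` lies inside the indifference region, a `max_samples` cap
(default `1e5`) produces the distinct outcome `budget_exhausted` —
never coerced to a decision.

The SPRT baseline runs Wald's test on the same relaxed hypotheses with
log-likelihood-ratio increments `log(u_l/u_r)` per satisfaction and
`log((1-u_l)/(1-u_r))` per violation, with thresholds
`(1-beta)/alpha` and `beta/(1-alpha)`.  Deterministic checks pin both
procedures to their closed forms: with `theta = 0.5`,
`eps1 = eps2 = 0.1`, `L = 100` and a uniform prior, an
always-satisfying sampler accepts at exactly `n = 5` (the trajectory
`B_n = (1 - 0.6^(n+1)) / 0.4^(n+1)` passes 100 between `n = 4`, where
it is 90.06, and `n = 5`, where it is 232.75), and the SPRT at
`alpha = beta = 0.01` accepts at exactly `n = 12` (the first `n` with
`(2/3)^n <= 0.01/0.99`).

## Annealed parameter search

The sample count `n` the checker consumes grows as the candidate's
true satisfaction probability `u(omega)` approaches `theta` — the
sample-cost profile across a parameter grid peaks at the grid point
nearest the threshold.  The search exploits this as a fitness surface:

* the initial point is uniform over the bounding box;
* candidates come from a Gaussian perturbation with per-dimension
  standard deviation `scale` times the dimension's range, clipped to
  the box; `scale` defaults to 0.2 after benchmarking on the Bernoulli
  fixture showed 0.1-of-range steps mix too slowly for the default
  cooling schedule (more budget-exhausted searches, double the
  runtime, lower-quality recoveries over hundreds of seeded runs);
* a move to a strictly larger `n` is always taken; otherwise it is
  taken with probability `exp(-(n - n')/t)` — so equal fitness is
  always accepted — under the geometric schedule
  `T(k) = t_start * 0.95^k`, stopping below `t_stop`;
* the first candidate the checker *accepts* ends the search
  immediately; if the temperature floor is reached first the result is
  `not_found`.  Budget-exhausted checker calls contribute `n = cap` as
  fitness and are logged distinctly.

Two repairs to the printed algorithm this search follows are worth
stating plainly.  As printed, the downhill branch accepts a worse
candidate when `rand(0,1) > exp(-(n'-n)/t)`; for `n' <= n` the
right-hand side is at least 1, so nothing worse would ever be
accepted — contradicting the stated purpose of annealing.  We
implement the standard Metropolis form (accept worse with probability
`exp(-(n-n')/t)`).  Likewise the checker call on the candidate point
is printed with the prior family evaluated at the *incumbent*; we pass
the prior for the point actually being checked.

What the algorithm guarantees — and what it does not.  An accepting
verdict certifies `u >= theta + eps2` only up to the checker's error
rate: accepts at `u` inside the indifference region are legitimate
answers of the relaxed test, and the roughly `1/L` false-accept rate
below `u_l` compounds over the many checker calls a search makes
because the first accept returns.  On the Bernoulli recovery benchmark
(`theta = 0.6`, `eps = 0.05`, `L = 100`) this materializes as a small
fraction of searches ending just below the threshold; raising `L`,
shrinking `eps`, or re-verifying found points (as
`run_case_study()` does with fresh traces) are the available remedies,
at proportional sampling cost.

Multiple specifications can be synthesized jointly — every
specification must accept at a candidate, with the summed sample count
as fitness — or per specification in separate runs; both modes exist
because a single joint run and four independent searches are equally
defensible readings of the case study.

## The inflammation demonstration model

The case-study target is an agent-based model of the acute
inflammatory response to Gram-negative bacterial endotoxin (LPS).  The
published model's internal update rules are not available, so this
package ships an explicitly labeled *interpretation*: a minimal
discrete-time stochastic system that honors the name and role of each
of the 28 synthesized parameters — 14 core dynamics parameters and 14
dosing-schedule parameters across four experiments (single low dose,
single high dose, and two paired-dose regimens) — without claiming
quantitative fidelity to the original.  Reproducing the published
parameter values is a non-goal: they are the output of one stochastic
search on an unavailable model.

Per step (one abstract time unit), with all stochastic choices seeded:

* scheduled dosing adds `amount/duration` LPS per step while the
  continuous-time dose window overlaps the step's interval;
* LPS, the pro- and anti-inflammatory mediators and tissue damage decay
  by their `*-evap` fractions;
* resting macrophages activate with hazard
  `(mac-act-LPS + mac-act-pro * pro) * LPS + mac-act-dam * dam` —
  the pro-mediator *amplifies* endotoxin-driven activation rather than
  acting alone, and damage is the only stimulus that persists after
  the endotoxin clears.  An earlier candidate with an additive
  `mac-act-pro * pro` term made chronic activation the attractor from
  essentially everywhere in the box, leaving the resolving behavior
  unreachable; the multiplicative form gives the model both a
  resolving regime (default once LPS clears) and a non-resolving one
  (through the damage feedback loop), which is precisely the dichotomy
  the behavioral specifications describe;
* activation and death are binomial draws (`1/mac-age` death hazard),
  regeneration is Poisson toward the baseline pool at rate
  `1/mac-regen`; a deterministic mode replaces these draws by their
  expectations and exists solely for the monotonicity and decay tests;
* mediators are produced proportionally to the activated count
  (`mac-prop`, `mac-anti`); damage production saturates in the
  pro-mediator (`max-pro-dam`, half-saturation `pro-dam-thresh`) and
  is attenuated by anti-mediated healing (half-saturation
  `anti-heal-thresh`).

Atomic propositions are threshold events on the observables — `D`,
`D_L`, `D_H` for an administered dose (any / at most `dose_low` / at
least `dose_high` per step), `I`/`N` for inflammation onset and return
to baseline, `I_L`/`I_H` for lower/higher inflammation levels — and
the ten step bounds `delta_1..delta_10` of the four specifications are
configuration with package defaults, since none of these constants are
quantified in the source material.  The default step bounds allow 10
steps for inflammation onset and 40 for resolution, matching the
demo's decay time-scales.  The four encoded properties are

1. `D_L -> F[d1](I & F[d2] N)` — resolving inflammation,
2. `D_H -> F[d3](G[d4] I_H)` — non-resolving inflammation,
3. `D -> F[d5](I_L & F[d6](D -> F[d7] I_H))`,
4. `D -> F[d8](I_H & F[d9](D -> F[d10] I_L))`.

The prose accompanying the original list pairs property 3 with
desensitization in one place and with priming in another; the package
keys everything by formula index and never by those labels.  Note also
that properties are checked at trace position 0, so an implication
whose dose antecedent fails there is vacuously satisfied; the default
search box forces the first experiment's dose window to overlap step 0
and caps its rate below `dose_low`, making specification 1's
antecedent genuinely hold on every trace.

## Problem sizes and runtime choices

The shipped tests and the reproduction script use desk-scale sizes
chosen to exercise every claim while keeping a full run in the low
minutes on one CPU: exhaustive monitor checks at trace length 6 over
two atoms; ~2,300 Bayes-factor quadrature comparisons; 200 seeded
checker runs per decision-accuracy setting; a 9-point sample-cost grid
at 200 runs per point with a 500-sample cap; 20 seeded recovery
searches with a 150-sample cap per checker call; and one
reduced-budget case-study search re-verified on 50 fresh traces.
Sequential-test caps in these experiments bound worst-case runs inside
the indifference region, where the test is allowed not to terminate.

## Limitations

* The fixtures are Bernoulli-like by design — their satisfaction
  probabilities are known exactly, which is what makes them oracles.
  Passing tests on them demonstrates the correctness of the monitor,
  the checker's stopping behavior and the search plumbing; it says
  nothing about identifiability or search difficulty on models with
  rugged fitness landscapes.
* The inflammation model is an interpretation at the scale of a unit
  demonstration: agent counts in the tens, mediators as scalar pools,
  no spatial structure.  Its role is to exercise the full pipeline on
  a 28-dimensional box with realistic specification structure.
* Unbounded temporal operators, continuous-time semantics and
  robustness degrees are out of scope; so are exact probabilistic
  model-checking engines beyond the small-instance enumeration oracle.
* Found parameter points are certificates of the sequential test, not
  of the model: their guarantee is bounded by the checker's error
  rates, as discussed above.
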