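---
title: "Methods: panel-observed multistate Markov models for stroke outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-observed multistate Markov models for stroke outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemsm)
```

## The model

`strokemsm` models post-stroke functional status as a three-state
continuous-time Markov chain: good outcome (1, MRS < 3), poor outcome
(2, MRS 3–5) and death (3, MRS 6, absorbing). Four instantaneous
transitions are allowed by default — deterioration 1→2, recovery 2→1, and
death from either transient state (1→3, 2→3). The generator Q has
off-diagonal intensities `q_ij` (units 1/month), diagonal
`q_ii = −Σ_{j≠i} q_ij`, and an all-zero death row.

Baseline covariates act proportionally on each intensity,
`q_ij(z) = q_ij(0) exp(β_ij'z)`, so `exp(β_ij)` is the hazard ratio of one
covariate on one transition. Three coefficient layouts are available:
unrestricted (the default — separate coefficients per transition, which is
how per-transition hazard ratios are usually reported), a restricted
variant sharing one coefficient vector across all forward and one across
all backward transitions, and a symmetric variant in which the backward
vector is the negated forward one. The restricted variants reduce the
parameter count at the cost of assuming a common covariate effect within
direction.

Key assumptions: the Markov property (the future depends only on the
current state), time-homogeneous intensities (constant over follow-up),
baseline-fixed covariates, and exponential sojourn distributions implied
by the chain. Time enters the likelihood only through interval lengths.

## The panel likelihood

Exact transition times are unobserved; data are states at visit times.
Each consecutive visit pair contributes
`log P(Δt; z)[x_prev, x_next]` with `P(t) = exp(Qt)` solving the Kolmogorov
forward equations; subjects contribute independently. Two conventions for
death are provided:

* **panel death (default)** — death is recorded at the scheduled visit
  following the event, so a death observation is an ordinary panel
  transition probability. This matches quarterly chart-review designs in
  which death is discovered at the next scheduled contact.
* **exact death** (`death_exact = TRUE`) — a visit row flagged `exact`
  contributes the density `Σ_k P(Δt)[i,k] q_k3` (in some transient state k
  just before death). Registry-linked studies with exact death dates would
  use this.

Probabilities are floored at 1e-300 before logs so an impossible-looking
pair (under a degenerate parameter point visited by the optimiser) yields a
very unfavourable but finite log-likelihood instead of `-Inf`.

Pairs sharing a covariate pattern and interval length share P, so the
likelihood is evaluated by aggregating pairs into (z, Δt) groups once and
computing one matrix exponential per group — the dominant cost of a fit.

## Numerical choices

* **Matrix exponential:** scaling-and-squaring with a degree-13 Padé
  approximant (the standard Higham algorithm), with tiny negative entries
  clipped, rows renormalised, and absorbing rows set exactly.
  Eigendecomposition is deliberately avoided: generators with repeated
  eigenvalues can be defective. The test suite checks this path against
  two independent routes — `Matrix::expm` and direct numerical integration
  of dP/dt = PQ with `deSolve` — to 1e-8 or better.
* **Optimiser:** quasi-Newton (L-BFGS-B) on the unconstrained working
  scale (log intensities, raw coefficients); positivity of intensities is
  structural, not a constraint. Wide box bounds (log q ∈ [−20, 5],
  β ∈ [−10, 10]) keep essentially unidentified parameters (e.g. a direct
  good→death rate supported by a handful of events) finite without
  affecting interior solutions. Up to 500 iterations; relative
  log-likelihood tolerance 1e-9; the gradient norm at the optimum is
  reported in the convergence record.
* **Starting values:** crude occurrence/exposure rates — observed r→s
  pairs divided by total time in intervals originating in r — with a
  0.01/month fallback for unobserved transitions; coefficients start at 0.
  This is deterministic, so fits are reproducible without random restarts.
* **Uncertainty:** central finite-difference Hessian of the negative
  log-likelihood (step 1e-4 on the working scale); the covariance is its
  inverse, symmetrised. Hazard-ratio and intensity intervals are Wald
  intervals on the working scale, exponentiated. A non-invertible Hessian
  is flagged and the covariance omitted rather than fabricated.
* **Ties and degenerate input:** duplicate visit times are an error (or
  drop the subject under `coerce`); zero-length intervals are rejected;
  a transient state with zero exit rate reports an infinite sojourn with a
  warning; rows with zero transition totals get all-zero proportions.

## Data handling policies

The visit-count filter defaults to 3 (a common cohort inclusion
criterion) but is configurable; two-visit subjects still carry likelihood
information, so the filter is a data-cleaning policy, not a model
requirement — the synthetic generator keeps every subject with at least
two visits precisely so that simulation-based calibration is not biased by
conditioning on survival to a third visit. Missing MRS values drop the
visit and widen the interval (the panel likelihood handles irregular gaps
natively; no imputation). The Glasgow coma scale enters as two indicator
columns (moderate, severe) against a mild reference; all binary covariates
code the exposed category as 1. The direct good→death intensity is kept
free by default — such transitions, though rare per interval, are
observable — with a configuration switch (`good_death_allowed = FALSE`) to
exclude it.

## Diagnostics

Observed prevalence at time t carries each subject's last observation at
or before t forward (death persists); dropouts keep their last state in
the denominator, with an alternative `censor` mode that removes them.
Expected prevalence conditions on each subject's observed baseline state
and covariates — the stricter reading of the usual "everyone starts
together" convention when covariates are heterogeneous — and averages rows
of P(t) over subjects. Expected survival from state i is
`1 − P(t)[i, death]`. The per-interval descriptive transition table and
the fitted intensities answer different questions (a 3-month transition
proportion mixes multiple jumps; an intensity is instantaneous), and the
package reports both without equating them.

Sojourn-time tables per covariate level hold all other covariates at their
reference level by default (the one-at-a-time presentation used in
clinical reports); a `marginal` mode instead averages −1/q_ii over the
empirical covariate distribution with the focal covariate forced to each
level, which is preferable when reference levels are rare in the data.

## The synthetic cohort generator

`cohort_spec()` defaults emulate the design of the motivating hospital
cohort: 298 subjects, visits at 0, 3, …, 36 months, binary covariate
prevalences (female 0.456, hypertension 0.47, diabetes 0.322, hemorrhagic
stroke 0.258, atrial fibrillation 0.319), a 191/35/72 mild/moderate/severe
Glasgow split, and a 93/205/0 baseline state mix. The age-60+ prevalence
is not published for that cohort and defaults to 0.5. The default
generating intensities (0.10, 0.001, 0.24, 0.09 per month) are a fixture
chosen to echo the published per-interval transition proportions so
synthetic descriptive tables look familiar; they are documented as a
fixture, not as estimates. Trajectories are simulated by competing
exponentials (Gillespie), observed at the schedule, with death recorded at
the next scheduled visit by default or at its exact time on request, and
optional state-independent dropout. Per-subject RNG substreams derived
from the cohort seed make output byte-reproducible and stable under
reordering.

What the generator does **not** emulate — and therefore what passing
simulations cannot certify about real data: correlated covariates (only
marginals are published; draws are independent, with baseline state drawn
independently of covariates), time-varying risk factors, non-exponential
sojourns, informative dropout, misclassified states, and visit-time drift
around the quarterly schedule (arbitrary positive times are accepted by
the likelihood, but the generator visits on schedule).

## Problem sizes in the test suite

Validation balances sharpness against runtime on a single CPU: hazard-ratio
recovery uses 20 replicates of n = 2000–3000 per scenario; likelihood-ratio
size is estimated from 500 null replicates at n = 300; Wald coverage from
300 fits at n = 400; prevalence self-consistency from one n = 10,000
cohort; matrix-exponential and semigroup identities from 100–200 randomised
generators. These sizes are the package's own validation design.

## Known limitations

Time-homogeneity is assumed, not tested against a time-varying
alternative (the likelihood-ratio machinery compares nested covariate
models on identical data). There is no misclassification (hidden Markov)
layer, no frailty or clustering, no bootstrap intervals, and no formal
goodness-of-fit statistic beyond the descriptive prevalence comparison.
Wald intervals can be poor for transitions supported by very few events —
visible as extremely wide intervals, as for direct good→death effects in
quarterly panels.
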