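---
title: "Instrumental causal forests for encouragement designs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrumental causal forests for encouragement designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Large social programmes are often rolled out as cluster-randomised
*encouragement* designs: an area is randomly assigned to the programme
(`Z`), but actual enrolment (`D`) is voluntary and targeted, so some
assigned households never enrol and some control households enrol anyway.
A regression of the outcome `Y` on `D` is then confounded by selection
into enrolment. With randomised assignment as an instrument, the causal
effect is identified for *compliers* — units whose enrolment follows
their assignment. `cctforest` estimates that local average treatment
effect (LATE), its conditional version CLATE as a function of covariates,
and downstream summaries of effect heterogeneity, for binary utilisation
outcomes of the kind collected in conditional cash transfer evaluations
(assisted delivery, facility delivery, pre- and post-natal visit
thresholds).

## Model and estimator

The structural model is

    Y_i = m(X_i) + tau(X_i) D_i + eps_i,

with `m` an unrestricted nuisance function and `eps` mean-independent of
assignment given covariates. Under instrument relevance and the exclusion
restriction,

    tau(x) = Cov(Y, Z | X = x) / Cov(D, Z | X = x),

the conditional Wald ratio: the conditional intention-to-treat effect
over the conditional complier share. The estimator follows the
generalised-random-forest recipe:

1. **Nuisances.** Three honest regression forests estimate
   `m(x) = E(Y|X)`, the treatment propensity `e(x) = P(D=1|X)` and the
   instrument propensity `g(x) = P(Z=1|X)`, all predicted out-of-bag.
   When supply-side covariates (health-worker availability terciles,
   facility-concern indicators) were used to determine eligibility, they
   are excluded from the `e(x)` model (`exclude_supply_from_e`, default
   on for tagged datasets) — they belong to the assignment mechanism, not
   the confounding structure.
2. **Residualise.** `Ytil = Y - m(X)`, `Dtil = D - e(X)`,
   `Ztil = Z - g(X)`.
3. **Instrumental forest.** Honest trees are grown on the residuals. At a
   parent node with local Wald estimate `tau_p` and moment
   `A_p = mean(Ztil * Dtil)`, each structure-half unit receives the
   gradient pseudo-outcome `rho_i = Ztil_i (Ytil_i - tau_p Dtil_i) / A_p`
   and the split maximises `sum_children (sum_child rho)^2 / n_child`.
   This is the standard computational surrogate for maximising
   within-leaf effect heterogeneity; re-solving the local 2SLS problem for
   every candidate split would be exact but quadratically more expensive
   and is not what this estimator family does in practice.
4. **Prediction.** `tau_hat(x)` solves the similarity-weighted moment
   condition: the weighted covariance ratio of `(Ytil, Ztil)` to
   `(Dtil, Ztil)`, with weights given by leaf co-membership in the
   estimation halves of (for training units) out-of-bag trees only.
5. **Aggregation.** Doubly robust scores
   `Gamma_i = tau_hat(X_i) + ((Z_i - g)/(g(1-g))) / delta(X_i) *
   ((Y_i - m) - (D_i - e) tau_hat(X_i))` average to the AIPW LATE with
   the i.i.d. standard error `sd(Gamma)/sqrt(N)`. The compliance score
   `delta(x) = E(D|X,Z=1) - E(D|X,Z=0)` comes from an auxiliary causal
   forest — the same machinery with `D` as outcome and `Z` as its own
   instrument.
6. **Heterogeneity summaries.** BLP (OLS of `Gamma` on `X` with HC1
   sandwich errors), CLAN (covariate means in the top vs bottom score
   quartile), split-frequency variable importance, and exhaustively
   searched policy trees of depth 2–3 maximising
   `(1/N) sum (2 pi(X_i) - 1) Gamma_i`.

## Parameters that matter

* `num_trees` (default 2000): the production setting; tests and examples
  use smaller ensembles because the estimates enter only through
  tree-averaged moments and converge quickly in the ensemble size.
* `sample_fraction` (0.5) and `honesty_fraction` (0.5): each tree sees
  half the data without replacement; half of that places splits, half
  estimates leaf moments. Without-replacement subsampling is what makes
  the out-of-bag and honesty contracts exact.
* `alpha` (0.05) and `min_node_size`: `alpha` bounds the child share of
  any split; `min_node_size` defaults to 5 structure units for
  regression forests, and for instrumental forests to
  `max(5, ceiling(n/100))`. The scaling rule is deliberate: local 2SLS
  leaf moments have variance proportional to the inverse leaf size, and
  with a fixed leaf size the dispersion of `tau_hat(X_i)` does not
  shrink as the sample grows. Scaling the leaf floor with `n` keeps the
  number of leaves roughly constant, so per-leaf moment noise — and with
  it the spread of CLATEs under a homogeneous truth — contracts at the
  root-n rate. An explicit `min_node_size` always overrides the rule.
* `mtry` (default `min(p, ceiling(sqrt(p)) + 20)`): covariates tried per
  split; tunable via `tune_iv_forest()`, which scores candidates by the
  out-of-bag squared moment violation
  `mean(((Ytil - tau_oob Dtil) Ztil)^2)` — a proxy that needs no ground
  truth. The proxy separates models that can and cannot see a genuine
  modifier, but is nearly flat across neighbouring settings; ties break
  toward smaller `mtry`, then stronger node regularisation.

## The synthetic generator

`synth_generate()` emulates the statistical structure the analysis
assumes, not any particular survey: principal strata drawn i.i.d. with
configurable shares (the `pkh2009`/`pkh2013` presets use
complier/always/never shares of 0.398/0.096/0.506 and 0.344/0.137/0.519,
the published decomposition of the two follow-up waves), 50/50
assignment optionally constant within clusters, treatment received
determined by the monotonicity rule, and binary potential outcomes from
a clipped linear probability model
`P(Y(d)=1) = clip(m(x) + tau(x) d, 0.01, 0.99)`. The linear probability
form keeps the true `tau(x)` in the same risk-difference units the
estimators report; a latent-index link would not. Baseline rates in the
presets span roughly 0.34–0.73, inside the 0.3–0.85 range typical of
maternal-utilisation outcomes, and effects vary with supply terciles and
household amenities. One integer seed drives four independent
sub-streams (covariates, strata, assignment, outcome noise) so that,
for instance, assignment can be redrawn while potential outcomes stay
bit-identical — the exclusion restriction holds mechanically and is
testable. (A three-stream design with assignment folded into the strata
stream would make that check impossible, which is why the package uses
four.)

What the generator does **not** emulate: multi-stage cluster sampling
frames, survey attrition and non-response, within-cluster outcome
correlation (units are i.i.d. given X; no published value was available
to calibrate one), measurement error in self-reported utilisation, and
strata whose composition drifts over waves. Passing recovery tests on
this generator therefore demonstrates correctness of the estimator
implementation under the maintained assumptions — not robustness to the
ways real survey data violate them.

`planted_binary` plants a single binary modifier (`tau = 0.4 x1`) among
noise covariates under the 2009 compliance regime; it is the benchmark
for every heterogeneity summary. The compliance shares are kept at the
application's values rather than an easier full-compliance setting, so
recovery is demonstrated at a realistic first-stage strength.

## Numerical conventions and degenerate cases

* Wald denominators below `1e-10` in absolute value return a degenerate
  marker; during tree growth a degenerate node inherits its parent's
  estimate, and at prediction a degenerate weighted denominator falls
  back to the global residualised Wald estimate, always flagged.
* A forest in which no tree places any split (e.g. `min_node_size = n`)
  carries no covariate information; its weights are uniform by
  convention, so every prediction equals the global Wald estimate
  exactly rather than a subsample-weighted approximation of it.
* Propensities are clipped to `[0.01, 0.99]` and compliance scores
  floored at `0.01`, with clipping events recorded; raw negative
  compliance scores are reported as a monotonicity concern, never
  silently repaired.
* Split ties resolve to the lowest covariate index, then the lowest
  threshold; policy-tree ties resolve lexicographically with not-treat
  before treat. All randomness flows through explicit integer seeds and
  a package-internal generator, so identical inputs give bit-identical
  forests across platforms.
* The printed decomposition convention for strata shares rounds the
  always- and never-taker percentages to one decimal and reports the
  complier share as the complement, which is the only convention under
  which the published 2009 numbers are mutually consistent; the raw
  convention (complier share = first-stage difference) is also available.
* SMD balance checks use the pooled-SD denominator
  `sqrt((s0^2 + s1^2)/2)`; the source tables do not state their
  denominator, and pooled is the common default.
* Tercile encoding uses the inclusive (type 1) empirical quantile with
  ties to the lower tercile, so heavily tied columns (e.g. 60% zeros)
  place all tied values in the first indicator and the indicators always
  partition the sample.

## Design decisions that were genuinely open

* **BLP standard errors** are heteroskedasticity-robust by default: the
  scores inherit the `1/delta(X)` and `1/(g(1-g))` factors and are
  heteroskedastic by construction. Classical errors remain available.
* **CLAN ranks by `Gamma_i`** (the score, as the method prescribes), not
  by `tau_hat(X_i)`; a `rank_scores` argument allows the alternative for
  sensitivity analysis, since the two orderings can differ when the
  correction term is large.
* **Variable importance** uses depth-weighted split frequency
  (`max_depth = 4`, `decay = 2`). A variance-weighted variant is also
  implemented (`mode = "variance"`); descriptions of this diagnostic mix
  the two conventions, so outputs record which was used. Only rankings
  are meaningful.
* **Policy search space**: indicator covariates with thresholds fixed at
  0.5, which makes exhaustive search exact; sibling leaves may share an
  action, so depth-`d` search dominates all shallower policies. Values
  are in-sample; an honest train/evaluate split is a caller-level choice
  (learn on one subset of scores, evaluate with `policy_value()` on
  another).
* **No cluster adjustment** in standard errors: the estimation treats
  units as i.i.d.; cluster-level assignment in the generator exists to
  study the consequences, not to correct for them.

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise the estimator at n = 4000
with 200-tree ensembles for single-fit recovery, 200 replications at
n = 2000 with 50 trees for interval coverage, and 50 replications at
n = 4000 with 60 trees for importance-ranking stability. These sizes were
chosen so the whole validation cycle completes in a few minutes on one
core while keeping Monte Carlo error well below the margins being
asserted; the estimator itself has no dependence on these choices.

## Known limitations

* Per-unit CLATEs carry no confidence intervals; inference aggregates
  through the doubly robust scores (LATE, BLP, CLAN).
* The exhaustive policy search is exponential in depth and is capped at
  depth 3; continuous thresholds, costs and budget constraints are out
  of scope.
* The 2SLS baseline supports one endogenous regressor and one
  instrument, which is the design under study.
* Treatment is binary enrolment; dose-response in the transfer amount is
  not modelled.
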