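---
title: "Comparing model selection methods for the LBA: models, metrics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing model selection methods for the LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling choices behind `lbaselect`: the
likelihood, the model space and its priors, the sampler, the nine
selection metrics, the scoring rules, and the synthetic design — together
with the numerical decisions and their rationale, and what the package's
tests do and do not establish.

## The likelihood

Each accumulator races linearly from a start point `U(0, A)` toward a
threshold `b` with a trial-wise drift rate drawn from `N(v, sv)` truncated
below at zero; the observed response time adds a non-decision offset `t0`.
The first-passage density and distribution function of one accumulator are
the classical closed forms for untruncated normal drift, divided by
`pnorm(v / sv)` so that they condition on a positive drift. Truncation is
applied per accumulator. Two consequences matter:

* every accumulator finishes almost surely, so each node's finishing-time
  density integrates to one, and the defective densities of the two
  responses (winner density times loser survivor) sum to one over
  responses — there is no "no response" mass;
* the likelihood of a trial is evaluated at decision time `rt - t0` and
  floored at `1e-10` before taking the log (`floor` argument throughout).
  The floor keeps single outlier trials — or proposals with `t0`
  exceeding an observed RT — from producing `-Inf` log-likelihoods that
  would stall the sampler. The floor value is exposed and tests cover the
  flooring rule explicitly.

`sv_c` is fixed to 1 to satisfy the model's scaling property; all times
are seconds.

## Model space and priors

The four variants share one parameter block; condition differences enter
through `v_c` (drift variant), `b` (threshold variant), or both
(complex). Free parameter counts are 6 / 7 / 7 / 8. Two structural
choices:

* the threshold is sampled as `B = b - A` with prior `TN(2, 2, 0, Inf)`,
  and `b` is derived as `A + B`. This keeps the prior block literal and
  makes the support a product of half-lines (`b >= A` holds by
  construction);
* under the per-condition parameterization, each condition's varying
  parameter carries an independent copy of the printed prior.

The mean/difference reparameterization replaces a varying pair by
`X_mean` and the half-difference `X_diff`
(`X_1 = X_mean - X_diff`, `X_2 = X_mean + X_diff`). The mean keeps the
default prior; the half-difference receives `N(0, sd)` with sd 10 (UP), 1
(WIP), 0.1 (MIP), or 0.01 (HIP). The second argument of every prior is a
standard deviation. The half-difference prior is left untruncated: support
is enforced through the mapped condition-level values instead (the log
prior is `-Inf` whenever a mapped `v_c` or `b - A` would be negative).
This was a genuinely open choice; enforcing support on the mapped scale
keeps the printed difference priors symmetric around zero.

## Sampling

Posteriors are estimated by differential-evolution MCMC: `3k` chains for
`k` free parameters, crossover proposals
`theta* = theta_i + gamma (theta_m - theta_n) + U(-0.001, 0.001)` with
`gamma = 2.38 / sqrt(2k)`, plus a migration step (probability 0.05,
burn-in only) that cycles states through a random chain subset and
rescues outlier chains. Chains start from prior draws redrawn until the
log posterior is finite.

Thermodynamic integration uses one run in which each chain targets the
power posterior `p(theta) p(y|theta)^t` at its own temperature, with the
fifth-power ladder `t_j = ((j-1)/(J-1))^5` and `J = 40` rungs by default;
the rung at `t = 0` samples the prior and the rung at `t = 1` the
posterior. The ladder's mean log-likelihood per rung is integrated by the
trapezoidal rule.

One initialization choice deviates from the plain prior-start rule: when
the pipeline runs a ladder it warm-starts every rung from the retained
draws of the ordinary posterior fit of the same model (the standalone
`power_posterior_run()` still defaults to prior starts, and accepts an
`init` matrix). With a single chain per temperature, prior-started
high-temperature rungs can take very long to reach the posterior's
typical set — crossover differences between rungs are large relative to
the `t = 1` posterior scale — and a stuck rung corrupts the integral by
tens of nats. Warm starts leave every rung's stationary distribution
unchanged and remove that failure mode; the low-temperature rungs relax
outward to the prior quickly because wide targets accept readily.

Convergence is monitored with a split-chain potential-scale-reduction
diagnostic (`split_rhat()`); fits above 1.1 are flagged rather than
discarded, matching the package's use of decisions (model selections)
rather than parameter point estimates as the quantity of interest.

## The metrics

All deviance-scale criteria use the convention that the "maximum
likelihood" is the best per-draw log-likelihood contained in the retained
posterior. DIC uses the minimum-deviance point as its plug-in
(`P_D = max log-lik - mean log-lik`), and DIC_p applies the identical
mechanics to the unnormalized log posterior. WAIC's penalty is the summed
per-trial sample variance (denominator `S - 1`) of the log-likelihood.
BIC's `n` is the total trial count over both conditions (600 at the
design's default).

The chi-squared tree compares the better single-effect model against the
null (df 1); if significant, that model against the complex model (df 1);
otherwise null against complex (df 2, the parameter-count difference).
`alpha = 0.05` by default and exposed in the configuration. A negative
deviance improvement is clamped to a zero statistic.

Bridge sampling splits the retained draws in half: the first half fits a
moment-matched multivariate normal proposal on the natural parameter
scale, the second half enters the optimal-bridge iteration together with
as many fresh proposal draws as there are retained draws; the iteration
runs to relative tolerance `1e-10` (at most 1000 iterations), and
non-convergence is flagged rather than fatal. Proposal draws landing
outside the support contribute zero posterior density, which the
estimator handles without bias. No unbounded reparameterization is
applied; the posteriors sampled here sit far from their boundaries, and
the conjugate-model tests confirm accuracy to well under 0.05 nats.

The augmented ROPE rule derives the posterior of each condition
difference on the natural scale (`v_c[2] - v_c[1]`, `b[2] - b[1]`) from
the complex-model fit and declares an effect present when more than half
of the difference draws fall outside its region of practical equivalence
(drift `[-0.3, 0.3]`, threshold `[-0.11, 0.11]` — the parameter changes
that define a small effect). An exact 50/50 tie counts as absent
(conservative; a measure-zero event). The two binary decisions combine
into one of the four variants, so a model is selected in every instance.

## Scoring

Weights over the four variants are `exp(-0.5 delta)` on the deviance
scale and `exp(delta)` on the log-marginal-likelihood scale, normalized
after subtracting the best value. For ROPE the weight of a variant is the
product over the two effects of the posterior proportion outside (effect
in the variant) or inside (not in the variant) its ROPE — the effects are
treated as independent binary cases; the exact construction used for the
original figures is not published, so treat cross-study comparisons of
ROPE Brier scores with care.

The raw Brier score over `R` outcomes, `(1/R) sum_i (f_i - o_i)^2`, is
mapped onto `[-1, 1]` by a piecewise-linear adjustment through three
anchors: perfect forecast 1, uniform forecast 0, all-mass-on-wrong -1.
With `B_c` the raw score of the uniform forecast and `B_max = 2/R`,
`adjusted = 1 - B/B_c` below chance level and
`-(B - B_c)/(B_max - B_c)` above. **This adjustment is a
reconstruction**: any monotone map through the three anchors preserves
orderings but not intermediate values, so adjusted scores are comparable
within this package, not numerically against other implementations.
Per-effect Brier scores apply the same adjustment to the two-outcome
forecast (`P(effect present)` = summed weights of the variants containing
the effect). The chi-squared test yields no forecast probabilities and is
excluded from Brier scoring.

## The synthetic design

The main design crosses drift and threshold effects of size none / small /
moderate / large: 1 null cell, 6 one-way cells, and 18 two-way cells
(3 x 3 sizes x extreme / balanced arrangement), each with 100 replicate
datasets of 300 trials per condition generated from identical parameter
values. Baselines: `v_c = 3, v_e = 2, sv_c = sv_e = 1, A = 1, b = 2,
t0 = 0.3`. Effects raise `v_c` to 3.3 / 3.75 / 4.25 or lower `b` to
1.89 / 1.74 / 1.595 — values calibrated to standardized RT differences of
about 0.2 / 0.5 / 0.8 between conditions. One-way effects, and the drift
component of two-way effects, manipulate condition 2; the "balanced"
arrangement puts the threshold decrease in condition 1 (the labels are
exchangeable; only the same-vs-different-condition structure matters).

The effect-size statistic is the pooled-SD standardized mean difference
over *all* RTs, correct and error pooled — a reconstruction, since the
original definition (which trials, which SD) is not printed. One subtlety
drove its exact form: because a drift draw can land arbitrarily close to
zero, the LBA's winning-time distribution has a roughly `t^-2` tail and
its variance diverges logarithmically, so a single pooled SD over
hundreds of thousands of trials is dominated by a handful of extreme
trials and keeps drifting with the simulation size. The package therefore
evaluates the statistic at the design's own scale: many pseudo-experiments
of 300 trials per condition, Cohen's d within each, averaged
(`calibrate_effect_size()`, with the single-pool variant available via
`trials_per_experiment = NULL`). Under this definition the printed
manipulations reproduce the 0.2 / 0.5 / 0.8 anchors to within about 0.01,
which is itself the strongest available evidence that the original
calibration worked at experiment scale; the single-pool variant lands
systematically lower (about 0.47 for the moderate threshold change) and
noisier.

The sample-size follow-up takes the five most diagnostic cells (null, the
two small one-way cells, and the two small/small two-way cells) at 30 /
100 / 300 / 900 trials per condition; the prior follow-up takes the same
five cells with the reparameterized models and a chosen prior level.

Replicate seeds derive deterministically from the master seed, the cell,
and the replicate index, so any subset of a study can be reproduced in
isolation and execution order never matters.

### What the generator does and does not emulate

Synthetic data are exactly LBA-distributed: no contaminant responses, no
lapses, no parameter drift over trials, a single simulated participant per
dataset, and exactly two conditions. Selection-method behaviour measured
here therefore reflects the pure inversion problem — which method
recovers the generating member of the model family — not robustness to
model misspecification, which real data would add.

## Problem sizes in the tests

The test suite exercises reduced-scale versions of the study, sized so the
qualitative contrasts of interest are unambiguous at desk scale:

* parameter recovery: 10 replicates of the moderate/moderate "extreme"
  cell at 1000 trials per condition, complex-model fits with burn 500 /
  keep 500, checking central 99% interval coverage;
* qualitative replication: 20 replicates each of the moderate/moderate
  "extreme" cell and the null cell at 300 trials per condition, all nine
  methods, ordinary fits with the study's burn-in of 1000 and 250
  retained iterations per chain. Ladder lengths follow the precision the
  cell demands: between-variant log-ML differences are tens of nats under
  strong effects (400 retained per rung suffices) but only a few nats
  under the null, where the ladder keeps the full 1000 per rung because
  the trapezoidal integral's Monte-Carlo error must stay well below those
  differences;
* marginal-likelihood validation: conjugate normal–normal and
  beta–binomial targets with analytic answers, about 10^4 draws per
  estimator.

These sizes are the package's own desk-scale choices; the full design
(100 replicates x 25 cells at the paper-scale chain lengths) runs through
the same code path via `study_config()` defaults.

## Known limitations

* Hierarchical (multi-participant) structures are out of scope; every
  dataset is one participant.
* The Brier adjustment and the ROPE weight construction are documented
  reconstructions (see above).
* The TI estimator is the noisiest metric at equal draw counts; its
  disagreements with bridge sampling at reduced scale mirror the
  approximation error the original study itself reports, and shrink with
  `ti_keep`.
* `chi2_select` presumes the four-variant nested structure; it is not a
  generic model-comparison routine.
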