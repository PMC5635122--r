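---
title: "Two-level models of preference-influenced learning and choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level models of preference-influenced learning and choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefdiff)
```

## The problem

When people learn which of two snack items another person prefers — or, in a
non-social framing, which of two items is "correct" — from probabilistic
feedback, their own preferences intrude on the process. `prefdiff` implements
a family of computational models that locate that intrusion at two distinct
levels, fits them jointly to choices and response times, compares them by
out-of-sample predictive accuracy, and quantifies by simulation when the
intrusion helps rather than hurts.

The reference task has 20 item pairs, each shown 30 times (600 trials in
three blocks of 200), with feedback that indicates the correct item with
probability 0.8. Before the task, each participant states a willingness to
pay between £0 and £3 for every item; the bid difference for a pair,
`delta_v` (bid for the correct item minus bid for the incorrect one), is the
preference-congruence signal, and `rho` (the share of other participants who
bid more for the correct item, minus 0.5) indexes item popularity.

## The two-level model

**Between trials** an ideal Bayesian observer tracks the probability that the
target item `A` of a pair is correct. The belief before any feedback is a
logistic function of the egocentric signals:

$$P(A)_{n=1} = \frac{1}{1 + e^{-(\beta_{\Delta v}\,\Delta v + \beta_\rho\,\rho)}}$$

Each displayed feedback multiplies the prior odds by 4 (i.e. 0.8/0.2) toward
the indicated item; with `x` of `n` feedback presentations pointing at `A`,
the binomial coefficients cancel and the posterior log-odds are the prior
log-odds plus `(2x − n) log(0.8/0.2)`. The package computes all updates in
log-odds space, so runs of hundreds of one-sided feedbacks cannot underflow
([`bayes_update()`], [`batch_posterior()`]). Beliefs condition on the
*displayed* feedback, never on ground truth: the learner has no access to the
latter. Popularity enters only through the first-trial prior; it is not
re-applied during updating.

**Within a trial** the belief drives a two-boundary drift diffusion process.
The drift is the belief difference scaled by a weight,
$d_n = \omega\,(P(A|data_n) - P(B|data_n)) = \omega\,(2p - 1)$, the upper
boundary is the correct item, and the starting point can itself be biased
toward the preferred item, $z = 1/(1+e^{-\kappa\,\Delta v})$. Choice and
response time are jointly evaluated through the Wiener first-passage-time
density ([`wfpt_log_density()`]).

Five variants differ only in which influence parameters are free:

| variant            | free influence parameters      |
|--------------------|--------------------------------|
| `neutral`          | none                           |
| `influenced_prior` | `beta_dv`                      |
| `influenced_choice`| `kappa`                        |
| `dual`             | `beta_dv`, `kappa`             |
| `dual_popularity`  | `beta_dv`, `beta_rho`, `kappa` |

All variants share `omega`, `a` (boundary separation) and `s_nd`
(non-decision time). Zeroing the fixed parameters of the `dual` model
reproduces each nested variant's likelihood exactly, which the test-suite
asserts bit-for-bit.

### Numerical conventions that matter

* **Diffusion scale.** The intra-trial noise coefficient is fixed at 1;
  `omega` and `a` absorb the scale. Parameter values are only comparable
  across studies under the same convention — a convention using 0.1, for
  example, rescales `omega` and `a` by a factor of 10.
* **Density evaluation.** The first-passage density uses the small-time or
  large-time series expansion, selected per evaluation by the standard
  term-count bounds with truncation error below 1e-7.
* **Sampling.** [`simulate_trial()`] draws the boundary from the closed-form
  absorption probability and the decision time by inverting the conditional
  first-passage CDF on a 1024-point log grid (trapezoid integration,
  normalized to the analytic boundary mass). [`simulate_trial_em()`] is a
  deliberately independent Euler–Maruyama oracle with a Brownian-bridge
  crossing test between steps, which removes the O(√dt) boundary bias of
  naive discrete monitoring; it exists to cross-check the series density and
  the inverse-CDF sampler, not for production use.
* **Impossible observations.** Response times at or below `s_nd` have
  log-density `-Inf`; the fitter treats any parameter vector implying one as
  rejected rather than erroring.

## Hierarchical estimation

[`fit_hierarchical()`] samples the joint posterior in which each
participant's free parameters are drawn from group-level normal
distributions (mean `mu`, SD `sigma`; `omega` and `a` truncated positive),
while non-decision time is per-participant and non-hierarchical, uniform on
(0, minimum RT) — participant-level non-decision times are already tightly
constrained by minimum response times, so hierarchy would add
hyperparameters without adding information.

Hyperpriors are weakly informative and overridable
([`default_hyperpriors()`]): normal(0, 2) for the influence weights'
group means, normal(1.5, 1) and normal(2, 1) truncated positive for `omega`
and `a`, half-normal(1) for all group SDs. Under these hyperpriors,
prior-predictive response times for the default configuration fall in the
plausible sub-10-second range.

The sampler is Metropolis-within-Gibbs. Each participant's parameters are
updated by componentwise random-walk Metropolis with per-coordinate proposal
scales, Robbins–Monro adapted toward 44% acceptance during warmup only, so
the post-warmup chain is a fixed Markov kernel; the sweep runs in compiled
code. The group-level means and (log) SDs are updated by univariate slice
sampling of their full conditionals, which are one-dimensional, cheap and
unimodal — no tuning required. Participant blocks are conditionally
independent given the group level, which keeps mixing adequate under the
centered parameterization; a non-centered parameterization is a geometry
fix for gradient-based samplers and buys nothing here. Convergence is gated on
split-R̂ ≤ 1.01 and effective sample size for every latent; failures raise a
warning carrying the full diagnostic table and mark the fit
`convergence_ok = FALSE` — never a silent success. Random-walk samplers have
no divergence diagnostic; the reported divergence count is identically zero
and R̂/ESS carry the convergence evidence.

## Model comparison

[`elpd_loo()`] estimates each model's expected log pointwise predictive
density by Pareto-smoothed importance sampling over the per-trial
log-likelihood matrix (one point = one trial, the natural grain of the
likelihood), with the Zhang–Stephens generalized-Pareto tail fit and the
usual shape-parameter diagnostics. [`compare_models()`] takes the paired
pointwise difference, its standard error, and a two-tailed t-test. The
test-suite checks the estimator against exact closed-form leave-one-out
refits of a conjugate normal-mean model.

## The advantage simulations

[`advantage_grid()`] asks: over a population of learners each learning every
other participant's preferences, how much accuracy does a strategy
`(kappa, beta_dv)` gain over a neutral actor with identical `omega` and `a`?
Two exact identities keep the Monte-Carlo noise small without changing any
expectation:

1. feedback does not depend on the agent's responses, so all strategy cells
   and the neutral comparator share the same feedback realizations (common
   random numbers), and
2. accuracy is recorded as the analytic probability of a correct response
   given the belief state, rather than a sampled choice
   (Rao-Blackwellization over the within-trial noise).

Advantages are reported in percentage points on the 0–100 scale, with
Monte-Carlo standard errors over (dyad × feedback-realization) sessions.
The origin cell is identically zero by construction. The random-preference
control ([`permute_preferences()`]) shuffles each participant's bid vector
across items, preserving bid marginals while destroying the alignment
between own preferences and partners' choices. [`expected_value()`] and
[`efficiency_map()`] blend the predictive and random regimes linearly in
the probability that stimulus values fail to transfer.

Grid axes are absolute parameter values; [`grid_from_multiples()`] expresses
them as multiples of fitted group means (the reference analysis spanned 0–8
times the non-social group means). The neutral comparator defaults,
`omega = 1.53` and `a = 2.10`, are that analysis's fitted values.

## The synthetic population generator

[`generate_population()`] emulates the structure the models need from real
bid data. Each item gets a common-value factor, each participant an
idiosyncratic taste, combined as
$z_{pi} = \sqrt{r}\,c_i + \sqrt{1-r}\,e_{pi}$ so that any two participants'
latent values correlate `r`; bids are a monotone map of `z` onto
truncated-lognormal marginals on [0, 3] (real willingness-to-pay data are
skewed and bounded), which preserves every sign comparison. For a bivariate
normal pair the probability of ordering a pair the same way is
`1/2 + asin(r)/π`, so a target mean pairwise agreement `A` is achieved
exactly in distribution by `r = sin(π(A − 1/2))` — no tuning loop. The
default target is the reference population's 69.8%; realized agreement is
checked within ±3 points and the population resampled (bounded retries)
otherwise. The Δv–popularity correlation that drives the simulated
advantages *emerges* from this structure rather than being imposed; it is
checked, not calibrated.

What the generator does **not** emulate: the specific 40 snacks and their
popularity values, menu effects between bids and binary choices, session
fatigue, or any drift in preferences over the session. Tests passing on
synthetic data therefore validate the algorithms and their implementation,
not claims about any particular human dataset.

[`generate_behavior()`] turns a population into a full behavioral dataset:
one designated participant acts as the partner whose choices define the
correct items, and the remaining participants are simulated learners with
parameters drawn from group-level distributions
([`group_params()`]). The generating group means are `omega = 1.53`,
`a = 2.10` (the reference fitted values) and, chosen once as plausible
per-pound scales for this £0–3 bid range: `beta_dv = 0.55` (a £1 bid gap
moves the prior to 0.63), `kappa = 0.15` (a £2 gap moves the starting point
to 0.57), non-decision time uniform on 0.25–0.45 s.

## Worked example

```{r example, eval = FALSE}
pop <- generate_population(12, n_pairs = 20, agreement = 0.698, seed = 1)
ds <- generate_behavior(pop, model_spec("dual"), group_params(), seed = 2)

fit_dual <- fit_hierarchical(model_spec("dual"), ds, seed = 3)
fit_neut <- fit_hierarchical(model_spec("neutral"), ds, seed = 3)
group_summary(fit_dual)

cmp <- compare_models(elpd_loo(pointwise_loglik(fit_dual)),
                      elpd_loo(pointwise_loglik(fit_neut)))
cmp$elpd_diff / cmp$se_diff

adv <- advantage_grid(pop, sim_config(reps = 100, seed = 4))
print(adv)
```

## Problem sizes and defaults

The package's own studies run at desk scale by choice: parameter recovery
uses 20 learners × 600 trials with 2 chains × 3000 iterations; model
recovery uses 10 replicates of 8 learners × 150 trials; advantage grids
default to 17 × 17 cells but the shipped analyses use coarser grids with
around 40–100 feedback realizations per dyad and report Monte-Carlo standard
errors throughout. The full-scale analogue (61 learners × 60 partners ×
1000 repetitions per cell) is a straightforward `sim_config()` away for
anyone with the patience.

## Known limitations

* The Rescorla–Wagner learner is a minimal coupled delta rule mapped to the
  same drift; it stands in for a family of delta-rule learners and is
  flagged experimental — model comparison against it should not be read as
  a statement about any particular published variant.
* The model family assumes a constant noise level across the session;
  datasets in which late-session behavior tightens (fatigue, memory
  consolidation) will show the same early-trial misfit the reference
  analysis reports.
* No inter-trial variability parameters (drift or starting point): the
  model family deliberately has none, so strongly variable empirical RT
  distributions will be absorbed into `omega`/`a` instead.
* ELPD values depend on the dataset and are not comparable across datasets;
  only differences between models fitted to the same trials are meaningful.
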