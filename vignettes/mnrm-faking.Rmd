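---
title: "Modeling faking and response styles with the multidimensional nominal response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling faking and response styles with the multidimensional nominal response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fakenrm)
```

## The model

`fakenrm` fits a multidimensional nominal response model (MNRM) in which
the logit of category $k$ on item $i$ is

$$\eta_{ik}(\theta_n) \;=\; \sum_{d=1}^{D} \alpha_{id}\, s_{idk}\, \theta_{nd} + \gamma_{ik},
\qquad
P(Y_{ni}=k\mid\theta_n) = \frac{\exp \eta_{ik}}{\sum_{m=0}^{K} \exp \eta_{im}},$$

with multivariate-normal person parameters $\theta_n$.  The *scoring
weights* $s_{idk}$ are fixed design constants, one row per latent
dimension:

| dimension | weight row (7-point scale) | interpretation |
|---|---|---|
| own trait | $0,1,2,3,4,5,6$ | higher trait, higher category |
| other traits | $0,\dots,0$ | no loading |
| ERS | $1,0,0,0,0,0,1$ | preference for endpoints |
| MRS | $0,0,0,1,0,0,0$ | preference for the midpoint |
| faking | $s^{F}_{i0},\dots,s^{F}_{i6} \in [0,1]$ | item-specific desirability |

The faking row is what distinguishes the approach from response-style
modeling: the weights differ per item, so the same latent faking level
can push one item toward its top category and another toward its middle
categories, exactly as context-specific desirability judgments do.  In
applications the weights come from pilot-study desirability ratings,
rescaled linearly to $[0,1]$ using the *global* bounds of the pilot
rating instrument (`rescale_desirability()`).  Global rather than
per-item bounds preserve between-item differences in desirability level;
per-item scaling (available via `per_item = TRUE`) would equalize items
whose trajectories differ only in level, and is offered without
endorsement.

Identification uses the standard constraints: latent means 0, latent
variances 1 (so the estimated $\Sigma$ is a correlation matrix), and
$\gamma_{i0}=0$ for every item.  Because slopes and weights enter only
through their product, the model is invariant to adding a constant to a
weight row and to rescaling a weight row while dividing the slope
(`category_probabilities()` is tested for both invariances at $10^{-12}$).

## Estimation

`mnrm()` maximizes the marginal likelihood by the Metropolis–Hastings
Robbins–Monro (MH-RM) idea: each cycle (1) imputes $\theta_n$ for every
person by component-wise random-walk Metropolis under the current
parameters, (2) takes a damped Newton step on the complete-data
log-likelihood of the item parameters, per item, using a Robbins–Monro
average of the complete-data information, and (3) updates the latent
correlation matrix by stochastic approximation of the imputed
second-moment matrix, projected to unit variances with `cov2cor()` (the
same fixed point as optimizing an unconstrained Cholesky factor and
renormalizing, with fewer moving parts).

The schedule (all in `mnrm_control()`):

* **Burn-in** (default 100 cycles): constant gain 0.25; Metropolis
  proposal scales adapt per dimension toward an acceptance rate in
  [.23, .45] and are then frozen.  A constant gain of 1 (i.e. full
  Newton steps on single-imputation data) is unstable — parameters can
  random-walk far before the decreasing-gain stage begins — which is why
  the burn-in gain is deliberately below 1.
* **Identification by construction**: after each cycle's imputations the
  person-parameter columns are centred and unit-scaled (and the latent
  covariance update is projected to a correlation matrix).  The latent
  location/scale is only weakly restored by the prior at finite $N$, so
  without this projection the imputations and the intercepts/slopes
  co-drift along nearly flat likelihood directions.
* **Robbins–Monro stage**: gain $(c + t)^{-0.75}$ with $c$ chosen so the
  gain continues smoothly from the burn-in level.  The stage ends when a
  sliding window (3 cycles) of maximum absolute parameter changes falls
  below `tol = 1e-3`, or after `stage2_max = 300` cycles.
* **Polyak–Ruppert averaging**: the returned estimates are the average
  of the final half of the Robbins–Monro iterates.  Averaging
  decreasing-gain iterates removes most of the stochastic-approximation
  noise; on 50-item, $N=250$ testbeds the averaged 400-cycle estimates
  match raw 2000-cycle runs.  The convergence flag additionally compares
  the first and second half of the averaging window; slow drift along
  nearly flat (collinear) directions is reported via `fit$drift`.

Degenerate inputs: response categories never observed for an item have
their intercepts pinned at $-30$ (probability $\approx 0$) and are
excluded from estimation, with a warning; a dimension whose weight rows
are constant on every item is rejected as unidentified; missing
responses are rejected rather than skipped, to keep the likelihood
semantics unambiguous.

The marginal log-likelihood attached to a fit is, by default, a Laplace
approximation at each person's posterior mode (deterministic, scales to
$D = 8$; a product Gauss–Hermite rule is infeasible there).  Adaptive
Gauss–Hermite quadrature is available for $D \le 3$ and importance
sampling with a mode-centred normal proposal for any $D$; on $D=1$
testbeds Laplace and a 61-node adaptive rule agree within 0.5%, and all
model comparisons require both fits to carry the same method (and seed,
if stochastic).

`map_scores()` computes MAP person estimates by Newton ascent from
$\theta = 0$ with the item parameters fixed, so a model calibrated in
one sample (a high-stakes applicant pool) can score another (low-stakes
incumbents) on the same scale; non-converged persons are flagged, never
dropped.

## The synthetic-data generator

`sim_design()` + `generate_dataset()` emulate a faking-contaminated
personality battery: `n_traits = 5` scales of `items_per_trait = 10`
items on a 7-point scale, with

* slopes of trait, ERS, and MRS dimensions drawn from $U(0.25, 0.75)$;
* item-category thresholds $\tau_{ik} \sim N(\bar\tau_k, 0.7)$ with
  $\bar\tau = (-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)$, turned into intercepts
  by $\gamma_{ik} = -\sum_{m\le k}\tau_{im}$ (so zero threshold variance
  gives exactly $(0, 1.5, 2.4, 2.7, 2.4, 1.5, 0)$);
* faking weights per item following one of three deterministic
  templates — monotone increasing, nonmonotone increasing (a local dip),
  inverted-U — assigned ~40/30/30 within each trait block, with optional
  uniform jitter (default 0);
* latent correlations: a fixed trait block with pairwise values in
  .10–.30, ERS and MRS orthogonal to everything, and faking–trait
  correlations $(.00, .10, -.10, .30, -.30)$; when faking is absent its
  slopes are 0 and its correlations are 0, making the dimension inert
  (dropping it entirely leaves the simulated responses bit-identical,
  which is tested).

**Faking impact scale.**  With faking weights on $[0,1]$ and trait
weights on $0..6$, identical slope distributions would give faking about
one sixth of a trait's impact on the logits.  The generator's default
(`faking_impact = "trait_metric"`) therefore draws faking slopes from
$K \cdot U(0.25, 0.75)$ — by the model's exact scale-absorption
invariance this is the same data-generating process as placing the
faking weights on the traits' $0..K$ metric, and it makes the faking
dimension's average impact equivalent to a substantive trait's.  Under
this scale the no-faking model's trait intercorrelations are strongly
positively biased on faking-present data and all three selection
criteria detect the faking dimension essentially always at $N = 250$,
whereas under `faking_impact = "unit"` the faking signal is too weak for
the penalized criteria at that sample size.  Empirically, desirability
weights on $[0,1]$ go together with faking slopes substantially larger
than trait slopes, which is the same phenomenon in reverse.

The trait intercorrelation matrix and the within-block shape census are
package choices (the exact values used in comparable published
simulations are not printed anywhere we can consult); both are plainly
visible in `sim_design()` and overridable, and results that depend on
them should be labeled as conditional on those settings.

What the generator does *not* emulate: acquiescence, person-specific
desirability perceptions (every test-taker shares the item's weight
vector), missing data, local item dependence, and non-normal latent
distributions.  Passing recovery tests on these data therefore shows
the estimator recovers *this* process, not that real rating data follow
it.

## The Monte Carlo study

`run_study()` chains generation, fitting of the nested roster (traits →
+ERS → +MRS → +faking), model selection, and recovery metrics:

* selection: AIC/BIC minimization over the roster; the LR criterion is
  the adjacent-pair test of the two largest models at $\alpha = .05$
  (`lr_chain` walks the whole chain instead);
* recovery: bias and RMSE of trait–trait and faking–trait latent
  correlations and of item slopes, pooled across replications; person
  recovery as the Fisher-$z$ mean correlation between MAP and generating
  person parameters, aggregated across traits and reported separately
  for faking;
* failures are recorded and excluded, never silently dropped; the whole
  study is reproducible from one master seed that spawns per
  (condition, replication, model) sub-streams.

Desk-scale defaults: the study runner and the tests use 20–100
replications with 18–50 items and the lighter MH-RM schedule
(burn-in 50, 150 Robbins–Monro cycles, 2–3 Metropolis sweeps); these
sizes are stated here as the package's standard study scale, and the
Monte Carlo standard errors reported by `run_study()` make the scaled
runs interpretable.  `scripts/acceptance.R` runs 20 replications of the
5 traits × 10 items, $N = 250$ faking-present condition.

## Numerical choices

* Logits are max-shifted before exponentiation everywhere.
* Newton steps use a ridge of $10^{-6}$ and an elementwise cap of 0.25
  per cycle; near-collinear weight rows (e.g. a monotone faking item,
  whose faking row is proportional to its trait row) make some
  directions genuinely flat, which slows their convergence without
  affecting the likelihood.
* The latent correlation update projects to unit diagonal each cycle and
  floors eigenvalues at $10^{-6}$ if a draw makes the matrix nearly
  singular.
* Ties in AIC/BIC selection resolve to the smaller (earlier) model.
* All randomness — generation, Metropolis sweeps, importance sampling —
  flows through R's RNG, so `set.seed()`/the `seed` arguments make every
  result bit-reproducible; fits with the same seed are identical to
  $10^{-12}$.

## Known limitations

* **LR calibration at extreme parameter-to-sample ratios.**  With free
  slopes, 7-point items and $D = 7$–$8$, the models carry roughly 450–500
  free parameters at $N = 250$; in that regime the likelihood-ratio
  statistic for adding the faking dimension is anti-conservative under
  the null (its mean sits near $1.5\times$ its degrees of freedom in our
  experiments, and the inflation is not an artifact of the
  likelihood approximation — Laplace and importance sampling agree, and
  a quadrature-exact two-dimensional testbed at the same $N$ is well
  calibrated).  BIC (and to a lesser degree AIC) remains reliable and is
  the selection criterion we recommend at these sizes; the power of all
  three criteria on faking-present data is unaffected.
* Standard errors of item parameters and latent correlations are not
  produced; the convergence trace and seed-to-seed replication are the
  current substitutes, and the fit object is structured so a bootstrap
  can be layered on top.
* Laplace log-likelihoods are approximations; comparisons must use the
  same method in both fits (enforced by `lr_test()`), and quadrature is
  available only up to $D = 3$.
* MAP scores shrink toward 0 for short tests; their correlation with
  generating parameters in the studies (~.7–.8 for traits with 10 items
  per trait) is the realistic ceiling for this scale length.
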