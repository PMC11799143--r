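---
title: "Thinking benefits, thinking costs, and the optimal short wait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thinking benefits, thinking costs, and the optimal short wait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsat)
```

## The question

In simple binary perceptual judgments, accuracy rises with thinking time but
the rise flattens, while the cognitive costs of thinking — conflict between
the alternatives, irritation with enforced delays — keep accumulating. If an
agent's objective is accuracy *minus* cost (the value-of-computation view of
resource rationality), there is an optimal, short thinking time; the
classical speed–accuracy trade-off (SAT), which ignores costs, instead
rewards thinking as long as possible. `rrsat` implements both sides of that
argument: a process model that locates the optimum, and the behavioral
measurements that test whether people show it.

## The adjustment model

The task is the *grid task*: judge whether black tiles exceed 50% of a
50×50 black-and-white grid whose true black proportion is `c_prop` (0.55 is
treated as difficult, 0.65 as easy). Estimation is modeled as
anchoring-and-adjustment implemented as a Markov chain:

* the initial estimate is drawn from the prior, a normal centred on the 0.5
  decision criterion with SD `belief_sd` (default 0.1), truncated to
  [0, 1] — the observer starts undecided;
* at each of `n_steps` (default 150) steps a small change
  `delta ~ N(0, proposal_sd)` (default SD 0.05) is proposed, and the
  adjusted value is accepted by the Metropolis–Hastings rule under the
  belief distribution, a normal centred on `c_prop` with SD `belief_sd`
  truncated to [0, 1]: always when at least as probable as the current
  value, otherwise with probability equal to the density ratio.

All distributions on the proportion scale are truncated to [0, 1]. Two
numerical consequences follow. First, inside the interval the truncation
constants cancel from the acceptance ratio, which therefore reduces to a
ratio of Gaussian densities; outside the interval the density is zero, so
out-of-range proposals are rejected with certainty and chains never leave
[0, 1]. Second, the *proposal* increment itself is not truncated — a
zero-mean increment truncated to [0, 1] could never move downward — so
truncation is enforced entirely through the target density. An alternative
bimodal prior (equal-weight mixture of truncated normals at 0.4 and 0.6, SD
0.05, for observers already leaning one way) is available via
`sim_config(prior = "bimodal")`; mixture weights are equal by symmetry since
neither component is privileged.

A judgment after `t` adjustments is correct when the estimate exceeds 0.5
(strictly: equality counts as incorrect, a measure-zero tie rule that keeps
the statistic deterministic). Per simulated individual, `n_iterations`
(default 1,000) chains give

* `think_benefit_raw[t]` — the fraction of chains correct at step t;
* `think_benefit[t]` — the same rescaled so its maximum over all steps,
  including step 0, is exactly 1;
* `think_cost[t] = max_cost * t / n_steps` — the linear cost schedule;
* `total_benefit = think_benefit - think_cost`.

`max_cost = 0` is the SAT regime (total benefit ≡ thinking benefit);
`max_cost = 0.5` is the resource-rational regime. The **peak time** is the
earliest step `t ∈ {1, …, n_steps}` maximizing total benefit. Step 0 is
excluded — "stop before adjusting at all" is not a thinking-time
recommendation — and ties break to the earliest step, again for
determinism. Because the benefit curve is a Monte-Carlo estimate, the SAT
argmax wanders over the late plateau where binomial noise dominates, which
is precisely why SAT peak times spread widely while costed peak times
concentrate early: the linear cost tilts the plateau so only the early
steep region can win.

`simulate_population()` runs `n_individuals` (default 500) independent
individuals. Each individual gets their own RNG stream derived from the
config seed by a fixed-stride counter, so results are bit-reproducible and
enlarging the population leaves earlier individuals' draws unchanged.
Passing a vector `max_cost` evaluates several cost regimes on *identical*
chains, the like-for-like comparison behind the earlier-and-narrower claim:

```{r population, fig.width = 6, fig.height = 4}
cfg <- sim_config(c_prop = 0.55, n_individuals = 60, n_iterations = 200,
                  seed = 42)
peaks <- simulate_population(cfg, max_cost = c(0, 0.5))
peak_summary(peaks)
autoplot(peaks)
```

At full scale (500 individuals × 1,000 chains × 150 steps, the setting of
`scripts/acceptance.R`) the mean peaks fall near step 95 (difficult) and
100 (easy) under SAT versus near 23 and 28 under the 0.5 cost ceiling. The
examples here and the test suite use scaled-down populations (60–100
individuals, 200 chains) that already show the same separation; the
stationary-distribution check uses 10⁴ chains, for which the Monte-Carlo
standard error of a tail probability is about 0.005. A useful closed-form
anchor: as `t` grows, `P(v_t > 0.5)` converges to the truncated-normal tail
probability, 0.6915 for `c_prop = 0.55` and 0.9332 for 0.65, which the test
suite verifies against the empirical terminal accuracy.

## The behavioral measurements

The experimental design the pipeline serves: three between-participant
groups differing only in an enforced waiting time before the response
buttons appear (0 s, 1 s, 2.5 s), 9 blocks × 40 trials per participant,
four stimulus proportions (0.35 and 0.65 easy, 0.45 and 0.55 difficult)
presented equally often, cursor position recorded from stimulus onset to
button click, and one 0–100 irritation rating per block in the waiting
groups.

Measurement definitions, and the numerical choices where a rule had to be
fixed:

* **Outlier rule.** Trials with response time strictly over 6 s are
  excluded; exactly-6-s trials are kept ("over" read literally).
  `filter_trials()` records the excluded fraction.
* **Time normalization.** Each trajectory is resampled to 101 points at
  equal fractions of the trial duration by linear interpolation of x and y
  separately (`time_normalize()`). Endpoints are pinned to the raw values
  to avoid floating-point drift; duplicate time stamps are averaged first.
  The operation is idempotent on already-normalized input. Trajectories are
  defined from stimulus onset to click.
* **AUC.** `traj_auc()` projects the path onto the straight line from its
  first to its last point and integrates the perpendicular deviation along
  the line by the trapezoid rule — equivalently, the signed polygon area
  between path and direct path. Deviation toward the unchosen button is
  positive and overshoot past the direct path is negative, so opposing
  excursions cancel; the caller orients the sign by passing the unchosen
  button's location (`auc_by_trial()` uses the mirror image of the endpoint
  across the start, which is that button in a symmetric layout). Units are
  squared pixels of the recording space. The area is invariant under rigid
  motions of the coordinates and scales quadratically with the display,
  both tested. AUC is computed on the 101-point normalized trajectory;
  since normalization only resamples the path in time, the polygon — and
  hence the area — is unchanged up to interpolation error.
* **Response-time categories.** Four bins, right-open with a closed top:
  [0, 1.0), [1.0, 2.5), [2.5, 4.0), [4.0, 6.0]. The boundary rule is a
  package choice (only labels are conventional); binning is deterministic.
* **Cumulative RT distributions.** 0.1-s bins over (0, 6]; `rt_cdf()`
  reports the cumulative fraction at each bin's upper edge per group ×
  difficulty × correctness stratum, non-decreasing and ending at 1; empty
  strata are omitted rather than padded.
* **Irritation.** A participant's score is the maximum of their 9 block
  ratings; participants rating 0 in every block are flagged as excluded
  (treated as non-responses).
* **Group statistics.** Per-participant accuracy — not pooled trials — is
  the unit for group comparisons. One-way ANOVA F and its p-value are
  delegated to `stats::aov()`; η² = SS_between / SS_total, Holm's step-down
  adjustment, and Cliff's δ are computed in-package (Holm is cross-checked
  against `stats::p.adjust()` in the tests, and the rank-sum W and p come
  from `stats::wilcox.test()`). Pairwise comparisons after the ANOVA use
  pooled-SD t tests on the residual degrees of freedom.

## The synthetic-data generator

`generate_dataset()` emulates the design above so every pipeline stage has
a known ground truth. What is injected, and why these defaults:

* **Accuracy.** Correctness is Bernoulli at group × difficulty targets
  (difficult 0.67 / 0.75 / 0.78; easy 0.91 / 0.99 / 0.99 for 0 s / 1 s /
  2.5 s) — the group means reported for the experiment the generator
  emulates, so recovering them is a real calibration check.
* **Response times.** Waiting time plus a log-normal decision time
  (meanlog `log(0.9)`, sdlog 0.55 — a median just under a second with
  positive skew, the conventional shape for simple-judgment RTs; no
  distributional form was reported, only summaries). The additive offset
  reproduces the response lockout: no 1 s-group response before 1 s, none
  in the 2.5 s group before 2.5 s. A fraction `outlier_rate = 0.021` of
  trials is inflated past 6 s to exercise the outlier rule at the reported
  rate.
* **Trajectories.** A straight centre-to-button path plus a half-sine
  perpendicular excursion toward the unchosen button, scaled so the
  enclosed area equals a target conflict of `auc_slope` (30 px²/s) times
  the response time, plus Gaussian noise — chosen because the tests need an
  analytically known area oracle, not a realistic movement model; the
  linear growth of conflict with time is the qualitative feature under
  test. Sampling at 60 Hz with small positional jitter; button geometry
  (±300, −200 px from a centred start) is fixed in the config since no
  screen geometry is prescribed by the design.
* **Irritation.** A per-participant latent score, truncated-normal with
  means 29 (1 s) and 42 (2.5 s) and SD 20 — locations matching the reported
  group means — realized as 9 block ratings whose maximum equals the
  latent; 5% of raters give all zeros to exercise the exclusion rule. Only
  the waiting groups rate, as in the design.

What the generator does **not** emulate: sequential dependencies between
trials, participant-level heterogeneity in accuracy or speed beyond
sampling noise, realistic cursor kinematics, any correlation between
conflict and correctness, or the real dataset's full distributions (it is
calibrated to printed summary statistics only). Passing the
parameter-recovery tests therefore shows that the measurement pipeline
faithfully extracts what was injected at realistic sizes — it does not
validate the psychological claims on real data.

```{r recovery, fig.width = 6, fig.height = 3.5}
ds <- generate_dataset(synth_config(n_per_group = 8, seed = 1))
res <- analyze_dataset(ds$trials, ds$trajectories, ds$ratings)
plot_auc_by_category(res$auc_by_category)
glance(res$stats$accuracy_difficult)
```

## Degenerate inputs and error policy

A benefit curve in which no chain ever crosses the criterion cannot be
rescaled and raises an error rather than returning NaN. Trajectories with
fewer than two samples, zero duration, or coincident endpoints are rejected
(the direct path is undefined). Response times over 6 s reaching
`rt_category()` or `rt_cdf()` raise a filter-first error instead of being
silently binned. Ratings tables must carry exactly the declared number of
blocks per participant. Empty accuracy cells are either omitted (default)
or, with `complete = TRUE`, reported as `n = 0` with `NA` accuracy and a
warning — never silently propagated; `analyze_dataset()` reports observed
cells only, because the waiting-time lockout makes early response-time
categories structurally empty in the waiting groups.

## Limitations

The simulator explores one cost family (linear in time) and one stopping
statistic (the total-benefit argmax); opportunity-cost formulations and
fitted sequential-sampling models are out of scope, as is fitting the chain
model to human response times. The AUC sign convention and pixel units are
package choices that real datasets may define differently; analyses of real
recordings should confirm the button geometry before interpreting signs.
Peak-time means are Monte-Carlo estimates: at 500 individuals their
between-seed standard error is roughly 0.7 steps in the costed regime and
1.5 steps under SAT, so small seed-to-seed differences are expected.
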