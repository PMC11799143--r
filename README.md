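# rrsat

Resource-rational speed–accuracy trade-offs in simple perceptual judgment.

People doing simple binary judgments — "are more than 50% of these tiles
black?" — get more accurate the longer they think, but the gain flattens
while the cognitive cost of thinking (conflict, irritation) keeps growing.
`rrsat` provides the tools to study that trade-off end to end:

* a **simulator** of the anchoring-and-adjustment account of the grid task:
  estimation is a Metropolis–Hastings chain of small proposed changes to the
  current estimate, accepted against a truncated-normal belief about the
  true black proportion;
* a **measurement pipeline** for the corresponding waiting-time experiment:
  outlier filtering, time-normalized mouse-trajectory area under the curve
  (AUC) as a conflict index, accuracy by response-time category, cumulative
  response-time distributions, irritation scoring, and group statistics
  (one-way ANOVA with η², Holm-adjusted pairwise comparisons, Mann–Whitney
  rank-sum with Cliff's δ);
* a **synthetic-data generator** that emulates the three-group (0 s / 1 s /
  2.5 s waiting time) experiment so the whole pipeline is testable without
  participant data.

## The model

An observer estimates the black-tile proportion of a 50×50 grid. The first
estimate v₀ is anchored at the decision criterion: v₀ ~ N(0.5, b) truncated
to [0, 1], with belief strength b = 0.1. At each of T = 150 adjustment
steps, a change δ ~ N(0, 0.05) is proposed and the new value v + δ is
accepted by the Metropolis–Hastings rule under the truncated-normal belief
N(C_prop, b), where C_prop is the true proportion (0.55 difficult, 0.65
easy): certainly if it is at least as probable as v, otherwise with
probability equal to the density ratio. Across 1,000 chains per simulated
individual,

* ThinkBenefit_t = P(v_t > 0.5), rescaled so its maximum is 1;
* ThinkCost_t = c·t/T, a linear cost schedule with ceiling c (c = 0 is the
  classical speed–accuracy trade-off, SAT; c = 0.5 is the resource-rational
  regime);
* TotalBenefit_t = ThinkBenefit_t − ThinkCost_t.

The statistic of interest is each individual's **peak time** — the earliest
step maximizing TotalBenefit — and its distribution over a population of
individuals. With thinking costs, peaks arrive early and in a narrow range;
without them they drift late and spread widely: an appropriately *short*
thinking time maximizes total benefit.

## Worked example

Simulate 100 individuals (200 chains each) on the difficult stimulus and
compare the two cost regimes on identical chains:

```r
library(rrsat)
cfg <- sim_config(c_prop = 0.55, n_individuals = 100, n_iterations = 200, seed = 42)
peaks <- simulate_population(cfg, max_cost = c(0, 0.5))
peak_summary(peaks)
#> # A tibble: 2 × 7
#>   c_prop prior    max_cost     n  mean   min   max
#>    <dbl> <chr>       <dbl> <int> <dbl> <int> <int>
#> 1   0.55 unimodal      0     100  89.4    21   150
#> 2   0.55 unimodal      0.5   100  22.6     4    48
```

With zero cost (SAT) the mean peak sits late (step 89 of 150) and ranges
over the whole scale; with the resource-rational cost the peak arrives
around step 23 in a much narrower band — thinking longer stops paying.
`autoplot(peaks)` shows the two distributions.

The behavioral side, on synthetic data (10 participants per group):

```r
ds  <- generate_dataset(synth_config(n_per_group = 10, seed = 1))
res <- analyze_dataset(ds$trials, ds$trajectories, ds$ratings)
res
#> Grid-task analysis: 10539 trials kept (2.4% excluded as > 6 s)
#> # A tibble: 3 × 3
#>   group difficult  easy
#>   <chr>     <dbl> <dbl>
#> 1 0s        0.673 0.911
#> 2 1s        0.751 0.989
#> 3 2.5s      0.771 0.990
#>
#> [accuracy_difficult] One-way ANOVA: F(2, 27) = 19.074, p = 6.85e-06, eta^2 = 0.586
#> ...
#> [irritation] Mann-Whitney rank-sum (1s vs 2.5s): W = 41.0, p = 0.5202, Cliff's delta = -0.180
```

Waiting improves accuracy (0.67 → 0.75/0.77 on difficult stimuli, matching
the generator's targets), trajectory conflict grows with response time
(`plot_auc_by_category(res$auc_by_category)`), and at this small n the
irritation contrast between the 1 s and 2.5 s groups is not yet resolved
(the full-size design, 40 per group, recovers it; negative δ here means the
first-level group, 1 s, rated lower).

A command-line wrapper over the same functions ships at
`inst/cli/rrsat.R`, with subcommands `simulate`, `synth` and `analyze`; see
`?run_pipeline`.

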