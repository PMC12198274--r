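# modnet

Moderated symptom-network models for ordinal rating-scale data.

## The problem

Symptom networks treat a disorder as a system of interacting symptoms: nodes
are rating-scale items and edges are conditional (partial) associations
between pairs of symptoms, controlling for all other symptoms. A recurring
question is whether these interrelations differ between groups — for
example, between stimulant-treated and untreated individuals with ADHD and
non-ADHD controls. `modnet` implements the moderated network approach to
that question for 18 DSM-IV ADHD items rated 0–3 on a parent rating scale:

- **Estimation.** A mixed graphical model is estimated by nodewise
  regression: each standardized item is regressed on all other items, on
  dummies for the non-reference moderator groups, and on item × group
  interaction terms, with an L1 (LASSO) penalty chosen per node by the
  extended Bayesian information criterion,
  `EBIC = n log(RSS/n) + k log n + 2γ k log P` with `γ = 0.5`. Edges are
  aggregated over the two regressions per node pair with the OR-rule (signed
  mean of the two absolute coefficients). The network *conditioned* on group
  g is the reference network plus g's selected interaction increments, so
  groups without selected interactions share the reference network exactly.
- **Stability.** Moderation effects are classified by a stratified
  (within-group, size-preserving) bootstrap of the full estimation
  procedure: present in ≥ 80% of resamples = good stability, 50–80% =
  moderate, below = insufficient.
- **Local metrics.** Node strength `s_i = Σ_j |w_ij|` and the Zhang–Horvath
  weighted local clustering coefficient
  `C_i = Σ_{j≠k} w̃_ij w̃_jk w̃_ik / Σ_{j≠k} w̃_ij w̃_ik` (weights scaled
  by the maximum), compared between groups by Pearson correlation over
  nodes.
- **Cohort statistics.** Continuity-corrected chi-squared for 2×2 tables,
  pooled/Welch t-tests, and Mann–Whitney W, as used in case-control
  descriptive tables.
- **Treatment trajectories.** Lifetime monthly dose series from prescription
  records (day-weighted, dexamphetamine converted to methylphenidate
  equivalents), six features (onset age, stop age, total dose from the raw
  series; duration, maximum dose, dose SD from a GCV-penalized GAM smooth),
  and Louvain community detection on thresholded feature correlations with
  modularity Q and a minimum community size of 10.
- **Synthetic data.** A latent Gaussian copula generator with per-group
  partial-correlation networks, planted moderation deltas, MCAR
  missingness, and two prescription-history archetypes (early-and-intense
  vs late-and-moderate), providing ground truth for every stage.

Because the motivating cohort data are under controlled access, the package
validates itself by parameter recovery on this generator rather than by
re-estimating the original networks.

## Worked example

```r
library(modnet)

# ground truth: a sparse positive 18-item network, one planted moderation
truth <- symptom_truth(moderated_edges = data.frame(
  item_i = "fidget", item_j = "run", group = "ADHD-stim", delta = 0.3))

d <- simulate_symptoms(truth, n_per_group = 500, seed = 1) |>
  inject_missingness(rate = 0.02, seed = 1)

completed <- filter_missingness(d)$data |>
  impute_items(m = 5, seed = 1)

fit <- fit_mgm(completed)
fit
#> Moderated mixed graphical model
#>   nodes: 18  groups: NAC, ADHD-nostim, ADHD-stim
#>   reference: NAC  rule: OR  gamma: 0.5
#>   edges (base): 21  moderation effects: 12  imputations averaged: 5
```

The planted fidget–run moderation is recovered with the largest increment
(0.084 on the standardized-coefficient scale; the others are near-zero
selection noise that the bootstrap sorts out):

```r
dplyr::arrange(fit$moderation, dplyr::desc(increment)) |> head(3)
#>   item_i   item_j group     increment
#> 1 fidget   run    ADHD-stim    0.0838
#> 2 closeatt org    ADHD-stim    0.0342
#> 3 fidget   seat   ADHD-stim    0.0267

rep <- moderation_stability(completed$completed[[1]], B = 100, seed = 1)
head(tibble::as_tibble(rep), 3)
#>   item_i item_j group     proportion class    in_reference
#> 1 fidget run    ADHD-stim       0.97 good     TRUE
#> 2 fidget seat   ADHD-stim       0.83 good     TRUE
#> 3 run    motor  ADHD-stim       0.75 moderate TRUE
```

The planted effect is the only strong one (presence 0.97, class good).
Local metrics show the moderated group's denser network while the metric
profiles stay highly correlated across groups:

```r
met <- local_metrics(fit)
summarize_metrics(met)
#>   group       strength_mean strength_sd clustering_mean clustering_sd
#> 1 NAC                0.0919      0.0731          0.0704         0.236
#> 2 ADHD-nostim        0.0973      0.0758          0.0706         0.236
#> 3 ADHD-stim          0.111       0.0985          0.168          0.282

compare_metrics(met, "NAC", "ADHD-stim")
#>   metric     group_a group_b   correlation
#> 1 strength   NAC     ADHD-stim       0.966
#> 2 clustering NAC     ADHD-stim       0.725
```

`autoplot(fit)`, `autoplot(met)` and `autoplot(rep)` draw the group
networks (shared layout and edge scale), the standardized metrics, and the
stability profile. `run_pipeline(config)` chains every stage from a CSV or
a simulation config and writes all tables, edge lists and a run log; a thin
command-line wrapper lives in `inst/cli/modnet`.

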