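---
title: "Moderated symptom networks: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated symptom networks: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modnet)
```

## The model

`modnet` estimates a pairwise Markov random field over 18 ordinal symptom
items together with group-specific *moderation* of individual edges. The
moderator is a categorical group variable (here: non-ADHD controls,
stimulant-naive ADHD, stimulant-exposed ADHD). Estimation is nodewise: for
each item $s$,

$$ z_s = \sum_{j \ne s} \beta_{sj} z_j
       + \sum_{g \ne \mathrm{ref}} \alpha_{sg} d_g
       + \sum_{g \ne \mathrm{ref}} \sum_{j \ne s} \delta_{sjg}\, z_j d_g
       + \varepsilon_s, $$

where $z$ are standardized item scores and $d_g$ are group dummies with the
largest group as reference. Coefficients are estimated by LASSO
(coordinate descent on the Gram form of the penalized least-squares
problem, implemented in C++), with the penalty selected per node by the
extended Bayesian information criterion
$\mathrm{EBIC} = n\log(\mathrm{RSS}/n) + k\log n + 2\gamma k \log P$ at
$\gamma = 0.5$. Pairwise parameters are aggregated across the two
regressions of each node pair: under the OR-rule an edge (or moderation
term) is retained when either coefficient is selected, with weight equal to
the signed mean of the two absolute coefficients; the AND-rule is available
for sensitivity analysis. The network conditioned on group $g$ is the
reference network plus $g$'s selected increments, which enforces the key
structural property that groups without selected interactions share the
reference network *exactly*.

### Assumptions and their consequences

The 0–3 Likert items are treated as continuous Gaussian nodes after
standardization. This is the practical regime of mixed-graphical-model
estimation for short ordinal scales: the resulting group networks are
real-valued weighted graphs, at the cost of attenuating associations
relative to the latent scale (a planted latent partial correlation of 0.25
appears as a standardized coefficient around 0.1). All recovery guarantees
quoted below are therefore statements about *selection* (which edges and
moderation terms are nonzero), not about unattenuated effect sizes.

The moderator coding uses reference-group dummies rather than an
overparameterized coding. The motivating analysis reports that two of its
three group networks coincide, which is precisely the behavior this coding
produces when no interactions are selected for a group; the cross-regression
aggregation (mean of absolute values, OR-rule) mirrors common nodewise MGM
practice. Sign conflicts between the two regressions of a pair are rare,
resolved by averaging the signed values, and flagged in
`fit$sign_conflicts`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC model-space penalty; 0 gives ordinary BIC, larger is sparser |
| `nlambda`, `lambda_min_ratio` | 50, 1e-4 | log-spaced penalty path from the per-node $\lambda_{\max}$ |
| `rule` | OR | edge retention rule across the two nodewise regressions |
| `reference_group` | first level | moderator reference (by convention the largest group) |
| `covariates` | none | age/sex/site entered as main-effect predictors |
| bootstrap `B` | 500 | resamples for stability classification |
| `min_community_size` | 10 | Louvain community retention threshold |
| `meq_factor` | 2 | dexamphetamine → methylphenidate dose equivalence (mg/day) |
| imputation `m`, `iterations`, `donors` | 5, 10, 5 | chained-equation PMM settings |

Interaction columns are standardized *after* forming the product, so the
penalty acts on comparable scales across main effects and interactions;
this is configurable via `standardize`.

Covariate nodes (age, sex, site) enter each item's design as main effects
only and are not interacted with the moderator. They are reported in a
separate coefficient table rather than widening the 18×18 group matrices,
because all local network metrics are defined on the symptom nodes.

## Preprocessing

Participants missing half or more of the items are excluded (threshold
configurable); remaining missing scores are completed by chained-equations
multiple imputation with predictive mean matching (5 donors), which
guarantees imputations in the observed category support {0,1,2,3}. PMM was
chosen over ordinal-model imputation for exactly that in-support guarantee.
With `m > 1` completed datasets the network is fitted on each and all
selected parameters are averaged element-wise — a simple, symmetric rule;
`use_first_only = TRUE` gives the single-dataset alternative. Averaging can
union small selection noise across imputations into many near-zero
moderation entries; the bootstrap stage is the instrument that separates
these from real effects (see the worked example in the README, where the
planted effect reaches presence 0.97 and the noise stays below 0.5).

## Bootstrap stability

"Block" resampling is interpreted as stratified-by-group: participants are
resampled with replacement within each moderator group, preserving the
group sizes the moderated model conditions on (an unstratified option
exists). Within each replicate the penalty is re-selected by EBIC — a
full-procedure bootstrap, not a refit at frozen tuning. The bootstrap runs
on one completed dataset (the first imputation): the resampling targets the
network estimation, and re-imputing inside every replicate would conflate
imputation and selection variability. Presence proportions are classed
good at ≥ 0.80 (boundary inclusive), moderate in [0.50, 0.80), else
insufficient.

## Local metrics

Node strength sums absolute incident weights. Local clustering defaults to
the Zhang–Horvath form on max-scaled absolute weights, with Onnela and
Barrat variants selectable; all three reduce to the unweighted clustering
coefficient on binary graphs (property-tested against a triangle-counting
oracle) and are invariant to rescaling all weights. Absolute weights make
the metrics well-defined under negative edges while being observationally
neutral for all-positive networks. Standardized variants z-score each
metric across the 18 nodes within one network, matching how per-group
metric profiles are usually displayed and compared.

## Trajectories

Monthly dose values are day-weighted means of overlapping prescription
records; total dose integrates monthly dose × days per month. The smoothed
features come from a penalized cubic regression spline (GCV smoothing).
Because a spline never returns exactly to zero, treatment duration is the
time the smoothed curve exceeds 1 mg/day. Louvain runs at resolution 1 on
the graph of nonnegative-thresholded Pearson correlations between z-scored
6-feature vectors; the similarity metric and scaling are declared
conventions (the upstream analyses do not state theirs), so the modularity
value and subgroup sizes of the original cohort are not reproduction
targets. Communities below 10 members are flagged excluded, mirroring the
exclusion of subgroups too small to compare.

## The synthetic generator

The generator emulates exactly what the estimator assumes: per-group latent
Gaussian vectors whose precision is implied by a partial-correlation
network (moderation = an additive delta on one group's matrix), discretized
at cutpoints {0.5, 1.0, 1.5} of the standard normal — a right-skewed score
distribution typical of community samples; the source cohort's item
distributions are not published, so the cutpoints are a declared default.
Missingness is MCAR only. Covariates are drawn with group-specific
marginals resembling the cohort (e.g. fewer females in the
stimulant-treated group) but independent of the items. The generator does
**not** emulate informant effects, comorbidity structure, longitudinal
waves, MAR/MNAR missingness, or covariate–symptom dependence — so passing
recovery tests demonstrate correctness of the estimation machinery under
the model's own assumptions, not robustness to those real-data features.

Prescription archetypes use disjoint uniform ranges (early-and-intense:
onset 6–9 y, 30–60 mg/day, 4–8 y; late-and-moderate: onset 12–16 y,
10–25 mg/day, 1–4 y), each history split into two records with a titration
step so the dose-SD feature is informative.

## Numerical choices and degenerate inputs

Coordinate descent converges when the largest coefficient change in a sweep
falls below 1e-8 (path solutions match closed-form oracles to 1e-6);
saturated path points (RSS ≈ 0) are excluded from EBIC scoring; EBIC ties
break toward the sparser model. Constant design columns are dropped and
recorded; constant items, groups below `min_group_n = 10`, items missing
for every participant, zero table margins, and zero-variance metric vectors
raise named errors. Element-wise averaging across imputations zeroes
magnitudes below 1e-10 (sign-cancelled machine noise). Clustering of nodes
with fewer than two neighbors is 0 by convention.

## Problem sizes used in validation

The test suite validates recovery at the generator's study-like conditions:
edge sensitivity and moderation detection on 20 replicates of three groups
× 500 participants (planted edges at partial correlation ≥ 0.25, planted
moderation delta 0.25); the bootstrap stability property with B = 200 on
one dataset of three groups × 1000 (delta 0.3); trajectory-archetype
recovery on 100 + 100 histories. These sizes give stable pass/fail behavior
for the stochastic properties while keeping the default suite in the
minutes range.

## Known limitations

- Ordinal items are modeled as Gaussian; no categorical/ordinal node
  likelihoods, and recovered weights are attenuated relative to the latent
  scale.
- Moderation is pairwise-by-group only; no three-way (edge × two
  moderators) terms.
- Imputation assumes MCAR/ignorable missingness and linear item
  regressions.
- Louvain results depend on the declared similarity construction; Q is
  comparable only within that construction.
- The pipeline's cohort table compares groups pairwise with unadjusted
  p-values, as in descriptive cohort tables.
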