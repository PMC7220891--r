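---
title: "Methods: a two-stage space-time model for childhood overweight and wasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage space-time model for childhood overweight and wasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its synthetic-data tests do and do
not demonstrate.

## The estimation problem

Household surveys measure weight, height, age and sex for children under 5
in geolocated clusters. We want annual prevalence surfaces, on a regular
grid, of three ordered nutritional states defined by the weight-for-height
z-score (WHZ): wasted (WHZ < −2), normal, and overweight (WHZ > +2), with
full uncertainty, and derived products: district aggregates, counts of
affected children, projections, and double-burden classes where wasting and
overweight co-occur.

## From child records to counts

WHZ is computed with the LMS (Box–Cox power) transform against a growth
reference indexed by sex and age: `z = ((x/M)^L − 1)/(L·S)` for `L ≠ 0` and
`z = log(x/M)/S` for `L = 0`. Classification uses *strict* inequalities at
±2 ("more than two standard deviations"): a z-score of exactly −2 is
normal. Records with missing required fields or |WHZ| > 5 are excluded with
a logged reason; the ±5 default follows the common anthropometric flagging
convention, and is configurable because no universal cutoff exists.

Counts are collapsed per cluster-year into the continuation-ratio layout:
`N` children, `C_w` wasted, and `C_o` overweight among the `N − C_w`
non-wasted. We condition overweight on *not being wasted* (the ordering used
by the model specification); the reverse conditioning is available via
`collapse_clusters(conditioning = "overweight_first")` for sensitivity
analysis, because the two orderings give slightly different stage-2
denominators.

## Seasonality adjustment

Survey timing confounds comparisons: WHZ dips in lean seasons. Before
collapsing we fit, with `mgcv`,

    WHZ ~ s_cc(month, k = 12) + s_tp(t, k = 4) + country

a cyclic cubic spline over calendar month (period 12, knots at month 0.5 and
12.5 so December wraps onto January), a rank-4 thin-plate spline over
months-since-study-start, and country fixed effects. Smoothing parameters
are chosen by GCV (the fitting ecosystem's default; exposed in the config).
The trend and country terms exist only to protect the seasonal curve from
confounding; the adjustment subtracts only the *periodic* component's
deviation from its cycle mean:

    WHZ_adj = WHZ − (s_cc(month) − mean_cycle(s_cc))

so a child interviewed at a month where the curve crosses its mean is
unchanged, and a uniform-month population keeps its mean WHZ. We adjust the
z-score directly rather than the raw weight: the category cutoffs live on
the z scale, and adjusting weight then recomputing z would interact with the
LMS curvature without changing the category logic. (Adjusting weight and
recomputing is possible through the exposed LMS utilities, but is not the
default path.)

## Polygon-referenced clusters

Surveys without cluster coordinates report only an administrative unit. Each
such observation is resampled to `k = min(100, max(1, round(n_cells/50)))`
pseudo-points drawn with replacement from the unit's cells with probability
proportional to population; pseudo-point weights are proportional to the
population of the sampled cells and normalized to sum to one per polygon.
Each pseudo-point carries the polygon's full counts, and its binomial
log-likelihood term is multiplied by its weight (a weighted
pseudo-likelihood), so one polygon contributes exactly one observation's
worth of information regardless of `k`. The 1-per-50-cells default keeps the
pseudo-point count proportional to polygon area, capped for cost; the exact
constant is a free design parameter and is configurable.

## Stacked-ensemble covariates

Three submodels are fitted per stage to the cluster counts on the gridded
covariates: a binomial additive model with penalized thin-plate smooths
(`mgcv`), gradient-boosted trees on binomial deviance (`xgboost`; 100
rounds, depth 3, learning rate 0.1 by default), and an L1-penalized logistic
regression with internally cross-validated penalty (`glmnet`). Each is
fitted under fivefold cross-validation; the compiled out-of-sample
predictions become the covariates of the geostatistical *fitting* stage
(preventing the meta-model from rewarding overfit submodels), while
full-data in-sample predictions are used at *prediction* time. Submodel
probabilities enter the linear predictor on the logit scale, so the
sum-to-one weights act on the same scale as the link and a weight vector
like (0, 1, 0) reproduces a single submodel exactly.

## The geostatistical stages

Each stage is the latent-Gaussian binomial model

    logit(p_it) = β₀ + X_it β + Z_it + ε_ctr(i) + ε_it,  Σ_h β_h = 1,

with `Z ~ GP(0, ω² R_Matérn(ν=2, κ) ⊗ R_AR1(ρ))`, `κ = sqrt(8ν)/δ` (so the
correlation at the range `δ` is ≈ 0.139, the conventional "distance where
correlation approaches 0.1"), iid country effects with variance γ², and an
iid nugget with variance σ² capturing survey-level noise.

**Support nodes instead of a triangulated mesh.** The GP is represented
exactly on a configurable subgrid of cells (default spacing 2–3 cell units,
mirroring an inner/outer mesh-resolution distinction); observations attach
to their nearest node, and prediction uses exact conditional (kriging) draws
from the Kronecker-factorized covariance. At the grid sizes this package
targets, dense Matérn algebra on a node subgrid fulfills the same contract
as a finite-element GMRF approximation — a latent GP with the stated kernel
— without the triangulation machinery. The node spacing trades spatial
resolution of `Z` against cost; spacing no larger than the true range is
needed for the range to be identifiable.

**Constraint and priors.** `β_H = 1 − Σ_{h<H} β_h` is substituted out, so
every represented coefficient vector sums to one *exactly*; the prior on the
free coefficients is the exact conditional of the iid `N(1/H, 3²)` prior
given the constraint (mean `1/H`, covariance `3²(I − J/H)`). Remaining
priors: `β₀ ~ N(0, 3²)`; Fisher-transformed `ρ`: `N(4, 1.2²)` (covering
ρ ∈ (−0.95, 0.95) within three sd while favouring strong positive annual
correlation); nugget and country precisions `~ Gamma(1, 5·10⁻⁵)` (the
conventional reading of the log-gamma default, i.e. shape and rate on the
precision); `log ω²` and `log κ` get diffuse `N(0, 10²)` priors since the
reference configuration defers these to mesh-dependent defaults. The five
documented sensitivity combinations are available as `prior_preset()`
presets.

**Laplace machinery.** At fixed hyperparameters θ the latent block
`(β₀, β_free, country, Z_nodes)` posterior is approximated by a Gaussian at
its Newton-optimized mode (step-halving, convergence at gradient ∞-norm
< 10⁻⁶, latent initialized at the prior mean and warm-started across θ
evaluations). The nugget adds one latent dimension per observation; those
dimensions are eliminated *analytically* from every Newton solve and
log-determinant through their diagonal Schur complement, so the factorized
dimension stays at fixed-effects + countries + nodes × years. θ — on the
scale `(log ω², log κ, Fisher ρ, log τ_nugget, log τ_country)` — maximizes
the Laplace-approximated marginal posterior by Nelder–Mead from
moment-flavoured initial values; proposals that make the node correlation
numerically singular are treated as −∞ posterior rather than errors. By
default prediction plugs in θ at its mode and propagates latent-block
uncertainty; `fit_control(theta_hessian = TRUE)` plus
`sample_stage(sample_theta = TRUE)` adds Gaussian θ-sampling at the mode
(full grid integration over θ is deliberately out of scope).

**Prediction and the nugget.** Draws of the latent block are combined with
exact conditional GP draws at the prediction cells; country effects for
countries unseen in training are drawn from `N(0, γ̂²)`. The nugget is
*excluded* from prevalence surfaces — it models survey noise, not
place-level prevalence — but *included* (with the binomial layer) in
predictive-count intervals for validation coverage, where observation noise
belongs. Stage draws combine as `p_over = (1 − p_wasting) · p_cond`, making
the three categories sum to one identically per draw.

## Post-estimation

All derived products operate at draw level. Cells labelled barren or with
total population below 10 per cell are masked. Unit prevalence is the
under-5-population-weighted mean over unmasked member cells; counts are
prevalence × under-5 population per draw; intervals are the 2.5th/97.5th
draw percentiles (the percentile convention is stated here because "95%
uncertainty interval" alone does not fix it). The annualized rate of change
is the *logit difference* between adjacent years — the printed ratio form is
interpreted as a logit difference because the projection adds AROC on the
logit scale, which is only dimensionally coherent for differences; the
literal ratio reading is available behind `aroc_type = "ratio"` for audit.
Recency weights `(t − t₀ + 1)^γ` are normalized to sum to one (otherwise the
AROC magnitude would scale with γ); γ defaults to 1 and is config since no
canonical value is fixed. Projections apply `logit⁻¹(logit(p_base) + AROC ×
8)`. Double-burden bands use lower-edge-inclusive thresholds (≥5, ≥10, ≥15
percent, reconciling ">5%" prose with "≥5–10%" banding); the DBM level is
the lower of the two conditions' bands. The WHO wasting target check is
strict: prevalence < 5%.

## Validation

Folds combine whole admin1 units (greedy balancing of observation counts,
seeded tie-breaks), so held-out clusters are spatially separated from
training data. For each fold the *entire* pipeline downstream of the raw
counts — stacking included — is refitted on the training folds. Coverage is
computed on predictive counts `Binomial(N, p_draw)` with nugget noise
included, using the smallest central ≥95% set (inclusive bounds, ties
conservative) since counts are discrete. Count-level (rather than
prevalence-level) coverage is the default because the observed quantity is
a noisy count; the prevalence-level alternative can be obtained by passing
nugget-free draws to `holdout_metrics()`.

## The synthetic world

`make_toy_world()` builds a planar unit-cell lattice — countries as vertical
strips, admin1/admin2 as nested axis-aligned blocks (guaranteeing strict
nesting), smooth low-frequency covariates, a log-smooth population surface
with a barren fraction, and a toy LMS reference whose `L` alternates between
1 and 0 by age so both z-score branches are exercised. Under-5 population is
a fixed 0.15 fraction of total. Child WHZ values are drawn from a
three-component truncated-normal mixture matching the latent truth's
category probabilities (the model only constrains category masses, so any
continuous law matching them is admissible; components stay within ±4.5 so
the plausibility filter is not triggered by construction), plus a planted
sinusoidal seasonal term; weights are back-computed through the LMS so the
z-score pipeline round-trips exactly. Cluster sizes are Poisson around a
configurable mean — survey cluster-size distributions vary too much across
programs to hard-code one.

Default truth parameters put most logit-scale variance in the covariates
(coefficient variance ≈ 1.5 versus GP ω² = 0.3, country γ² = 0.1,
range δ = 3 cells, ρ = 0.9): the modeling premise of the ensemble-covariate
design is precisely that covariates are well correlated with the outcome and
the GP absorbs *residual* autocorrelation. Worlds where the GP dominates are
easily configured, but then no method can predict held-out spatial blocks
well — a property of the problem, not of the implementation.

What the synthetic world does **not** emulate: real covariate semantics
(education, precipitation, travel time), irregular country shapes and
geodesic distance (the kernel is isotropic and stationary, so geodesy adds
no testable content at desk scale), survey design effects beyond observation
weights, and age-heaping or measurement error in anthropometry. Passing
tests therefore demonstrate correctness of the machinery and calibration
under correct specification — not robustness to the misspecifications real
surveys carry.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: the
cross-validation study uses a 20×20 grid, 8 years, 600 clusters of ~60
children, support spacing 2, 100–250 draws; parameter-recovery replicates
use 400 cluster-observations over 8 years on a 20×20 grid. The
cross-validation cluster size (60) was chosen by a signal-to-noise
calculation done at design time: with ~8% prevalence, binomial noise at
N = 30 would bound the attainable out-of-sample correlation near 0.8 even
for a perfect model, leaving no room to observe model error; N = 60 moves
that ceiling to ≈ 0.9. Admin1 units are 20 bands of 20×2 cells — small
relative to the domain, as real first-level units are — so conditional
(kriging) prediction into held-out bands remains meaningful.

Numerical details: correlation matrices receive escalating diagonal jitter
before Cholesky (error with guidance if still indefinite); covariance
*factors* used only for drawing noise fall back to an eigenvalue-clipped
square root when a kriging Schur complement is numerically rank-deficient;
Matérn evaluation uses the exponentially scaled Bessel function on the log
scale to avoid underflow at large distances, with the removable `D = 0`
singularity handled explicitly; probabilities are clamped to
`[10⁻⁶, 1 − 10⁻⁶]` before logits in post-estimation, with a warning.
Degenerate fits (all-zero or all-`N` counts) proceed with a boundary
warning rather than failing, since sparse strata do occur.

## Known limitations

Plug-in hyperparameters understate total uncertainty relative to full
integration over θ (the optional Gaussian θ-sampling narrows but does not
close this gap); ω² is attenuated when the node spacing under-resolves the
true range; the Nelder–Mead optimizer can need a few hundred evaluations on
flat marginal surfaces; and the support-node formulation scales as the cube
of nodes × years, so continental grids would need the sparse-precision
machinery this package intentionally replaces at desk scale.
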