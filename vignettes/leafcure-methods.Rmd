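---
title: "Methods: image-based moisture prediction for air-cured leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based moisture prediction for air-cured leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the modelling choices behind `leafcure`: the
pipeline's assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the decisions taken where the
design was genuinely open.

## Ground truth

Moisture is wet-basis: the water lost between the pre-imaging weighing
and oven drying to constant weight, over the wet leaf mass,

$$MC = \frac{(M_{leaf}-M_0)-(M_{dry}-M_0)}{M_{leaf}-M_0},$$

with $M_0$ the container weight (`moisture_content()`). The package
represents moisture internally as a fraction in $[0,1)$; campaign
summaries print percent.

## Segmentation

The scene assumed is a single suspended leaf against a near-white
background under diffuse light. Two binary masks are combined by
logical OR:

* an **HSV window**: a pixel is foreground iff all of hue, saturation
  and value lie inclusively within `t_min = (15, 20, 15)` to
  `t_max = (175, 255, 255)`. Hue is on the 0–179 integer scale
  (degrees/2) — the only scale on which a 15–175 window spans
  green-through-brown foliage while excluding the red wrap-around; the
  saturation floor of 20 rejects the grey-white background.
* an **Otsu threshold** of the BT.601 grayscale image after 5×5 median
  smoothing. The mask takes the *darker* class, since the background
  is bright. This branch catches late-curing leaves whose hue drifts
  below the window floor.

Cleanup keeps the largest 8-connected component (component labelling
runs on a pixel-adjacency graph via igraph) and fills interior holes;
masks below `min_component_fraction` (default 1% of the image) raise a
"no leaf found" error. Keeping only the largest component discards
disconnected curled tips; that is a deliberate, configurable choice —
a fragment large enough to matter should survive as part of the main
component in practice.

Numerical conventions worth noting: Otsu's threshold is the argmax of
between-class variance over all 256 candidate levels, the lowest level
on ties; a constant image is a degenerate input and raises an error
rather than returning an arbitrary level.

## Features

Per surface, colour statistics (mean and SD of B, G, R and CIELAB L\*,
a\*, b\*) are computed over mask pixels only — background pixels never
enter a statistic. CIELAB uses standard sRGB companding and the D65
white point; L\* spans $[0,100]$ and a\*/b\* are unscaled. The
conversion is implemented in the package and cross-checked in the test
suite against `grDevices::convertColor` (which uses a slightly
different D65 adaptation; agreement is within a few hundredths of a
unit).

Texture comes from a grey-level co-occurrence matrix (GLCM) over the
masked region: gray values quantized to 64 equal bins, pixel pairs at
distance 1 along 0°, 45°, 90° and 135°, each direction's count matrix
symmetrized and normalized, directions averaged with equal weight.
Only pairs with *both* endpoints inside the mask are counted, so
leaf-background transitions contribute no spurious contrast. Five
Haralick statistics summarize the matrix: angular second moment,
contrast, correlation, entropy (natural log) and inverse difference
moment. Correlation is defined as 1 when both marginal variances
vanish: a constant region is perfectly self-correlated, and this keeps
the statistic continuous as a region approaches uniformity. All GLCM
parameters are configurable through `texture_config()`.

Leaf position (lower/middle/upper → 0/1/2) and airing period (wilting
… dry tendon → 0–4) enter as label-encoded integers, which lets them
participate in Pearson-correlation screening alongside the continuous
descriptors.

## Two-step feature filter

Step one correlates every feature with moisture and classes them by
|PCC|: above 0.75 *important*, 0.45–0.75 *relatively important*, at or
below 0.45 *unimportant* (dropped). Constant features are classed
unimportant with an audit note rather than raising mid-pipeline.

Step two prunes redundancy greedily: features are visited in
decreasing target |PCC| (ties broken by the canonical 36-column
order, so builds are deterministic) and dropped when |PCC| ≥ 0.80 with
any feature already retained. The 0.80 threshold is a package default
— "strongly correlated" is not a quantity with a canonical value —
and is configurable. Two backstops reflect how texture features behave
in practice (they correlate strongly with each other but weakly with
colour): the texture feature most correlated with the target, and the
texture feature least correlated with everything retained, are always
kept. Every removal is logged with its reason in the audit trail.

## Candidate learners, scoring, stacking

The registry holds eight regressors in three families: LR, SVR, MLP
(single); RF, ET (bagging, extra-trees via ranger's `extratrees`
split rule); GBDT, XGBoost, AdaBoost (boosting). Least-squares
gradient boosting and AdaBoost.R2 are implemented in the package over
`rpart` base trees — the classic stagewise-residual and
weighted-median-of-rounds algorithms. A ninth boosting variant common
in this literature (LightGBM) has no R implementation available here
and is not in the registry.

Hyperparameter search spaces are package defaults (tree counts
50–400, depths 2–8, SVR cost/γ/ε on log scales, MLP width 2–16 and
weight decay 1e-4–0.1) — explicitly a reconstruction, since no
canonical spaces exist. `ga_tune()` searches a space with a
generational GA: population 30, 20 generations, tournament size 3,
one-point crossover p = 0.9, per-gene mutation p = 0.1, elitism of
one, fitness = mean 5-fold CV R². The GA is deterministic under its
seed; fold assignment and per-fold fit seeds are derived from it.
Tuning is optional: the pipeline's defaults are sensible, and the
acceptance script runs the campaign with default hyperparameters so
its runtime stays in tens of seconds.

Each candidate is judged by 5-fold CV: mean, standard deviation and
coefficient of variation (Std/mean) of R², MSE, MAE, MAPE (a
fraction, not ×100 — moisture is strictly positive so MAPE is always
defined) and the explained variance score, 15 indicators total.
R²_mean and EVS_mean count as positive, the other 13 as negative, and
the entropy weight method turns the models × indicators matrix into
one composite score per model: direction-aware min–max normalization,
column shares with an ε = 1e-12 shift, Shannon entropy, weights
proportional to 1 − entropy. An indicator identical across models
gets weight zero — it cannot discriminate. Runtime is recorded as a
complexity proxy but never scored; it breaks ties when choosing the
meta-learner. On EVS: the standard explained-variance score
$1 - \mathrm{Var}(y-\hat y)/\mathrm{Var}(y)$ is used, which is 1 for
perfect predictions; a printed variant that would score a perfect
predictor 0 is a known typographical hazard in this literature and is
not reproduced.

The best scorer per family becomes a base learner; the meta-learner
defaults to LR (the least complex adequate single model). `leafstack`
builds the meta-features as out-of-fold base predictions — the
prediction for a training row always comes from a fold model that
never saw it — fits the meta-learner on them, then refits the bases
on the full training set for inference (fold-model averaging is
available behind `inference = "fold_average"`; the refit convention
is the package default because it uses all training data at
prediction time). The meta-learner sees only the base predictions, no
passthrough features. Final predictions are clipped into $[0,1]$ with
a message, since moisture is a fraction.

Standardization (z-scores, sample SD) is fitted on the training split
only and applied unchanged to the test split — fitting it on all data
would leak test information into the transform. The train/test split
itself is period-stratified: 35 uniformly sampled test leaves per
period by default, so the test set mirrors the campaign's moisture
distribution.

## Shapley attribution

`shapley_values()` implements permutation-sampling Shapley estimation
with marginal (background-replacement) imputation: a sampled feature
order is walked from a background row towards the explained row, and
each feature is credited with the prediction change it causes.
Permutations are used in antithetic pairs (each order and its
reverse), which cancels the order-asymmetry of up-to-bilinear effects
exactly, and background rows are cycled from a shuffled copy rather
than drawn iid, so with the default 200 permutations and a 100-row
background the background mean is matched almost exactly. For a
linear model the estimate then reproduces the closed form
$\phi_j = \beta_j (x_j - \bar z_j)$ to a fraction of a percent of the
prediction range. An exhaustive-enumeration mode (`exact = TRUE`,
feasible to ~14 features) computes coalition values against the full
background and serves as the oracle in the test suite.

Additivity — base value plus attributions equals the prediction — is
exact in enumeration mode and holds to Monte-Carlo error in sampling
mode; the per-row residual is stored on the result, with 0.05 of the
prediction range the documented tolerance for sampling mode.
`rv_contributions()` converts attributions into each feature's
percent share of total mean |φ| (summing to 100 by construction) and
aggregates by surface group; `dependence_profile()` tabulates one
feature's attribution against another feature's value — the material
of an interaction (PDP-style) plot. Plotting itself is left to the
caller; numbers, not pixels, are the tested surface.

## The synthetic campaign

`make_dataset()` emulates the composition of a real curing campaign:
880 leaves, period counts 164/172/177/211/156, positions 280/320/280,
per-period moisture drawn from a truncated normal with the campaign's
printed mean/SD/min/max. Weights are synthesized backwards from
moisture (container 10 g, wet mass 100 g), so the wet-basis formula
recovers the drawn moisture exactly. A note on counts: the emulated
campaign reports 880 samples with two photographs each; the generator
follows the per-sample table (880 leaves, 1760 images).

`make_leaf_image()` renders a smoothed random blob (harmonic
perturbation of an ellipse) whose colour follows period anchors — the
green mean falls strictly and the red/green ratio rises across
periods, within-period colour tracks moisture — with period-graded
shrinkage and vein texture, and a dimmed hue-shifted rear surface.
Rendering is deterministic per sample seed. The default rendered size
in examples (195×130) keeps test runtimes small; `generator_config`'s
default `image_size` of 780×520 is a quarter of the emulated capture
resolution.

`synth_feature_table()` is the fast analytic path for modelling
experiments: a latent appearance state $u = m + \varepsilon$,
$\varepsilon \sim N(0, 0.015)$, drives monotone near-linear curves
for the informative descriptors, while descriptors the filter should
discard are noise-dominated. The 1.5-point latent noise floor was
chosen once so that competent learners land in the upper-0.98/0.99
CV-R² regime a real campaign of this kind produces — high enough to
be realistic, low enough that the stacking comparison is not decided
by noise. Because every informative column is driven by the same
latent state, the synthetic table is *more* collinear than real
data: the two-step filter typically retains only ~8 of 36 columns
(real campaigns retain ~15), and the AP code can be pruned as
redundant with colour. Consequences for interpretation: the
contribution report on synthetic data concentrates on front-surface
colour and should not be read as a statement about real leaves.

What passing tests on this generator do show: the segmentation
recovers known masks (IoU ≥ 0.95), features respond monotonically to
the planted drift, every learner clears CV R² 0.8 under the stated
noise, the stack's test R² is never materially below its best base,
and the attribution machinery satisfies its exact invariants. What
they cannot show: robustness to illumination change, camera noise,
occlusion, multi-leaf scenes, or any claim about real curing barns.

`make_feature_table()` serves the filter's own tests: an explicit
factor construction (target factor + independent group factors) whose
pairwise correlations are exact in expectation and positive
semidefinite by construction; unrealizable requests
($r^2 + c^2 > 1$) are rejected. `make_selection_fixture()` instances
it with planted relevances and redundancy blocks arranged so the
filter's documented rules retain exactly the canonical 15-name
subset; margins between planted values and the 0.45/0.75/0.80
boundaries exceed three sampling standard errors at n = 880, so
recovery is seed-stable.

## Problem sizes and runtime

The test suite and the acceptance script run the full 880-leaf
campaign: 5-fold CV of all eight learners on the 705-row training
split (~25 s on one core), stacking fit and evaluation (~5 s), and
Shapley attribution of 50 held-out leaves at 200 permutations
(~10 s). The GA is validated on a one-parameter closed-form learner
against a grid-search oracle rather than on tree ensembles, whose
tuning costs minutes and adds no additional coverage of the GA
itself.

## Known limitations

* The segmentation assumes one leaf on a near-white background;
  cluttered scenes are out of scope.
* The GLCM is computed on masked pairs only; a bounding-box variant
  (including background pixels) would give systematically different
  texture values.
* LP/AP enter correlation screening as integer codes; Pearson
  correlation on ordinal codes is a pragmatic convention, not an
  ordinal-association measure.
* The synthetic generator's collinearity caveat above: selection
  results on synthetic tables are structurally, not numerically,
  comparable to real campaigns.
* `predict` clipping to $[0,1]$ introduces a small nonlinearity at
  the range edges; it is logged whenever it fires.
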