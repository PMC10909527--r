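---
title: "Methods: building and testing an autonomic-subjective affective space"
author: "affectspace"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: building and testing an autonomic-subjective affective space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectspace)
```

## The problem

A long-standing question in emotion research is whether the body and the
mind move together: do autonomic responses (pupil dilation, skin
conductance, heart rate) covary with the subjective experience of emotion
(valence, arousal) on a trial-by-trial basis? Univariate tests of one signal
at a time have produced famously mixed answers. This package implements the
multivariate alternative: place the subjective ratings and the autonomic
features of every trial into one table, partition the columns into a
*subjective* and an *autonomic* group, and ask how many latent dimensions
the joint covariance supports and which groups build each dimension.
Coherence appears as a dimension with material contributions from both
groups; divergence appears as structure confined to the autonomic group
(the classic physiological reading of such an autonomic-only profile is an
orienting response: a nonspecific reaction to salient stimuli).

The pipeline has five stages, each usable on its own:

1. `generate_trial_table()` — a synthetic study with planted structure
   (or `read_trial_table()` for real data);
2. `extract_trial_features()` — pupil/SCR/HR features from raw signals;
3. `coherence_model_suite()` — trial-level mixed models;
4. `fit_mfa()` + `inference_report()` — the group-weighted factor space
   with bootstrap and permutation inference;
5. `classify_space()` / `cluster_space()` — validation of the retained
   dimensions.

## The synthetic-data generator

The generator defines the study conditions under which every guarantee in
the test suite is stated. It emulates a 51-participant by 56-image design:
each trial yields subjective valence and arousal on −10..+10 sliders,
baseline-corrected pupil diameter (mm), phasic skin-conductance amplitude
(µS), heart-rate change (post − pre, bpm), and a standardized image
brightness covariate.

The data-generating model is the minimal structure that produces a
two-dimensional joint space:

$$y_{vij} \;=\; \lambda^{(1)}_v f_{1,ij} \;+\; \lambda^{(2)}_v f_{2,ij}
\;+\; b_{vi} \;+\; c_{vj} \;+\; \textit{(extras)}_v \;+\;
\varepsilon_{vij},$$

for variable $v$, participant $i$, stimulus $j$: a shared **affect factor**
$f_1$ loading on all five variables, an **orienting factor** $f_2$ loading
on the autonomic variables only, crossed participant and stimulus random
intercepts, and variable-specific extras — a valence-by-arousal product
term and the brightness coefficient for pupil, and a log link for skin
conductance (amplitudes are `exp(scr_log_mean + latent)`, which keeps them
nonnegative while preserving a monotone link to the factors; truncating a
Gaussian would not).

Parameter choices worth knowing about:

* **Loadings.** Defaults plant a mixed dimension (valence loads negatively,
  arousal positively — more negative experiences are also more intense —
  with moderate autonomic involvement) and an autonomic-only dimension
  dominated by an SCR–HR covariance with weak opposite-sign pupil
  involvement. The implied cross-signal correlations have pupil–SCR near
  zero, pupil–HR positive and SCR–HR negative, the pattern the univariate
  stage is expected to recover.
* **Stimulus affect share** (`stimulus_affect_share = 0.4`): 40% of the
  affect factor's variance is a deterministic normal-score function of the
  stimulus norms, so stimulus categories genuinely organize the space (this
  is what supplementary projection and classification detect); the
  remaining 60% is trial-level, reflecting the sizable momentary and
  idiosyncratic variability that motivates mixed models in the first place.
* **Variance components.** Participant intercept SDs are generous and
  stimulus intercept SDs small: stimulus-level variance is mostly carried
  by the norm-driven affect component, while individual differences are a
  dominant feature of trial-level psychophysiology.
* **Residual valence–arousal correlation** (`rho_va = -0.1`): a small
  negative residual coupling beyond the shared factor.
* **SCR interaction default 0.** The valence-by-arousal modulation is
  planted on pupil (`interaction = c(pupil = 0.03, scr = 0)`). Keeping the
  log-SCR model linear-Gaussian gives the package an exact closed-form
  implied covariance (`implied_covariance()`), which the test suite uses as
  an independent oracle; a nonzero SCR interaction is honoured by the
  generator but removes the closed form.
* **Homogeneous loadings.** Some individuals plausibly have
  reversed coherence directions; the default generator does not plant
  participant-specific loading signs, because the group-level space is the
  estimand of every downstream check and heterogeneous signs would change
  that estimand itself. Sign heterogeneity is better studied as an explicit
  extension than as a hidden default.

`implied_covariance()` gives the population covariance of the five observed
variables in closed form, including the log-normal SCR corrections
($\mathrm{cov}(e^X, Y) = \sigma_{XY} E e^X$ for jointly Gaussian latents)
and the product-term variance $\beta^2(1 + r^2)$. Rating clipping at ±10 is
ignored there: under default scales fewer than 1% of ratings clip and the
effect on any correlation is below $10^{-3}$. With `stimuli` (and
optionally the realized `stimulus_effects` attached to every generated
table) it returns the covariance *conditional on the stimulus set* — the
estimand of any analysis that treats the 56 images as fixed by design.

What the generator does **not** emulate: within-trial temporal dynamics
beyond canonical response shapes, habituation across trials, missing-data
mechanisms other than missing-completely-at-random, eye movements, and
participant-varying coherence direction. Tests passing under these
conditions show the *machinery* is correct and calibrated; they do not show
that real data satisfy the model.

## Raw signals and feature extraction

`generate_raw_signals()` back-generates per-trial pupil series (150 Hz),
skin-conductance series (10 Hz) and heart-rate window means whose extracted
features reproduce the trial table exactly at zero noise (a closure
property the acceptance suite asserts at 5% tolerance). The pupil event
response uses a saturating shape so that even strong constrictions stay
inside the physiological validity range; the SCR wave is bi-exponential
(rise 0.75 s, decay 2 s) with onset latency 1.5 s, inside the scoring
window.

Preprocessing follows standard pupillometry/electrodermal practice:

* pupil samples outside **2–10 mm** are invalid; invalid runs up to
  **150 ms** with valid neighbours are linearly interpolated, longer runs
  stay excluded (`interpolate_invalid()` reports both counts);
* **subtractive baseline correction** with a window from **−1 s to +1 s**
  around onset. A baseline that straddles onset is unusual but intentional
  here; `preprocess_params(baseline_mode = "pre_onset")` restores the
  conventional pre-onset window;
* SCR is scored **trough-to-peak** in the **1–6 s** post-onset window as
  the maximum rise over a running minimum, with a conventional
  **0.01 µS** minimum-amplitude criterion (smaller rises score 0);
  smoothing beyond the windowed amplitude is a plain moving average and is
  off by default;
* heart rate is consumed as pre/post window means; the change score is
  **post − pre**, so stimulus-evoked *deceleration is negative*. The sign
  convention is worth stating loudly because the opposite subtraction
  order is also in circulation; this package fixes the sign so that
  "deceleration with higher arousal" reads as a negative coefficient.

Trials failing a precondition (no valid baseline sample, window outside
the recording) carry `NA` plus a flag — never a silent zero.

## Trial-level mixed models

`fit_trial_lmm()` fits REML linear mixed models with crossed random
intercepts for participant and stimulus via `lmerTest`, reporting
Satterthwaite approximate p-values (the method is recorded in the fit
metadata). Predictors are z-scored by default (`standardize = FALSE` keeps
raw scales; the predictor SDs are stored either way so `simple_slopes()`
can place moderator levels at ±1 SD). Random slopes are not fitted by
default; the grouping structure is the conservative intercepts-only
reading. Degenerate variance components come back as 0, non-convergence is
flagged, and a rank-deficient fixed design fails with the collinear terms
named. `coherence_model_suite()` packages the standard model set: each
autonomic feature on valence, arousal and their product (brightness added
for pupil), the single-predictor heart-rate models, and all pairwise
cross-signal predictions.

## The group-weighted factor space

`fit_mfa()` implements Multiple Factor Analysis for quantitative groups
from first principles. Each active column is centered and scaled to unit
variance (the stated motivation for MFA — groups should not dominate
through range or count — presupposes standardization), then every column
of group $g$ is multiplied by $1/\sqrt{\lambda_1^{(g)}}$ where
$\lambda_1^{(g)}$ is the first eigenvalue of the group's standardized
covariance. After weighting, each group's sub-table has first eigenvalue
exactly 1. The global solution is the eigendecomposition of the weighted
covariance; with eigenvector entries $v_{js}$, eigenvalues $\lambda_s$ and
column weights $w_j$:

* correlation of variable $j$ with dimension $s$:
  $\sqrt{\lambda_s}\, v_{js} / \sqrt{w_j}$, and $\cos^2$ its square;
* contribution of variable $j$: $100\, v_{js}^2$ (equivalently
  $100\, w_j \cdot \mathrm{cor}^2 / \lambda_s$), summing to 100 per
  dimension, and group contributions are their sums;
* partial coordinate of row $i$ for group $g$: $G$ times the projection of
  the row's group-$g$ weighted profile on the global axis, so the mean of
  the partial coordinates across groups is exactly the global coordinate
  (asserted to 1e-10);
* partial axes are correlations between each group's separate PCA scores
  and the global scores;
* supplementary categories are plain barycentres of their rows' scores
  (no eigenvalue rescaling — software conventions differ, so the choice is
  stated); per-group barycentres of the partial coordinates quantify group
  disagreement about a category.

Determinism: each dimension's sign is fixed so that the variable with the
largest absolute correlation loads positively; ties cannot occur with
continuous data, and the first index wins if they do. Missing policy is
complete-case with a logged dropped-row count. A single active group
reduces the procedure to ordinary principal components (asserted in the
suite), and on any small table the eigenvalues and scores match an
independent brute-force oracle to 1e-10.

`aggregate_table()` produces the sensitivity variants (cell means by
participant, stimulus, or participant × category); standardization and
weighting happen downstream, *within* each variant, so the variants differ
only in the rows they analyze.

Brightness can either be pre-residualized out of pupil before the space is
built (`pipeline_config(brightness_adjust = TRUE)`, the default, using a
crossed-intercept regression so the luminance confound never enters the
space) or left in; both paths are exposed because either policy is
defensible and they answer slightly different questions.

## Resampling inference

**Permutation test.** Null datasets are built by independently reshuffling
each quantitative column while respecting the hierarchy, refitting the MFA
each time, and computing one-tailed add-one p-values
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$ (so $p$ can
never be 0 and is valid in finite samples).

Two choices here deserve their own paragraphs, because both were made on
measurable grounds.

*The statistic is the percent-of-inertia share, not the raw eigenvalue.*
Group weights are data-dependent: permuted columns decorrelate, every
group's $\lambda_1^{(g)}$ is pushed toward 1, and the null total inertia
(about 5 for five variables) exceeds the observed one (about 3 under
planted structure). Raw eigenvalues of observed and null fits therefore
live on different scales, and a genuinely structured second dimension can
sit *below* every null draw of $\lambda_2$. The share
$100\,\lambda_s/\sum_t \lambda_t$ is scale-free, with null expectation
$100/p$ percent per dimension; it is the statistic under which "how many
dimensions are significant" is well-posed. Raw-eigenvalue p-values are
reported alongside (`p_eigenvalues_raw`).

*The default scheme permutes stimulus blocks, not rows.* In a crossed
design the same stimuli appear in every participant, so each column carries
cross-participant stimulus-level coherence. Row-level shuffling within
participant × category strata destroys that coherence in the null draws
while the observed statistic retains it, which makes the test
anticonservative. The default `scheme = "stimulus_blocks"` instead relabels
each column's stimulus identities within stimulus category, consistently
across participants: this is a subgroup of the within-stratum permutations
(every participant × category multiset is preserved exactly), it keeps the
stimulus-level coherence in every null draw, and it is exactly exchangeable
under a crossed-random-effects null. The row-level scheme remains available
as `scheme = "within_strata"` for comparison. The acceptance suite verifies
the default scheme's type-I error at $\alpha = .05$ over 200 null
generator seeds.

Null replicates are compared to the observed solution dimension-by-rank.
Aligning null draws to the reference would select, per replicate, the
null dimension most similar to the observed one and inflate the null
loading distribution; alignment is for bootstrap replicates only.

`retained_dimensions()` counts the *leading consecutive* dimensions with
eigenvalue-share $p < \alpha$: an isolated significant dimension after a
non-significant one does not reopen the count, because dimension identity
beyond a non-significant gap is not stable under resampling.

**Bootstrap.** Confidence intervals resample participants with replacement
(all trials of a drawn participant travel together), refit the space,
*align* each replicate to the reference solution — greedy one-to-one
matching of dimensions by absolute correlation of loading vectors, with
sign flips; the proportion of replicates needing swaps or flips is reported
as an alignment diagnostic — and take the .025/.975 quantiles. By default a
second stage also resamples trials within each drawn participant: with
about 50 clusters and a smooth nonlinear statistic like an eigenvalue, the
single-stage percentile interval is systematically narrower than the
sampling dispersion of the estimate, and the second stage restores
near-nominal coverage; the plain cluster bootstrap is available with
`resample_trials = FALSE`. The acceptance suite measures coverage of the
95% interval for the leading eigenvalue against the population value from
the conditional implied covariance, over 100 generator seeds at 200
replicates each.

Reference replicate counts are 10,000 for both procedures; the test suite
and the acceptance script run reduced counts (199–2,000) chosen to keep
the whole suite in minutes at one CPU while leaving Monte-Carlo error well
inside every asserted band. Replicate seeds are derived deterministically
from the master seed, so results are bit-identical for any parallelism
degree (`jobs`).

## Validation of the retained dimensions

`classify_space()` trains a 500-tree random forest
($\sqrt{p}$ features per split, 70/30 stratified split — the forest size
and split are reported with the results) to predict valence category from
the retained dimension scores, reporting out-of-bag and held-out accuracy,
one-vs-rest AUC per class from the vote proportions, permutation variable
importance (mean decrease in accuracy) per dimension, and the chi-square
test of the held-out confusion matrix. `cluster_space()` runs k-means with
many restarts over $k \in 2..8$ and reports the silhouette-maximizing
solution with its percent between-cluster variance and (when labels are
supplied) the cluster-by-class chi-square. The silhouette is computed from
its definition (mean over points of $(b-a)/\max(a,b)$, zero for
singletons); with a few thousand rows the full distance matrix is cheap.
Guard tests assert that shuffled labels score at chance (no leakage), that
three well-separated blobs yield $k = 3$ with a high silhouette, and that
importance follows where the class signal was planted.

## Numerical choices, degenerate inputs, limitations

* Eigen-solutions use symmetric eigendecomposition; negative round-off
  eigenvalues are clamped at 0; ranks are decided at a relative 1e-12
  threshold and `n_dims` beyond the rank truncates with a warning.
* Zero-variance active columns are an error naming the column; in
  bootstrap replicates they drop the replicate with a count, never
  silently.
* Greedy dimension matching breaks ties by first maximum; the suite checks
  it against exhaustive matching over all permutations on planted
  replicates.
* Closed-form moments ignore rating clipping (sub-0.1% effect at default
  scales) and, in the conditional form, approximate the log-normal SCR
  moments by a single Gaussian rather than the 56-component mixture —
  both far below the resolution of any asserted band.
* Aggregated tables can have very few rows per cell; the MFA requires at
  least 3 complete rows and nonzero variance and says so.
* The checks in this package are statements about the generator's study
  conditions (problem sizes 51 × 56; calibration at 200 seeds × 199
  permutations; coverage at 100 seeds × 200 bootstrap replicates; mixed
  models at 50 seeds). Real psychophysiological data bring habituation,
  drift, artifacts and individual differences in coherence direction that
  the generator deliberately omits; on real data the package reports the
  same diagnostics (alignment proportions, dropped replicates, quality
  flags) so those departures surface rather than hide.
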