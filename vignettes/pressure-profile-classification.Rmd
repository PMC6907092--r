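---
title: "Classifying pelvic floor pressure profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pelvic floor pressure profiles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(pfpress)
```

## The problem

Urinary incontinence in women is tied to how the pelvic floor muscles (PFM)
generate and sustain pressure along the vaginal canal. An instrumented,
non-deformable intravaginal probe carrying a 10 × 10 matrix of capacitive
sensors records that pressure field over time while a subject performs four
instructed maneuvers: a 3 s maximal contraction, a 5 s Valsalva push, a 10 s
endurance hold and a 4 s "wave" (caudal–cranial contraction followed by the
reverse relaxation). `pfpress` implements the complete analysis chain that
turns such spatiotemporal recordings into a continent / incontinent
classification: sensor-grouping supersets, formula-defined feature
extraction, two-stage feature selection and nested leave-one-out (LOO)
evaluation of three classifiers. Because clinical recordings of this kind
are not publicly available, the package also ships a seeded synthetic
cohort generator so every stage can be exercised, calibrated and tested end
to end.

## Sensor geometry

Columns of the matrix run around the probe circumference, rows (rings) along
its axis. Features are computed over six superset families:

* **quadrants** (`s_long`): posterior, anterior, right, left column groups;
* **axial bands** (`s_lat`): cranial, medial, caudal rows, sizes 3/4/3;
* **planes**: plane *i* = columns *i* and *i + 5* (two diametrically
  opposed sensor lines, 20 sensors each);
* **rings**: the ten 10-sensor circumferential rows;
* **quadrant × band intersections**: twelve groups;
* the **whole matrix**.

Only the anterior columns (8 and 9) are anchored by the insertion protocol.
The remaining quadrant memberships are a design choice: the posterior
quadrant is taken as the diametric partners {3, 4} (consistent with the
plane pairing *i*, *i + 5*), right as {5, 6, 7}, left as {10, 1, 2}; all are
configurable through `geometry_config()`. The axial orientation is genuinely
ambiguous — "the first three rows" can be counted from the deep end or from
the vaginal opening — so `row1_position` switches between the two readings;
the default places row 1 at the deep (cranial) end.

For a sensor set $S$, two series are formed per frame $t$:
$Y^S_{peak}[t] = \max_{s' \in S} S[t]$ and
$Y^S_{sum}[t] = \sum_{s' \in S} S[t]$ (kPa). Every per-sensor series is
low-pass filtered *before* any grouping or feature extraction — grouping a
filtered recording is not the same as filtering a grouped series, and the
pipeline deliberately uses the former (there is a regression test pinning
the order).

### Zero-phase filtering

The preprocessing filter is an effective 8th-order low-pass Butterworth at
8 Hz with zero phase lag, realized as a forward–backward pass of a 4th-order
design (the standard biomechanics convention for "zero-lag, 8th order").
Startup transients are controlled by odd-reflection padding of 3 × the
effective order (24 samples) at each end, and each pass is referenced to its
starting value so a constant series passes through exactly. The attenuation
is verified in the tests against the analytic squared magnitude response of
the designed digital filter.

## Feature extraction

On the post-baseline maneuver window (instants normalized to $[0, 1]$ over
the window, earliest index on ties):

* `max_p`, `max_s` — maxima of the peak and sum series (kPa);
* `t_max_p`, `t_max_s` — their normalized instants;
* `t_activ` — first instant with $Y_{peak} > \delta$;
* `int_p`, `int_s` — raw sample sums of the two series (kPa · samples; the
  defining formulas sum samples, so no $1/f_s$ rescaling is applied);
* `plateau` — longest contiguous run with $Y_{peak} \ge 0.9 \max Y_{peak}$,
  in seconds (whole matrix, endurance only);
* `cr`, `rr` — wave contraction and relaxation rates on normalized time
  $t'$: $CR = (\max Y - Y[0]) / \operatorname{argmax} Y$ and
  $RR = (Y[1] - \max Y) / (1 - \operatorname{argmax} Y)$ (whole matrix,
  wave only);
* 23 covariance features: the main diagonal (12) and first subdiagonal (11)
  of the sample covariance matrix of the twelve intersection `y_sum` series
  (maximal contraction, Valsalva, endurance). "Lower diagonals" is an
  ambiguous plural, so the number of subdiagonals is configurable; the
  default is one.

The activation threshold is defined from the 1 s pre-command rest segment as
$\delta = \text{baseline mean} + 2 \times \text{baseline SD}$ of the peak
series. A bare $2 \times SD$ threshold would sit below resting pressure and
fire at the first sample; adding the baseline mean makes the threshold an
excursion criterion. Both the multiplier and the mean offset are
configurable in `activation_config()`. The relaxation-rate numerator is
taken as *value at the end minus the maximum* (a negative rate for a decaying
tail), which is the only reading consistent with a relaxation phase.

Per maneuver the menu yields 198 features (maximal contraction, Valsalva),
229 (endurance) and 177 (wave); `feature_menu_counts()` records the
arithmetic and a test audits it.

**Undefined features.** `t_activ` can never cross the threshold, and a wave
rate with its argmax on the window boundary has a vanishing denominator.
Selection and classification need a complete matrix, so these are imputed
with the window boundary values (`t_activ` → 1, rates → 0) and logged via
the `"imputed"` attribute. Imputation at the boundary is conservative: an
undetectable activation is treated as "latest possible".

## The synthetic cohort generator

`generate_cohort()` emulates the acquisition protocol: a balanced cohort
(default 24 + 24 subjects), four maneuvers per subject, a 10 × 10 array at
50 Hz, a 1 s rest segment before the command, additive Gaussian sensor
noise, quantization to the 0.42 kPa sensor resolution and clamping to the
0.50–100.00 kPa measurement range. Each recording is

$$\text{baseline} + \text{amplitude} \times \text{envelope}(t) \times
  \text{spatial map}(r, c) + \text{noise},$$

with raised-cosine envelopes (smooth, closed-form argmax): a symmetric bump
peaking mid-maneuver for the maximal contraction, a trapezoid with a hold
for Valsalva, a ramp–plateau–ramp with exponential plateau decay for
endurance, and for the wave a traveling Gaussian activation whose ring
center moves caudal → cranial → caudal (`wave_ring_center()`). The static
spatial map is a separable Gaussian bump over rings (the "high-pressure
zone") times a mild posterior-dominant column profile.

Class differences enter only through `class_effect()`, applied to the
incontinent group: `amplitude_ratio` (multiplicative, < 1 = weaker
contraction), `timing_shift_frac` (delayed peak), `plateau_decay` (failing
endurance hold), `wave_asymmetry` (slower contraction phase) and
`spatial_focus_shift` (displaced pressure focus, in rings). The neutral
setting (1, 0, 0, 0, 0) makes the two classes exchangeable in distribution,
which is what the null-calibration test exploits.

Defaults were chosen once as plausible study conditions and are documented
placeholders — no public quantitative description of baseline pressures per
group exists to calibrate against:

| parameter | default | unit | rationale |
|---|---|---|---|
| baseline pressure | 5 ± 1 | kPa | resting vaginal pressure well inside the measurement range |
| contraction amplitude | 20 ± 4 | kPa | clear dynamic range below the 100 kPa ceiling |
| sensor noise SD | 0.8 | kPa | about twice the quantization step |
| timing jitter SD | 0.03 | fraction | small trial-to-trial coordination variability |
| default class effect | 0.75 / 0.10 / 1.5 / 0.20 / 1 | — | moderate, multi-facet group difference |

Determinism: each subject owns an RNG stream derived from the master seed by
a counter-based split, so cohorts are pure functions of their configuration
and independent of generation order. Quantization is applied before
clamping, and values are clamped to the nearest quantization level *inside*
the measurement range ([0.84, 99.96] kPa at defaults) so that stored values
are simultaneously within range and exact multiples of the resolution.

What the generator does **not** model: tissue biomechanics, probe-surface
curvature, sensor cross-talk, drift, or absolute clinical pressure
magnitudes. Passing tests therefore demonstrate that the pipeline recovers
planted effects of the assumed separable form — not that it would reach any
particular accuracy on clinical recordings.

## Feature selection

Selection is two-stage and independent of the classifiers.

**Ranking.** Features are scored by the absolute Pearson correlation with
the 0/1 class label and by a classic binary RELIEF pass (deterministic full
sweep; features min-max scaled; nearest hit and miss by Euclidean distance;
constant features score zero). How the two criteria combine into one ranking
is not prescribed anywhere, so the default aggregates by average rank, with
single-criterion modes available; ties break by Pearson rank, then name.
The top `n_keep = 25` features survive, a cutoff chosen to keep the
covariance inversions of the next stage tractable.

**Branch and bound.** The Mahalanobis class-separability criterion
$J(S) = d_S^{\top} \Sigma_S^{-1} d_S$ (class-mean difference $d$, pooled
within-class covariance $\Sigma$) is monotone non-increasing under feature
deletion, so a branch-and-bound search over deletions returns the global
size-$d$ optimum without exhausting all subsets: any node whose criterion
does not exceed the incumbent is pruned with its whole subtree. The search
(RcppArmadillo) seeds the incumbent with greedy backward elimination and
orders children by ascending criterion so large subtrees are pruned first;
a pure-R exhaustive search serves as the test oracle. The candidate subset
dimensions default to 1–6 and the combined scheme fixes 6. With up to 25
features and ~47 training subjects the pooled covariance can be
near-singular, so a ridge of $10^{-8} \times \text{mean diagonal}$ is added
by default (configurable; the criterion itself defaults to ridge 0). The
variant of the search that pre-designates features to discard is
deliberately not implemented.

**RFE.** Recursive feature elimination fits a seeded random forest
(10 trees, fully grown — minimum split size 2 maps to terminal node size
1 — half the features tried per split), ranks by mean impurity decrease and
discards the 5 lowest-ranked features per round (fewer on the last) until
the target dimension remains. The forest, rather than the SVM, drives the
ranking so that no evaluated classifier is favored. Because ensemble
importance is not a subset score, the `criterion_value` stored with an RFE
result is the Mahalanobis criterion of the selected subset, re-evaluable
independently of the ensemble.

## Classifiers and nested evaluation

Three classifiers are evaluated, each with exactly one scanned
hyperparameter: k-NN with $k \in \{1, 3, \ldots, 25\}$ (odd values avoid
voting ties; the printed source range for this grid is corrupted, so the
default is declared a choice, not an inference), ridge-penalized logistic
regression and a linear-kernel SVM with inverse regularization strength
$C \in \{10^{-4}, 10^{-3}, 5 \cdot 10^{-3}, 10^{-2}, 5 \cdot 10^{-2},
10^{-1}\}$ and the same grid without $0.1$ respectively. The logistic model
is fitted with `glmnet` at $\lambda = 1 / (nC)$, matching the
inverse-strength parameterisation; the SVM kernel is fixed to linear.
Features are z-scored with training-fold statistics for all three models
(scale-sensitive distances and penalties; the choice is a package decision).

Evaluation is a nested LOO: the inner loop ranks configurations by
validation accuracy on the training fold, the outer loop tracks the
fold-best configuration and each model's own best, tallies per-model
selection frequencies (summing to the subject count) and aggregates
accuracy, precision and recall — positive class incontinent, since false
negatives carry the clinical cost. Inner ties break deterministically:
highest accuracy, then the simpler model (larger $k$, smaller $C$), then
the fixed order k-NN, logistic, SVM.

Feature selection placement is genuinely open: running the search once on
the full table before the outer loop mirrors a selection "independent of the
classification process" but lets the search see every subject
(`selection_scope = "global"`, optimistically biased — the README flags
this); recomputing ranking, search and standardization inside every outer
fold is leakage-free (`"outer_fold"`, the default). Both are provided rather
than guessing; the calibration tests use the leakage-free scope.

The **combined scheme** runs ranking + branch-and-bound per maneuver at
dimension 6, concatenates the four subsets into a 24-feature table
(maneuver-tagged names stay distinct) and feeds that to the remaining
selection and nested evaluation.

Model comparison uses McNemar's test on the discordant counts with
continuity correction, $(|b - c| - 1)^2 / (b + c)$ against $\chi^2_1$, with
an exact binomial variant for small $b + c$. Top-selected features are
summarized per class with Shapiro–Wilk normality tests, two-sided
Mann–Whitney tests, medians and IQRs; `pca_projection()` gives the
standardized two-component view of class separability.

## Numerical choices and degenerate inputs

* argmax ties take the earliest index; instants map the window onto
  $[0, 1]$ with its first sample at 0.
* Constant features: Pearson score 0, RELIEF weight 0 (span guarded),
  dropped from PCA with a warning.
* Singular pooled covariance at ridge 0 raises an explicit error advising a
  positive ridge.
* Zero metric denominators (e.g. a model that never predicts the positive
  class) report 0 with a warning rather than `NaN`.
* Identical error patterns in McNemar ($b + c = 0$) give statistic 0,
  p = 1 by convention.
* A class with a single member makes the nearest hit undefined; RELIEF
  skips that subject with a warning.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run comfortable on one CPU: the structural and formula oracles run on toy
series and 8–12-feature random instances (50 instances for the
branch-and-bound / exhaustive-search equivalence); the combined-scheme
plumbing runs on a full 48-subject cohort; null calibration averages
outer-LOO accuracy over 20 seeds of 16-subject neutral cohorts with reduced
classifier grids (k ∈ {3, 5}, two C values per linear model) and per-fold
Pearson ranking + branch-and-bound at dimension 3; signal recovery uses a
20-subject cohort with a strong planted amplitude effect
(`amplitude_ratio = 0.4`, noise SD 0.3 kPa). These sizes are the package's
own calibration choices and are deliberately smaller than a clinical study.

## Known limitations

* The generator's separable signal structure is favorable to the
  Mahalanobis criterion; planted-effect recovery rates do not transfer to
  clinical data.
* RELIEF uses a single nearest hit/miss (no k-nearest smoothing); with very
  noisy features its ranking is unstable, which the average-rank default
  mitigates only partly.
* The branch-and-bound optimality guarantee holds for the ridge-adjusted
  criterion actually searched; a large ridge changes the objective.
* `selection_scope = "global"` reproduces a published-style protocol but is
  optimistically biased; conclusions about generalization should rely on
  the `"outer_fold"` scope.
* Logistic regression at very small $C$ approaches an intercept-only model
  whose leave-one-out accuracy on balanced data is pathologically low (the
  held-out subject always belongs to the training minority); the inner
  selection loop weeds such configurations out, but their presence in the
  grid is visible in per-configuration accuracies.

## A complete run

```{r pipeline-example}
cfg <- pipeline_config(
  cohort = cohort_config(n_per_class = 24, seed = 7),
  scheme = "combined", fss = "bb", fss_scope = "outer_fold"
)
res <- run_pipeline(cfg, out_dir = "pfpress-report")

glance(res$reports$combined)
feature_selection_frequency(res$reports$combined)
autoplot(pca_projection(res$features$wave))
```

The report directory carries every table as CSV plus `manifest.json` with
the configuration snapshot, seeds, package version and MD5 hashes of all
outputs; re-running the same manifest reproduces them byte for byte.
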