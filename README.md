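# pfpress

Classification of intravaginal spatiotemporal pressure profiles for
objective assessment of female urinary incontinence.

A non-deformable probe carrying a 10 × 10 matrix of capacitive pressure
sensors records the pressure field of the pelvic floor (50 Hz, 0.42 kPa
resolution, 0.50–100.00 kPa range) while a subject performs four
maneuvers: a 3 s maximal contraction, a 5 s Valsalva push, a 10 s endurance
hold and a 4 s caudal–cranial contraction / cranial–caudal relaxation wave.
`pfpress` is the full analysis chain that turns such recordings into a
continent / incontinent classification, for biomechanics and pelvic-floor
researchers who want a tested, reproducible reference implementation:

* **sensor geometry** — six superset families of sensor groupings
  (quadrants, axial bands, planes = diametrically opposed column pairs,
  rings, quadrant × band intersections, whole matrix) and per-grouping
  peak/sum series $Y^S_{peak}[t] = \max_{s' \in S} S[t]$,
  $Y^S_{sum}[t] = \sum_{s' \in S} S[t]$, after zero-phase 8th-order
  Butterworth low-pass filtering (8 Hz) of every sensor series;
* **feature extraction** — per-maneuver menus of maxima and their
  normalized instants, activation instant (first crossing of
  $\delta$ = baseline mean + 2 × baseline SD), pressure integrals, plateau
  duration ($\ge 0.9 \max$), wave contraction/relaxation rates, and the
  main/first-lower diagonals of the covariance matrix of the twelve
  intersection sum series (198 / 198 / 229 / 177 features for the four
  maneuvers);
* **feature selection** — Pearson + RELIEF ranking to the top 25, then
  either an exact branch-and-bound subset search under the Mahalanobis
  class-separability criterion
  $J(S) = d_S^\top \Sigma_S^{-1} d_S$ (monotone under deletion, so pruning
  preserves global optimality) or recursive feature elimination driven by
  random-forest impurity importance (10 trees, step 5, half the features
  per split);
* **evaluation** — nested leave-one-out model selection over k-NN
  ($k \in \{1, 3, \ldots, 25\}$), ridge-penalized logistic regression and a
  linear SVM (inverse regularization strength $C$), per-model selection
  frequencies, accuracy / precision / recall (positive class:
  incontinent), McNemar paired comparisons with continuity correction,
  top-feature Shapiro–Wilk / Mann–Whitney summaries and 2-component PCA
  projections;
* **synthetic cohorts** — a seeded generator of four-maneuver recordings
  with configurable class effects (amplitude ratio, peak timing shift,
  plateau decay, wave asymmetry, spatial focus shift), used to calibrate
  and test the pipeline end to end since clinical recordings of this kind
  are not publicly deposited.

The combined four-maneuver scheme runs ranking + branch-and-bound per
maneuver at dimension 6 and concatenates the four subsets into a 24-feature
table before the remaining selection and nested evaluation.

Feature selection can run once on the full table (`selection_scope =
"global"`, mirroring protocols where selection is independent of the
classification process — note this lets the search see every subject and is
optimistically biased) or be recomputed inside every outer fold
(`"outer_fold"`, leakage-free, the default).

## Worked example

Simulate a 16-subject cohort, extract wave-maneuver features, and run the
nested leave-one-out evaluation with per-fold ranking + branch-and-bound:

```r
library(pfpress)

cohort   <- generate_cohort(cohort_config(n_per_class = 8, seed = 7))
features <- extract_cohort_features(cohort, build_superset_catalog())

report <- nested_loo_evaluate(
  features$wave,
  default_model_grids(knn_k = c(3, 5), logistic_C = c(0.05, 0.1),
                      svm_C = c(0.01, 0.05)),
  selection = "bb", selection_scope = "outer_fold",
  cfg = selection_config(n_keep = 10, ranking_method = "pearson"),
  subset_dim = 3
)
tidy(report)
#> # A tibble: 4 × 6
#>   model    accuracy precision recall selection_count out_of
#>   <chr>       <dbl>     <dbl>  <dbl>           <int>  <int>
#> 1 best            1         1      1              NA     NA
#> 2 knn             1         1      1              16     16
#> 3 logistic        1         1      1               0     16
#> 4 svm             1         1      1               0     16

head(feature_selection_frequency(report), 3)
#> # A tibble: 3 × 3
#>   feature                                   count out_of
#>   <chr>                                     <int>  <int>
#> 1 wave.rings.ring_01.t_max_p                   11     16
#> 2 wave.s_long_x_s_lat.right_cranial.t_max_p    11     16
#> 3 wave.planes.plane_4.t_max_p                  10     16
```

Every row of `tidy(report)` is one tracked model over the 16 outer folds:
the fold-best configuration (`best`) and each model's own best classify
this strongly separated synthetic cohort perfectly, k-NN wins the inner
model selection in all 16 folds, and the most frequently selected features
are wave-timing instants — the planted class effect delays and skews the
wave. `pairwise_model_tests(report)` adds McNemar comparisons between the
three classifiers, `plot_top_features()` and `autoplot(pca_projection(...))`
the box-plot and PCA views, and `run_pipeline()` wraps
simulate → extract → select → evaluate into one seeded run that writes CSV
tables plus a `manifest.json` with config, seeds and output hashes.

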