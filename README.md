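# finlink

Predictability and imputation of weighted interareal cortical networks from
retrograde tract-tracing data.

## The problem

Retrograde tract-tracing reveals, for each *injected* target area, the
complete set of incoming connection weights — the fraction of labeled
neurons (FLN) found in every source area, spanning roughly 10⁻⁷ to 1. With
T injections on an N-area atlas, the data form a T×N row submatrix
G<sub>T×N</sub> of the full interareal network (FIN) G<sub>N×N</sub>, which
is not available for any mammal. Two questions follow for anyone working
with such connectomes:

1. **How predictable is the network?** If links and their weights can be
   forecast from the observed rows and the interareal distances, the
   network is to that extent rule-based — and the unobserved part can be
   estimated.
2. **Can the missing rows be imputed** to give usable full-network samples
   for comparative connectomics?

finlink implements a link-prediction framework for this setting. Because
no information flows *into* non-injected areas, only out-link information
(the columns of the observed rows) is usable identically for every ordered
pair (u, v); path-based predictors are excluded by construction.

## What is inside

- **Preprocessing** — weights w = 7 + log₁₀(FLN) on a 0–7 scale (0 encodes
  a nonlink), distance features D_f = 31·D/D_max on a 0–31 scale, inclusive
  weight classes (strong w ≥ 5, strong-&-medium w ≥ 3, medium-&-weak
  0 < w ≤ 5, weak 0 < w ≤ 3).
- **Classical predictors** — out-neighbourhood adaptations of common
  neighbours, preferential attachment, Adamic–Adar, resource allocation and
  Jaccard (CN2, PA2, AA2, RA2, JA2), e.g.
  JA2(u,v) = Σ_z min(w(z,u), w(z,v)) / Σ_z max(w(z,u), w(z,v)) over
  injected z.
- **Feature builder** — the eight per-pair feature vectors (adjacency,
  degree-plus-distance, out-distances, FLN profiles, FLN-plus-distance…),
  computed from training rows only, with the pair's own entries masked so
  a training pair never sees its own label.
- **Learners** — KNN, decision tree, random forest, multilayer perceptron,
  gradient boosting, AdaBoost and naive Bayes behind one fit/predict
  contract, as classifiers (probability-like scores) and regressors.
- **Evaluation** — randomized row-wise k-fold cross-validation (folds are
  sets of target areas, never pairs), ROC/AUC with the max-accuracy
  threshold, MAE and relative MAE (RMAE; nonlink denominator w_cut = 0.9),
  per-link and per-region error matrices, error-vs-weight/distance
  profiles, residual diagnostics and leave-one-out scaling curves.
- **Synthetic data** — an exponential-distance-rule (EDR) generator,
  p(l) ∝ e^(−λl) with λ = 1/⟨l⟩ (0.19 mm⁻¹ macaque-like, 0.78 mm⁻¹
  mouse-like), plus degree-preserving configuration-model rewiring as the
  null control.
- **Imputation** — FIN samples trained on all observed rows, with observed
  entries preserved exactly and a provenance mask.

## Worked example

```r
library(finlink)

# a macaque-like EDR study: 40 areas, 20 injected, lambda = 0.19 / mm,
# geometry spanning 58.2 mm, projection count calibrated to 0.66 density
study <- simulate_edr_study("macaque", seed = 7, n_areas = 40, n_injections = 20)
ds <- study$ds
ds
#> <tracing_dataset> 20 injected targets x 40 areas
#>   links: 504  binary density: 0.646
#>   Dmax: 58.2 mm; regions: R2, R3, R4, R1

plan <- make_fold_plan(ds$injected, k = 3, R = 10, seed = 1)
cv <- cross_validate_binary(ds, predictor_config("GB", "classifier", seed = 2),
                            "fln_plus_distance", plan)
cv
#> <cv_binary> GB + fln_plus_distance, k = 3, R = 10
#>   AUC 0.915 +/- 0.006; max-accuracy 0.851 at threshold 0.788
```

An AUC of 0.92 means a randomly chosen true link outranks a randomly
chosen nonlink 92% of the time; at the max-accuracy score threshold, 85%
of all pair-level link/nonlink calls are correct. Weighted prediction with
the same features:

```r
cvw <- cross_validate_weighted(ds, predictor_config("GB", "regressor", seed = 2),
                               "fln_plus_distance", plan)
weighted_error_table(cvw)
#> # A tibble: 7 × 4
#>   group         n_pairs     mae     rmae
#>   <chr>           <int>   <dbl>    <dbl>
#> 1 weak                0 NaN     NaN
#> 2 weak_medium       206   1.60    0.360
#> 3 medium_strong     504   0.788   0.172
#> 4 strong            296   0.226   0.0416
#> 5 all_links         504   0.788   0.172
#> 6 nonlinks          276   1.22    1.36
#> 7 both              780   0.943   0.592
```

RMAE is the fraction of the link weight *not* predicted: strong links lose
only ~4% of their weight to prediction error while weaker classes lose
progressively more — the characteristic predictability gradient of these
networks. (This small synthetic network has no links below w = 3, hence
the empty weak row.) `tidy()`, `glance()` and `autoplot()` expose per-pair
tables, one-row summaries and ROC/profile/heat-map plots;
`error_matrix()`, `error_profiles()`, `residual_diagnostics()`,
`internal_error_scaling()`, `rewire_configuration()` and `impute_fin()`
cover the remaining analyses, and `run_pipeline(run_config(...))` drives
any of them from a single serializable configuration with a manifest.

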