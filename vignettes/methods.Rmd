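---
title: "Link predictability and imputation for interareal cortical networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link predictability and imputation for interareal cortical networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finlink)
```

## The observation model

Retrograde tract-tracing injects a tracer into one *target* area; the
tracer back-labels the cell bodies of every neuron projecting into that
area. The weight of the directed connection from source area *j* into
target *i* is the fraction of labeled neurons (FLN) counted in *j*. One
injection therefore reveals one **complete row** of the full interareal
network (FIN) G~N×N~, and T injections give the row submatrix G~T×N~.
Nothing is ever observed about the in-links of a non-injected area — this
asymmetry shapes the entire framework:

- prediction features may use **out-link information only** (entries of the
  observed rows), because that is the only information available
  identically for every ordered pair (u, v);
- cross-validation must hold out whole **target rows**, never individual
  pairs, or the held-out labels would leak through the shared rows;
- path-based predictors (Katz, PageRank, shortest path) are structurally
  inapplicable: no paths lead into unobserved areas.

## Preprocessing

FLN values span about seven orders of magnitude (~10⁻⁷ to 1), so links
are modelled on the log scale: `w = 7 + log10(FLN)`, mapping links onto a
0–7 range with `w = 0` reserved for nonlinks; zero FLN entries stay
exactly 0. The inverse map `FLN = 10^(w−7)` recovers nonzero entries to
relative error below 10⁻¹². FLN values below 10⁻⁷ would give negative
weights; they are retained unclamped with a warning, because the 0–7 range
is an empirical property of the data rather than an enforced one.

Distances between area barycenters (mm, along estimated obstacle-avoiding
paths) enter features as `D_f = 31 · D / D_max`, spanning 0–31. The fixed
31 endpoint gives the same feature resolution in any species regardless of
brain size; the scaling makes all distance features invariant to the
measurement unit. The weight classes used throughout are inclusive at
their boundaries — strong (w ≥ 5), strong-&-medium (w ≥ 3), medium-&-weak
(0 < w ≤ 5), weak (0 < w ≤ 3) — so a boundary weight belongs to both
adjacent classes by construction.

The nonlink cutoff `w_cut = 0.9` is the weight of the lowest statistically
acceptable FLN value (8 × 10⁻⁷). Relative errors on nonlink pairs divide
by this cutoff rather than by zero. The rounded 0.9 is the default;
`w_cut(unrounded = TRUE)` gives `7 + log10(8e-7)` for sensitivity checks.

## Classical predictors

The five classical scores (CN2, PA2, AA2, RA2, JA2) are out-neighbourhood
adaptations of the standard social-network predictors. With `w(z, x)`
denoting the weight of the out-link x → z (matrix entry `w[z, x]`) and I
the injected training targets:

- CN2(u,v) = ½ Σ~z∈I~ [w(z,u) + w(z,v)]
- PA2(u,v) = (Σ~z∈Γo(u)~ w(z,u) / |Γo(u)|) · (Σ~z∈Γo(v)~ w(z,v) / |Γo(v)|)
- AA2(u,v) = ½ Σ~z∈I~ (w(z,u) + w(z,v)) / log Σ~x∈Γo(z)~ w(x,z)
- RA2(u,v) = Σ~z∈I~ (w(z,u) + w(z,v)) / Σ~x∈Γo(z)~ w(x,z)
- JA2(u,v) = Σ~z∈I~ min(w(z,u), w(z,v)) / Σ~z∈I~ max(w(z,u), w(z,v))

Numerical conventions, chosen where the formulas leave freedom and all
testable via configuration:

- Γo(x) is taken as {z ∈ I : w(z,x) > 0}. The reading in which an area's
  neighbourhood "includes itself" is exposed as `gamma_includes_self`
  (default off): when x is itself an observed target it then contributes a
  zero-weight term to |Γo(x)|. No worked value disambiguates the two
  readings; the switch makes both reachable.
- AA2 skips common-neighbour terms whose observed out-strength is ≤ 1
  (non-positive logarithm), mirroring the degree ≥ 2 convention of
  classical Adamic–Adar and avoiding sign flips. The natural logarithm is
  used; any other base only rescales all scores by a positive constant,
  leaving rankings and hence ROC/AUC unchanged (asserted in the tests).
- A PA2 factor with an empty out-neighbourhood is 0, not NaN: an area with
  no observed out-links carries no preferential-attachment mass.
- JA2 returns 0 when both profiles are empty (0/0).

All five scores are symmetric in (u, v) as defined.

## Features and leakage control

Eight per-pair feature vectors are built from the training rows only,
with per-target blocks interleaved as (f(i,u), f(i,v)) for i ascending in
global atlas order — learners need one fixed layout. For |I| training
targets the lengths are 1 (weighted common neighbours), 3
(degree-plus-distance), |I| (each out-distance profile), 2|I| (adjacency,
FLN, joint out-distance) and 2|I| + 1 (FLN-plus-distance, which appends
the scaled pair distance).

When a training pair (u, v) has its target v among the training rows, the
entry `w[v, u]` is that pair's own label. Feature entries indexed by
either endpoint of the pair are therefore **masked to 0** (weights and
distances alike). The alternative — dropping i ∈ {u, v} from I — would
change the vector length per pair; masking preserves fixed dimensionality.
The out-degree features count strictly positive out-weights into the
training set after the same masking. Two property tests pin this down:
perturbing the would-be label leaves the feature matrix bit-identical, and
perturbing any held-out row leaves the whole training design matrix
bit-identical.

## Learners

Seven engines sit behind one fit/predict contract (`predictor_config()`,
`fit_predictor()`, `predict_pairs()`), each in classifier and regressor
mode (naive Bayes: classifier only). Defaults are the configurations the
framework was characterised with:

| engine | defaults |
|---|---|
| KNN | 5 neighbours |
| RF  | 200 trees, Gini impurity (classification) |
| MLP | one hidden layer of 100 units, tolerance 10⁻⁶, max 20 iterations |
| GB  | 100 boosting stages, depth 7, learning rate 0.1 |
| DT, ADA, NBA | engine defaults |

The MLP iteration cap of 20 is kept although convergence warnings are
expected at that budget; `params` overrides it. Classifier scores are the
positive-class probability where the engine provides one, otherwise a
min–max-scaled decision value — ROC construction needs only a ranking.
Regressor outputs outside 0–7 are kept (clipping would silently alter
learner behaviour) and flagged. DT, ADA and NBA are implemented for
completeness but are not part of headline analyses, which use the four
stronger engines (KNN, MLP, RF, GB). AdaBoost is provided by an
in-package SAMME (classification) and AdaBoost.R2 (regression,
weighted-median aggregation) over `rpart` stumps, since no boosting
engine with reweighting ships in the dependency stack; all other engines
wrap caret/randomForest/xgboost/nnet/rpart/e1071.

## Cross-validation and metrics

`make_fold_plan()` randomizes target order and splits the T targets into k
near-equal folds (sizes differ by at most one), repeated R times; defaults
k = 3, R = 100. Candidate pairs for a fold are all (u, v) with v in the
held-out targets and u any area, u ≠ v. Training uses only training-row
information, for features, classical scores and labels alike.

The ROC is built by sweeping the threshold over the unique score values
(positive ⇔ score ≥ threshold); tied scores collapse to one point so the
trapezoidal area equals the concordant-pair (Mann–Whitney) statistic with
ties counted one half — the tests verify agreement to 10⁻¹². The
max-accuracy threshold maximizes ACC = (TP+TN)/(TP+TN+FP+FN) on each
repetition's ROC and is then averaged; an ROC per repetition, not one
pooled curve, mirrors how the spread (±sd) of AUC is reported. Binary
per-pair errors are |y_true − ⟨y_pred⟩| with ⟨y_pred⟩ the mean of the
threshold-binarized predictions over repetitions.

Weighted prediction uses the same plans with real weights as ground truth.
RMAE = |w_pred − w_true| / w_true is the fraction of the link weight not
predicted; for nonlinks the denominator is w_cut. The class table reports
weak (w_cut < w < 3), weak-&-medium (w_cut < w < 5), medium-&-strong
(w > 3), strong (w > 5), all links, nonlinks, and both combined.
Binary prediction is refused meaning (a `DensityWarning`) when fewer than
5% of candidate pairs are nonlinks — with almost no true negatives to
learn from, classifier scores are uninterpretable; this is the situation
of the mouse data at 97% density, where only weighted prediction is
informative.

Class-restricted analyses come in two modes. `within_class` keeps, as
candidates, the class's links (positives) and all nonlinks (negatives),
excluding out-of-class links from training and scoring; whether the
negatives should also include out-of-class links is not determinable from
the description, so the decomposition mode covers the alternative:
`train_class_predict_all` restricts only training, scores every pair, and
reports AUC decomposed by the true class of the scored pairs.

The leave-one-out scaling analysis draws a random subset ℳ of m targets,
leaves each member out in turn, predicts its out-links restricted to
sources within ℳ from the other m − 1 rows, and averages the internal
RMAE per weight class over members and redraws (default 500 per m). The
"out-links of the excluded area" are read as its row entries — rows are
what injections observe.

Residual diagnostics report the mean residual and the Spearman
correlations of r and |r| with the predicted value; a scatter is declared
featureless when both absolute correlations are below 0.1 (configurable),
the operational criterion for "the signal has been extracted".

## Synthetic data: what it emulates and what it does not

The generator exists so that every stage is testable without any download.
`generate_geometry()` places areas uniformly in a box (2D by default —
cortex is sheet-like at this scale) and rescales so the maximum
barycenter distance matches a stated span; regions are spatial k-means
clusters standing in for lobes. `sample_edr_projections()` drops
projections independently on ordered pairs with probability
∝ e^(−λ·d), the exponential distance rule; row-normalizing the counts
gives FLN values, zero counts are nonlinks. The projection total is
calibrated deterministically (`calibrate_projections()`) from the
expected coverage Σ(1 − e^(−n·p)) so that binary density hits the
species-typical value. The macaque-like study is therefore N = 91,
T = 29, λ = 0.19 mm⁻¹, D~max~ = 58.2 mm, density 0.66; mouse-like is
N = 47, T = 19, λ = 0.78 mm⁻¹, D~max~ = 12 mm, density 0.97. These
constants are the species' published characteristics, not tuning knobs.

`estimate_edr_lambda()` refits λ by maximizing the multinomial
log-likelihood Σ c~ij~(−λd~ij~) − n·log Σ e^(−λd~ij~) (one-dimensional
optimization); with 10⁶ projections it recovers λ well within 5%.
`rewire_configuration()` performs degree-preserving double-edge swaps on
the observed view (weights travel with their link; self-links and
duplicates are rejected; exhausting the attempt budget raises
`RewireStall`) — the null control on which predictability must collapse.
`synthetic_weight_noise()` perturbs log-weights with zero-mean Gaussian
noise, giving a known error floor that an oracle predictor's RMAE must
track monotonically.

What the generator does **not** emulate: real cortical geometry (the
uniform box has a more regular pair-distance distribution than area
barycenters on a folded sheet — binary AUC on the synthetic EDR network
runs a few hundredths above the value measured on the real macaque
distance matrix), lognormal weight dispersion around the distance trend,
hemispheric structure, and the very weakest empirical links (at
density-calibrated projection counts the smallest synthetic FLN values sit
well above 10⁻⁷ unless the projection total is raised). Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
directional reproduction of the published effects, not quantitative
equality with tract-tracing results.

## Imputation

`impute_fin()` trains a regressor on all observed pairs and predicts every
(u, v) whose target was never injected. Observed rows are copied into the
output exactly (bitwise); imputed entries carry both the raw regressor
output and a 0–7-clipped variant, plus an observed/imputed provenance
mask. Imputation is only meaningful when cross-validation shows real
predictability, so a measured binary AUC can be supplied as a gate
(refuse at AUC ≤ 0.55). Weighted imputation is the primary product;
binary imputation thresholds classifier scores at a supplied max-accuracy
threshold. Imputed weak weights are not thresholded to nonlinks — any such
cleanup is left to the user, with the mask making provenance explicit.
Successive samples use successive seeds; across samples, observed entries
have zero spread and stochastic learners give positive spread on imputed
entries.

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed; `run_pipeline()`
expands one global seed into per-stage seeds by a fixed counter scheme and
records them, along with input-file hashes and the engine's actual
hyperparameter defaults, in a JSON manifest, so any run can be reproduced
exactly from its manifest. The packaged test-suite and acceptance-script
runs use deliberately compact problem sizes — synthetic networks of 14–91
areas, cross-validation with R = 2–10 repetitions instead of the
reference R = 100, scaling analyses with a handful of subset redraws —
chosen so the whole suite completes in well under a minute of CV time
while leaving every statistical assertion comfortably clear of its
tolerance; the full-size settings remain the documented defaults.

## Known limitations

- The real macaque/mouse matrices are not redistributable with the
  package; the checks tied to their published summary values run only when
  the user supplies the files, and the EDR predictability level is
  reproduced on a synthetic geometry, slightly above the value reported on
  the real one (see the generator section).
- Sklearn-era "library defaults" for DT/ADA/NBA are not reconstructable;
  the manifest records this package's own engine defaults instead.
- The classifier score for engines without probability outputs is a
  min–max-scaled decision value; rankings (and hence AUC) are unaffected,
  but such scores are not calibrated probabilities.
- `class_restricted_cv()` can leave a repetition without both classes in a
  small weight class; such repetitions are dropped from the AUC spread
  rather than imputed.
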