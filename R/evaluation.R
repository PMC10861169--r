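#' Randomized row-wise fold plan
#'
#' Cross-validation splits the injected target areas (rows of the FLN
#' matrix) -- never individual pairs -- into k near-equal folds, after
#' randomizing target order; the randomization is repeated R times and all
#' performance metrics are averaged over repetitions.
#'
#' @param targets Character vector of injected target areas (or an integer
#'   count, in which case targets are indexed `1..T`).
#' @param k Number of folds, `2 <= k <= T`.
#' @param R Number of randomized repetitions.
#' @param seed Integer seed; the same seed reproduces the plan exactly.
#' @return An object of class `fold_plan`: a tibble with columns `rep`,
#'   `target`, `fold`, plus attributes `k`, `R`, `seed`.
#' @export
#' @examples
#' make_fold_plan(29, k = 3, R = 2, seed = 1)
make_fold_plan <- function(targets, k = 3, R = 100, seed = 1) {
  if (is.numeric(targets) && length(targets) == 1) {
    targets <- as.character(seq_len(targets))
  }
  T_ <- length(targets)
  if (k < 2 || k > T_) {
    stop("BadFoldCount: need 2 <= k <= ", T_, ", got ", k)
  }
  sizes <- rep(T_ %/% k, k)
  if (T_ %% k) sizes[seq_len(T_ %% k)] <- sizes[seq_len(T_ %% k)] + 1
  fold_of <- rep(seq_len(k), times = sizes)
  set.seed(seed)
  plan <- purrr::map_dfr(seq_len(R), function(r) {
    perm <- sample(T_)
    tibble::tibble(rep = r, target = targets[perm], fold = fold_of)
  })
  structure(plan, k = k, R = R, seed = seed, targets = targets,
            class = c("fold_plan", class(plan)))
}

# ---- ROC machinery --------------------------------------------------------

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (a pair is
#' called positive when its score is >= the threshold), yielding one ROC
#' point per unique score plus the (0, 0) endpoint. Tied scores collapse
#' into a single point, so the trapezoidal area equals the concordant-pair
#' (Mann-Whitney) statistic with ties counted one half.
#'
#' @param y_true Binary 0/1 vector.
#' @param score Numeric scores, higher = more link-like.
#' @return A tibble `threshold, tp, fp, tpr, fpr, acc`, threshold
#'   decreasing from `Inf`.
#' @export
roc_curve <- function(y_true, score) {
  stopifnot(length(y_true) == length(score))
  P <- sum(y_true == 1)
  N <- sum(y_true == 0)
  if (P == 0 || N == 0) {
    stop("SingleClassLabels: ROC needs both positives and negatives")
  }
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- y_true[o]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  idx <- which(last_of_group)
  tp <- c(0, cumsum(y == 1)[idx])
  fp <- c(0, cumsum(y == 0)[idx])
  tibble::tibble(
    threshold = c(Inf, s[idx]),
    tp = tp, fp = fp,
    tpr = tp / P, fpr = fp / N,
    acc = (tp + (N - fp)) / (P + N)
  )
}

#' Area under an ROC curve (trapezoidal)
#'
#' @param roc A [roc_curve()] tibble (or `y_true`, `score` vectors).
#' @param score Optional; when given, `roc` is taken as `y_true`.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc, score = NULL) {
  if (!is.null(score)) roc <- roc_curve(roc, score)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Maximum-accuracy threshold of an ROC curve
#'
#' The score cutoff maximizing ACC = (TP + TN) / (TP + TN + FP + FN),
#' determined numerically on the curve; ties resolve to the highest
#' threshold.
#'
#' @param roc A [roc_curve()] tibble.
#' @return A one-row tibble `threshold, acc, tpr, fpr`.
#' @export
max_accuracy_threshold <- function(roc) {
  i <- which.max(roc$acc)
  roc[i, c("threshold", "acc", "tpr", "fpr")]
}

# ---- shared CV engine -----------------------------------------------------

cv_candidate_pairs <- function(areas, test_targets) {
  grid <- tidyr::expand_grid(target = test_targets, source = areas)
  dplyr::filter(grid, .data$target != .data$source)
}

lookup_w <- function(w, pairs) {
  w[cbind(match(pairs$target, rownames(w)), match(pairs$source, colnames(w)))]
}

# pair_keep: optional predicate on true weight, applied to both training and
# test candidate pairs (weight-class restriction); train_keep: applied to
# training pairs only.
run_cv <- function(ds, predictor, features, plan, mode,
                   pair_keep = NULL, train_keep = NULL,
                   gamma_includes_self = FALSE) {
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  areas <- colnames(w)
  injected <- ds$injected
  k <- attr(plan, "k")
  R <- attr(plan, "R")
  classical <- is.character(predictor)
  if (classical) {
    predictor <- match.arg(predictor, CLASSICAL_METHODS)
    if (mode == "weighted") {
      stop("UnknownMethod: classical predictors are binary-only")
    }
  } else {
    stopifnot(inherits(predictor, "predictor_config"))
    want <- if (mode == "binary") "classifier" else "regressor"
    if (predictor$mode != want) {
      stop("UnknownMethod: predictor mode must be '", want, "' for ", mode,
           " cross-validation")
    }
  }

  all_pairs <- cv_candidate_pairs(areas, injected)
  nonlink_frac <- mean(lookup_w(w, all_pairs) == 0)
  if (mode == "binary" && nonlink_frac < 0.05) {
    warning(sprintf(
      "DensityWarning: binary prediction is unreliable at %.0f%% density (under 5%% nonlinks to learn from)",
      100 * (1 - nonlink_frac)))
  }

  gt <- if (mode == "binary") "binary" else "weight"
  preds <- vector("list", R * k)
  slot <- 0L
  for (r in seq_len(R)) {
    rep_plan <- plan[plan$rep == r, ]
    for (f in seq_len(k)) {
      slot <- slot + 1L
      test_targets <- rep_plan$target[rep_plan$fold == f]
      train_targets <- setdiff(injected, test_targets)
      if (length(train_targets) == 0) stop("BadFoldCount: empty training set")
      test_pairs <- cv_candidate_pairs(areas, test_targets)
      if (!is.null(pair_keep)) {
        test_pairs <- test_pairs[pair_keep(lookup_w(w, test_pairs)), ]
      }
      if (nrow(test_pairs) == 0) next
      if (classical) {
        sc <- classical_score_all(predictor, test_pairs,
                                  w[train_targets, , drop = FALSE],
                                  gamma_includes_self)$score
      } else {
        train_pairs <- cv_candidate_pairs(areas, train_targets)
        keep_fn <- pair_keep %||% train_keep
        if (!is.null(keep_fn)) {
          train_pairs <- train_pairs[keep_fn(lookup_w(w, train_pairs)), ]
        }
        dm_train <- build_design_matrix(features, train_pairs, w, dfeat,
                                        train_targets, ground_truth = gt)
        if (mode == "binary" && length(unique(dm_train$y)) < 2) {
          stop("SingleClassLabels: training fold has a single class")
        }
        cfg <- predictor
        cfg$seed <- predictor$seed + (r - 1L) * k + (f - 1L)
        handle <- fit_predictor(cfg, dm_train)
        dm_test <- build_design_matrix(features, test_pairs, w, dfeat,
                                       train_targets, ground_truth = "none")
        sc <- predict_pairs(handle, dm_test)
      }
      preds[[slot]] <- dplyr::mutate(test_pairs, rep = r, fold = f,
                                     pred = as.numeric(sc))
    }
  }
  preds <- dplyr::bind_rows(preds)
  preds$w_true <- lookup_w(w, preds)
  preds$y_true <- as.numeric(preds$w_true > 0)
  list(preds = preds, w = w, dfeat = dfeat, plan = plan,
       predictor = predictor, features = if (classical) NULL else features,
       mode = mode)
}

finish_binary <- function(run, ds) {
  preds <- run$preds
  rep_metrics <- preds |>
    dplyr::group_by(.data$rep) |>
    dplyr::group_modify(function(d, g) {
      roc <- roc_curve(d$y_true, d$pred)
      best <- max_accuracy_threshold(roc)
      tibble::tibble(auc = auc_trapezoid(roc),
                     threshold = best$threshold, acc = best$acc)
    }) |>
    dplyr::ungroup()
  thr <- setNames(rep_metrics$threshold, rep_metrics$rep)
  preds$y_pred <- as.numeric(preds$pred >= thr[as.character(preds$rep)])
  pair_summary <- preds |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      y_true = .data$y_true[1], w_true = .data$w_true[1],
      score_mean = mean(.data$pred), y_pred_mean = mean(.data$y_pred),
      n_rep = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(error = abs(.data$y_true - .data$y_pred_mean))
  didx <- cbind(match(pair_summary$target, rownames(ds$dist)),
                match(pair_summary$source, colnames(ds$dist)))
  pair_summary$dist_mm <- ds$dist[didx]
  roc_pooled <- roc_curve(preds$y_true, preds$pred)
  structure(
    list(pairs = pair_summary, rep_metrics = rep_metrics,
         roc = roc_pooled,
         auc = mean(rep_metrics$auc), auc_sd = sd(rep_metrics$auc),
         acc = mean(rep_metrics$acc),
         threshold = mean(rep_metrics$threshold[is.finite(rep_metrics$threshold)]),
         predictor = run$predictor, features = run$features,
         plan = run$plan, raw = run$preds),
    class = "cv_binary"
  )
}

finish_weighted <- function(run, ds, w_cut_value) {
  preds <- run$preds
  rep_metrics <- preds |>
    dplyr::group_by(.data$rep) |>
    dplyr::summarise(mae = mean(abs(.data$pred - .data$w_true)),
                     .groups = "drop")
  pair_summary <- preds |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      w_true = .data$w_true[1],
      w_pred_mean = mean(.data$pred),
      mae = mean(abs(.data$pred - .data$w_true)),
      n_rep = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      denom = ifelse(.data$w_true > 0, .data$w_true, w_cut_value),
      rmae = .data$mae / .data$denom
    )
  didx <- cbind(match(pair_summary$target, rownames(ds$dist)),
                match(pair_summary$source, colnames(ds$dist)))
  pair_summary$dist_mm <- ds$dist[didx]
  structure(
    list(pairs = pair_summary, rep_metrics = rep_metrics,
         mae = mean(rep_metrics$mae), w_cut = w_cut_value,
         predictor = run$predictor, features = run$features,
         plan = run$plan, raw = run$preds),
    class = "cv_weighted"
  )
}

#' Binary link-prediction cross-validation
#'
#' Runs randomized row-wise k-fold cross-validation of a binary link
#' predictor over a tracing dataset: in each fold, models see only the
#' training targets' rows (features, classical scores and labels alike) and
#' score every ordered pair into the held-out targets. Per repetition, an
#' ROC curve is built from the pooled fold scores, the AUC and the
#' maximum-accuracy threshold are recorded, and scores are binarized at that
#' threshold; pair-level predictions are averaged over repetitions.
#'
#' @param ds A [tracing_dataset()].
#' @param predictor A [predictor_config()] in classifier mode, or a
#'   classical method name (`"CN2"`, `"PA2"`, `"AA2"`, `"RA2"`, `"JA2"`).
#' @param features Feature spec for ML predictors (default
#'   `"fln_plus_distance"`); ignored for classical methods.
#' @param plan A [make_fold_plan()] over `ds$injected`.
#' @param gamma_includes_self Passed to [classical_score_all()].
#' @return An object of class `cv_binary` with elements `pairs` (per-pair
#'   tibble: truth, mean score, mean binarized prediction, error), `rep_metrics`,
#'   pooled `roc`, `auc`, `auc_sd`, `acc`, `threshold`.
#' @export
cross_validate_binary <- function(ds, predictor = predictor_config("GB"),
                                  features = "fln_plus_distance",
                                  plan = make_fold_plan(ds$injected),
                                  gamma_includes_self = FALSE) {
  run <- run_cv(ds, predictor, features, plan, "binary",
                gamma_includes_self = gamma_includes_self)
  finish_binary(run, ds)
}

#' Weighted link-prediction cross-validation
#'
#' Same row-wise scheme as [cross_validate_binary()] but the ground truth is
#' the actual link weight on the 0--7 scale and the engine is a regressor.
#' Errors are summarised as MAE and relative MAE (RMAE = MAE / w_true); for
#' nonlink pairs the RMAE denominator is the nonlink cutoff weight
#' [w_cut()].
#'
#' @inheritParams cross_validate_binary
#' @param predictor A [predictor_config()] in regressor mode.
#' @param w_cut_value RMAE denominator for nonlinks; defaults to the
#'   rounded 0.9, switchable to the unrounded `7 + log10(8e-7)`.
#' @return An object of class `cv_weighted` with per-pair `pairs` tibble
#'   (`w_pred_mean`, `mae`, `rmae`), `rep_metrics` and overall `mae`; see
#'   [weighted_error_table()] for the class-resolved summary.
#' @export
cross_validate_weighted <- function(ds,
                                    predictor = predictor_config("GB", "regressor"),
                                    features = "fln_plus_distance",
                                    plan = make_fold_plan(ds$injected),
                                    w_cut_value = w_cut()) {
  run <- run_cv(ds, predictor, features, plan, "weighted")
  finish_weighted(run, ds, w_cut_value)
}

#' Class-resolved weighted error table
#'
#' Summarises a weighted cross-validation by link-weight group: weak
#' (w_cut < w < 3), weak-&-medium (w_cut < w < 5), medium-&-strong (w > 3),
#' strong (w > 5), all links (w > w_cut), nonlinks (w <= w_cut), and both
#' combined. Groups overlap by construction.
#'
#' @param cv A `cv_weighted` object.
#' @return A tibble `group, n_pairs, mae, rmae`.
#' @export
weighted_error_table <- function(cv) {
  stopifnot(inherits(cv, "cv_weighted"))
  p <- cv$pairs
  wc <- cv$w_cut
  groups <- list(
    weak = p$w_true > wc & p$w_true < 3,
    weak_medium = p$w_true > wc & p$w_true < 5,
    medium_strong = p$w_true > 3,
    strong = p$w_true > 5,
    all_links = p$w_true > wc,
    nonlinks = p$w_true <= wc,
    both = rep(TRUE, nrow(p))
  )
  purrr::imap_dfr(groups, function(sel, nm) {
    tibble::tibble(group = nm, n_pairs = sum(sel),
                   mae = mean(p$mae[sel]), rmae = mean(p$rmae[sel]))
  })
}

#' Weight-class-restricted binary predictability
#'
#' Measures binary predictability inside one weight class. In
#' `within_class` mode, candidate positives are the class's links and
#' candidate negatives are nonlinks; links outside the class are excluded
#' from both training labels and scoring. In `train_class_predict_all`
#' mode, training is restricted the same way but every pair in the test
#' folds is scored, and per-class AUCs are reported by decomposing the
#' predictions by ground-truth weight class.
#'
#' @inheritParams cross_validate_binary
#' @param class One of `"strong"` (w >= 5), `"strong_medium"` (w >= 3),
#'   `"medium_weak"` (0 < w <= 5), `"weak"` (0 < w <= 3).
#' @param mode `"within_class"` or `"train_class_predict_all"`.
#' @return A `cv_binary` object; in decomposition mode it carries an extra
#'   `class_auc` tibble (`class, auc, auc_sd`).
#' @export
class_restricted_cv <- function(ds, class, predictor = predictor_config("GB"),
                                features = "fln_plus_distance",
                                plan = make_fold_plan(ds$injected),
                                mode = c("within_class",
                                         "train_class_predict_all"),
                                gamma_includes_self = FALSE) {
  class <- match.arg(class, WEIGHT_CLASSES)
  mode <- match.arg(mode)
  in_class <- function(wv) assign_weight_classes(wv)[[class]]
  keep <- function(wv) wv == 0 | in_class(wv)
  w <- transform_weights(ds)
  all_pairs <- cv_candidate_pairs(colnames(w), ds$injected)
  wv <- lookup_w(w, all_pairs)
  if (!any(in_class(wv))) stop("EmptyClass: no links with class '", class, "'")
  if (!any(wv == 0)) {
    stop("SingleClassLabels: restriction leaves no negatives")
  }
  if (mode == "within_class") {
    run <- run_cv(ds, predictor, features, plan, "binary", pair_keep = keep,
                  gamma_includes_self = gamma_includes_self)
    finish_binary(run, ds)
  } else {
    run <- run_cv(ds, predictor, features, plan, "binary",
                  train_keep = keep,
                  gamma_includes_self = gamma_includes_self)
    out <- finish_binary(run, ds)
    preds <- run$preds
    out$class_auc <- purrr::map_dfr(WEIGHT_CLASSES, function(cl) {
      sel <- preds$w_true == 0 | assign_weight_classes(preds$w_true)[[cl]]
      d <- preds[sel, ]
      per_rep <- d |>
        dplyr::group_by(.data$rep) |>
        dplyr::summarise(auc = tryCatch(
          auc_trapezoid(.data$y_true, .data$pred),
          error = function(e) NA_real_), .groups = "drop")
      per_rep <- dplyr::filter(per_rep, !is.na(.data$auc))
      tibble::tibble(class = cl, auc = mean(per_rep$auc),
                     auc_sd = sd(per_rep$auc))
    })
    out
  }
}

# ---- error localisation ---------------------------------------------------

#' Per-link and regional prediction-error matrices
#'
#' Lays pair-level errors out as a (target x source) matrix aligned to the
#' observed FLN rows, and averages them within region-pair blocks (cortical
#' lobes), excluding diagonal self cells.
#'
#' @param cv A `cv_binary` or `cv_weighted` object.
#' @param ds The [tracing_dataset()] the CV was run on.
#' @param value Error column to use; defaults to `error` (binary) or
#'   `rmae` (weighted).
#' @return An object of class `error_matrix`: list with `link_matrix`
#'   (T x N), `regional` (region x region matrix) and `regional_table`
#'   (long tibble).
#' @export
error_matrix <- function(cv, ds, value = NULL) {
  value <- value %||% if (inherits(cv, "cv_weighted")) "rmae" else "error"
  p <- cv$pairs
  stopifnot(value %in% names(p))
  targets <- ds$injected
  areas <- ds$atlas$area
  m <- matrix(NA_real_, length(targets), length(areas),
              dimnames = list(targets, areas))
  m[cbind(match(p$target, targets), match(p$source, areas))] <- p[[value]]
  region_of <- setNames(as.character(ds$atlas$region), areas)
  miss <- unique(c(p$target, p$source))[!unique(c(p$target, p$source)) %in% areas]
  if (length(miss)) stop("MissingRegion: ", paste(miss, collapse = ", "))
  tab <- p |>
    dplyr::mutate(region_target = region_of[.data$target],
                  region_source = region_of[.data$source]) |>
    dplyr::group_by(.data$region_target, .data$region_source) |>
    dplyr::summarise(error = mean(.data[[value]]), n = dplyr::n(),
                     .groups = "drop")
  regions <- sort(unique(region_of))
  reg <- matrix(NA_real_, length(regions), length(regions),
                dimnames = list(regions, regions))
  reg[cbind(match(tab$region_target, regions),
            match(tab$region_source, regions))] <- tab$error
  structure(list(link_matrix = m, regional = reg, regional_table = tab,
                 value = value),
            class = "error_matrix")
}

#' Prediction-error profiles along weight or distance
#'
#' Running mean and standard deviation of pair-level errors over a fixed
#' equal-width binning of link weight or projection distance; bins holding
#' fewer than 3 pairs are flagged.
#'
#' @param cv A `cv_binary` or `cv_weighted` object.
#' @param against `"weight"` or `"distance"`.
#' @param bins Number of equal-width bins over the observed range.
#' @param links_only Drop nonlink pairs first; defaults to `TRUE` for
#'   weighted results, `FALSE` for binary.
#' @param value Error column (as in [error_matrix()]).
#' @return A tibble `bin, x_mid, mean, sd, n, flagged`.
#' @export
error_profiles <- function(cv, against = c("weight", "distance"), bins = 20,
                           links_only = inherits(cv, "cv_weighted"),
                           value = NULL) {
  against <- match.arg(against)
  value <- value %||% if (inherits(cv, "cv_weighted")) "rmae" else "error"
  p <- cv$pairs
  if (links_only) p <- dplyr::filter(p, .data$w_true > 0)
  x <- if (against == "weight") p$w_true else p$dist_mm
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), bins)
  tibble::tibble(bin = bin, x = x, err = p[[value]]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$err),
                     sd = if (dplyr::n() > 1) sd(.data$err) else NA_real_,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(x_mid = (edges[.data$bin] + edges[.data$bin + 1]) / 2,
                  flagged = .data$n < 3) |>
    dplyr::select("bin", "x_mid", "mean", "sd", "n", "flagged")
}

#' Residual diagnostics for weighted predictions
#'
#' Residuals r = w_pred - w_true per pair, with rank correlations of r and
#' |r| against the predicted value. A scatter with no such structure
#' ("featureless") indicates the predictor has extracted the signal; it is
#' declared when both |rank correlations| fall below `tol`.
#'
#' @param cv A `cv_weighted` object.
#' @param tol Featurelessness threshold on the absolute rank correlations.
#' @return A list with `residuals` (tibble), `mean_residual`,
#'   `cor_residual`, `cor_abs_residual` (Spearman, vs predicted) and
#'   `featureless`.
#' @export
residual_diagnostics <- function(cv, tol = 0.1) {
  stopifnot(inherits(cv, "cv_weighted"))
  p <- cv$pairs
  r <- p$w_pred_mean - p$w_true
  cor_r <- if (sd(r) == 0 || sd(p$w_pred_mean) == 0) 0 else
    cor(r, p$w_pred_mean, method = "spearman")
  cor_abs <- if (sd(abs(r)) == 0 || sd(p$w_pred_mean) == 0) 0 else
    cor(abs(r), p$w_pred_mean, method = "spearman")
  list(
    residuals = tibble::tibble(source = p$source, target = p$target,
                               w_pred = p$w_pred_mean, w_true = p$w_true,
                               residual = r),
    mean_residual = mean(r),
    cor_residual = cor_r,
    cor_abs_residual = cor_abs,
    featureless = abs(cor_r) < tol && abs(cor_abs) < tol
  )
}

#' Scaling of internal prediction error with training-set size
#'
#' Leave-one-out analysis over random target subsets: draw a subset of m
#' injected targets, leave each member out in turn, predict its out-links
#' restricted to source areas within the subset from the remaining m - 1
#' rows, and compute the relative errors (internal to the subset). The
#' random subset draw is repeated `n_rep` times per m and errors averaged,
#' split by link-weight group.
#'
#' @param ds A [tracing_dataset()].
#' @param m_values Integer vector of subset sizes, each in `2..T`.
#' @param n_rep Number of random subsets per m.
#' @param predictor A regressor [predictor_config()].
#' @param features Feature spec.
#' @param seed Integer seed.
#' @param w_cut_value Nonlink RMAE denominator.
#' @return A tibble `m, group, rmae, n_pairs` (groups as in
#'   [weighted_error_table()]).
#' @export
internal_error_scaling <- function(ds, m_values, n_rep = 500,
                                   predictor = predictor_config("GB", "regressor"),
                                   features = "fln_plus_distance",
                                   seed = 1, w_cut_value = w_cut()) {
  T_ <- length(ds$injected)
  if (any(m_values < 2 | m_values > T_)) {
    stop("BadSubsetSize: m must lie in 2..", T_)
  }
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  set.seed(seed)
  fit_counter <- 0L
  purrr::map_dfr(m_values, function(m) {
    errs <- purrr::map_dfr(seq_len(n_rep), function(rr) {
      M <- sample(ds$injected, m)
      purrr::map_dfr(M, function(t_out) {
        I_tr <- setdiff(M, t_out)
        train_pairs <- cv_candidate_pairs(M, I_tr)
        test_pairs <- cv_candidate_pairs(M, t_out)
        if (nrow(test_pairs) == 0) return(NULL)
        dm_tr <- build_design_matrix(features, train_pairs, w, dfeat, I_tr,
                                     ground_truth = "weight")
        cfg <- predictor
        fit_counter <<- fit_counter + 1L
        cfg$seed <- predictor$seed + fit_counter
        handle <- fit_predictor(cfg, dm_tr)
        dm_te <- build_design_matrix(features, test_pairs, w, dfeat, I_tr,
                                     ground_truth = "none")
        pred <- predict_pairs(handle, dm_te)
        w_true <- lookup_w(w, test_pairs)
        tibble::tibble(w_true = w_true,
                       ae = abs(pred - w_true),
                       rmae = abs(pred - w_true) /
                         ifelse(w_true > 0, w_true, w_cut_value))
      })
    })
    groups <- list(
      weak = errs$w_true > w_cut_value & errs$w_true < 3,
      weak_medium = errs$w_true > w_cut_value & errs$w_true < 5,
      medium_strong = errs$w_true > 3,
      strong = errs$w_true > 5,
      all_links = errs$w_true > w_cut_value,
      nonlinks = errs$w_true <= w_cut_value
    )
    purrr::imap_dfr(groups, function(sel, nm) {
      tibble::tibble(m = m, group = nm, rmae = mean(errs$rmae[sel]),
                     n_pairs = sum(sel))
    })
  })
}

#' @export
print.cv_binary <- function(x, ...) {
  cat("<cv_binary> ",
      if (is.character(x$predictor)) x$predictor else
        paste0(x$predictor$algorithm, " + ", x$features),
      ", k = ", attr(x$plan, "k"), ", R = ", attr(x$plan, "R"), "\n",
      sprintf("  AUC %.3f +/- %.3f; max-accuracy %.3f at threshold %.3f\n",
              x$auc, x$auc_sd, x$acc, x$threshold), sep = "")
  invisible(x)
}

#' @export
print.cv_weighted <- function(x, ...) {
  tab <- weighted_error_table(x)
  cat("<cv_weighted> ", x$predictor$algorithm, " + ", x$features,
      ", k = ", attr(x$plan, "k"), ", R = ", attr(x$plan, "R"), "\n", sep = "")
  cat(sprintf("  all-links RMAE %.3f; nonlinks %.3f; overall MAE %.3f\n",
              tab$rmae[tab$group == "all_links"],
              tab$rmae[tab$group == "nonlinks"], x$mae))
  invisible(x)
}
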