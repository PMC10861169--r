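test_that("fold plans are balanced, exhaustive and reproducible", {
  plan <- make_fold_plan(29, k = 3, R = 4, seed = 9)
  sizes <- plan |>
    dplyr::count(rep, fold) |>
    dplyr::pull(n)
  expect_true(all(sort(unique(sizes)) %in% c(9, 10)))
  per_rep <- split(plan, plan$rep)
  for (p in per_rep) {
    expect_setequal(p$target, as.character(1:29))
    expect_equal(sort(as.integer(table(p$fold))), c(9L, 10L, 10L))
  }
  expect_identical(make_fold_plan(29, 3, 4, seed = 9)$fold, plan$fold)
  expect_identical(make_fold_plan(29, 3, 4, seed = 9)$target, plan$target)
  expect_false(identical(make_fold_plan(29, 3, 4, seed = 10)$target,
                         plan$target))
  expect_error(make_fold_plan(29, k = 1), "BadFoldCount")
  expect_error(make_fold_plan(5, k = 6), "BadFoldCount")
})

test_that("ROC construction matches hand and concordant-pair oracles", {
  # hand case: labels (1,0,1,0), scores (.9,.8,.7,.1) -> AUC = 0.75
  expect_equal(auc_trapezoid(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  roc <- roc_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  # random small instances with heavy ties: trapezoid == Mann-Whitney
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:15, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(auc_trapezoid(y, s), auc_mann_whitney(y, s),
                 tolerance = 1e-12)
  }
})

test_that("AUC hits its analytic anchors", {
  set.seed(23)
  y <- rbinom(400, 1, 0.4)
  expect_identical(auc_trapezoid(y, y), 1) # truth as score
  # permutation null: 0.5 within Mann-Whitney sampling error
  aucs <- replicate(50, auc_trapezoid(y, sample(y)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  # invariance under strictly monotone transforms of the scores
  s <- runif(400)
  expect_equal(auc_trapezoid(y, s), auc_trapezoid(y, exp(3 * s) - 1))
  expect_equal(auc_trapezoid(y, s), auc_trapezoid(y, rank(s)))
  expect_error(roc_curve(rep(1, 5), runif(5)), "SingleClassLabels")
})

test_that("the max-accuracy point dominates both ROC endpoints", {
  set.seed(25)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- runif(60) + 0.3 * y
    roc <- roc_curve(y, s)
    best <- max_accuracy_threshold(roc)
    expect_gte(best$acc, roc$acc[1])
    expect_gte(best$acc, roc$acc[nrow(roc)])
  }
})

test_that("row-wise CV covers every candidate pair once per repetition", {
  study <- small_edr_study(seed = 2, n_areas = 18, n_injections = 9)
  ds <- study$ds
  plan <- make_fold_plan(ds$injected, k = 3, R = 2, seed = 4)
  cv <- cross_validate_binary(ds, "JA2", plan = plan)
  counts <- cv$raw |>
    dplyr::count(source, target)
  expect_true(all(counts$n == 2)) # once per repetition
  expect_equal(nrow(counts), length(ds$injected) * (ncol(ds$fln) - 1))
  expect_false(any(counts$source == counts$target))
  expect_true(all(cv$pairs$n_rep == 2))
  expect_true(all(cv$pairs$error >= 0 & cv$pairs$error <= 1))
})

test_that("CV results are reproducible from the plan seed and predictor seed", {
  study <- small_edr_study(seed = 3, n_areas = 16, n_injections = 8)
  ds <- study$ds
  plan <- make_fold_plan(ds$injected, k = 2, R = 2, seed = 7)
  cfg <- predictor_config("RF", "classifier",
                          params = list(n_estimators = 20L), seed = 5)
  cv1 <- cross_validate_binary(ds, cfg, "degree_plus_distance", plan)
  cv2 <- cross_validate_binary(ds, cfg, "degree_plus_distance", plan)
  expect_identical(cv1$raw$pred, cv2$raw$pred)
  expect_equal(cv1$auc, cv2$auc)
})

test_that("ultra-dense data triggers the density warning", {
  study <- list(ds = simulate_edr_study("mouse", seed = 4, n_areas = 16,
                                        n_injections = 8)$ds)
  expect_warning(
    cross_validate_binary(study$ds, "JA2",
                          plan = make_fold_plan(study$ds$injected, 2, 1, 1)),
    "DensityWarning")
})

test_that("weighted CV errors are coherent with the class table", {
  study <- small_edr_study(seed = 5, n_areas = 20, n_injections = 10)
  ds <- study$ds
  plan <- make_fold_plan(ds$injected, k = 2, R = 2, seed = 3)
  cv <- cross_validate_weighted(
    ds, predictor_config("KNN", "regressor", seed = 2),
    "fln_plus_distance", plan)
  tab <- weighted_error_table(cv)
  expect_true(all(tab$rmae[!is.nan(tab$rmae)] >= 0))
  classes <- tab$rmae[tab$group %in% c("weak", "weak_medium",
                                       "medium_strong", "strong")]
  classes <- classes[!is.nan(classes)]
  all_links <- tab$rmae[tab$group == "all_links"]
  expect_gte(all_links, min(classes) - 1e-12)
  expect_lte(all_links, max(classes) + 1e-12)
  # nonlink denominators use the cutoff weight
  nl <- cv$pairs[cv$pairs$w_true == 0, ]
  expect_equal(nl$rmae, nl$mae / w_cut())
})

test_that("class-restricted CV scores only in-class links against nonlinks", {
  study <- small_edr_study(seed = 6, n_areas = 20, n_injections = 10)
  ds <- study$ds
  plan <- make_fold_plan(ds$injected, k = 2, R = 2, seed = 8)
  cv <- class_restricted_cv(ds, "strong_medium", "JA2", plan = plan)
  w <- transform_weights(ds)
  scored_w <- cv$raw$w_true
  expect_true(all(scored_w == 0 | scored_w >= 3))
  # decomposition mode scores everything but reports per-class AUCs
  cv2 <- class_restricted_cv(
    ds, "strong_medium",
    predictor_config("KNN", "classifier", seed = 2),
    "degree_plus_distance", plan, mode = "train_class_predict_all")
  expect_true(all(c("class", "auc") %in% names(cv2$class_auc)))
  expect_equal(nrow(cv2$class_auc), 4)
  expect_error(class_restricted_cv(ds, "bogus", "JA2", plan = plan))
})

test_that("error matrices localise errors by link and by region", {
  ds <- toy_dataset()
  pairs <- pair_table(ds) |>
    dplyr::transmute(source, target, y_true = as.numeric(link),
                     w_true = w,
                     y_pred_mean = ifelse(link, 0.2, 0),
                     error = abs(y_true - y_pred_mean))
  em <- error_matrix(fake_cv_binary(pairs), ds)
  expect_equal(dim(em$link_matrix), c(5, 8))
  i <- which(pairs$y_true == 1)[1]
  expect_equal(em$link_matrix[pairs$target[i], pairs$source[i]], 0.8)
  expect_true(all(is.na(diag(em$link_matrix[, ds$injected][ds$injected, ]))))
  # constant predictions give a constant regional matrix
  pairs2 <- dplyr::mutate(pairs, error = 0.37)
  em2 <- error_matrix(fake_cv_binary(pairs2), ds)
  vals <- em2$regional[!is.na(em2$regional)]
  expect_true(all(abs(vals - 0.37) < 1e-12))
})

test_that("error profiles are flat at zero error and flag sparse bins", {
  ds <- toy_dataset()
  pairs <- pair_table(ds) |>
    dplyr::transmute(source, target, w_true = w, dist_mm,
                     error = 0, rmae = 0, y_true = as.numeric(link))
  prof <- error_profiles(fake_cv_binary(pairs), "weight", bins = 5,
                         links_only = FALSE, value = "error")
  expect_true(all(prof$mean == 0))
  expect_true(all(prof$flagged == (prof$n < 3)))
  prof_d <- error_profiles(fake_cv_binary(pairs), "distance", bins = 5,
                           links_only = FALSE, value = "error")
  expect_true(all(prof_d$mean == 0))
})

test_that("residual diagnostics detect bias and heteroscedastic structure", {
  ds <- toy_dataset()
  base <- pair_table(ds) |>
    dplyr::filter(link) |>
    dplyr::transmute(source, target, w_true = w)
  exact <- dplyr::mutate(base, w_pred_mean = w_true)
  d0 <- residual_diagnostics(fake_cv_weighted(exact))
  expect_equal(d0$mean_residual, 0)
  expect_true(d0$featureless)
  biased <- dplyr::mutate(base, w_pred_mean = w_true + 0.5)
  db <- residual_diagnostics(fake_cv_weighted(biased))
  expect_equal(db$mean_residual, 0.5)
  set.seed(31)
  n <- nrow(base)
  hetero <- dplyr::mutate(base,
                          w_pred_mean = w_true + rnorm(n, 0, 0.02 + 0.4 * w_true))
  dh <- residual_diagnostics(fake_cv_weighted(hetero))
  expect_false(dh$featureless)
})

test_that("internal error scaling is reproducible and exact at m = T", {
  study <- small_edr_study(seed = 7, n_areas = 14, n_injections = 7)
  ds <- study$ds
  cfg <- predictor_config("KNN", "regressor", seed = 2)
  sc1 <- internal_error_scaling(ds, m_values = c(4, 7), n_rep = 2,
                                predictor = cfg,
                                features = "degree_plus_distance", seed = 11)
  sc2 <- internal_error_scaling(ds, m_values = c(4, 7), n_rep = 2,
                                predictor = cfg,
                                features = "degree_plus_distance", seed = 11)
  expect_identical(sc1, sc2)
  expect_setequal(unique(sc1$m), c(4, 7))
  # m = T with one repetition is plain leave-one-out over all targets
  loo <- internal_error_scaling(ds, m_values = 7, n_rep = 1, predictor = cfg,
                                features = "degree_plus_distance", seed = 1)
  expect_true(all(loo$rmae[loo$group == "all_links"] >= 0))
  expect_error(internal_error_scaling(ds, m_values = 1, n_rep = 1),
               "BadSubsetSize")
})
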