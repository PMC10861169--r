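#' Impute the full interareal network (FIN)
#'
#' Trains a weighted regressor on every observed pair (all T injected rows)
#' and predicts the weight of every ordered pair (u, v) whose target v was
#' never injected, producing N x N samples of the full interareal network.
#' Observed rows are preserved exactly; imputed entries are reported both
#' raw and clipped to the 0--7 weight range. Imputation is only meaningful
#' when cross-validation indicates real predictability, so a gate can be
#' supplied: a measured binary AUC at or below `min_auc` refuses to impute.
#'
#' @param ds A [tracing_dataset()].
#' @param predictor A regressor [predictor_config()] (binary imputation uses
#'   a classifier config plus `threshold`).
#' @param features Feature spec.
#' @param n_samples Number of FIN samples (successive seeds).
#' @param seed Base integer seed; sample s uses `seed + s - 1`.
#' @param predictability_auc Optional binary CV AUC measured beforehand
#'   (e.g. `cross_validate_binary(ds, ...)$auc`); checked against `min_auc`.
#' @param min_auc Gate level (default 0.55).
#' @param threshold For a classifier config: score cutoff (typically the
#'   max-accuracy threshold from a CV run) used to binarize imputed links.
#' @return A list of `fin_sample` objects, each with `w` (N x N, raw),
#'   `w_clipped`, `mask` ("observed"/"imputed"/"diagonal"), `seed`.
#' @export
impute_fin <- function(ds, predictor = predictor_config("GB", "regressor"),
                       features = "fln_plus_distance", n_samples = 1,
                       seed = 1, predictability_auc = NULL, min_auc = 0.55,
                       threshold = NULL) {
  if (!is.null(predictability_auc) && predictability_auc <= min_auc) {
    stop("PredictabilityGateFailed: binary AUC ", round(predictability_auc, 3),
         " <= ", min_auc, "; imputation is not meaningful")
  }
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  areas <- ds$atlas$area
  injected <- ds$injected
  hidden <- setdiff(areas, injected)
  gt <- if (predictor$mode == "classifier") "binary" else "weight"
  train_pairs <- cv_candidate_pairs(areas, injected)
  dm_train <- build_design_matrix(features, train_pairs, w, dfeat, injected,
                                  ground_truth = gt)
  test_pairs <- cv_candidate_pairs(areas, hidden)
  dm_test <- if (nrow(test_pairs)) {
    build_design_matrix(features, test_pairs, w, dfeat, injected,
                        ground_truth = "none")
  } else NULL

  mask <- matrix("imputed", length(areas), length(areas),
                 dimnames = list(areas, areas))
  mask[injected, ] <- "observed"
  diag(mask) <- "diagonal"

  purrr::map(seq_len(n_samples), function(s) {
    cfg <- predictor
    cfg$seed <- seed + s - 1L
    handle <- fit_predictor(cfg, dm_train)
    fin <- matrix(0, length(areas), length(areas),
                  dimnames = list(areas, areas))
    fin[injected, ] <- w[injected, areas]
    if (!is.null(dm_test)) {
      pred <- predict_pairs(handle, dm_test)
      if (predictor$mode == "classifier") {
        if (is.null(threshold)) {
          stop("UnknownMethod: binary imputation needs a `threshold`")
        }
        pred <- as.numeric(pred >= threshold)
      }
      fin[cbind(match(test_pairs$target, areas),
                match(test_pairs$source, areas))] <- pred
    }
    diag(fin) <- 0
    structure(list(w = fin, w_clipped = pmin(pmax(fin, 0), 7),
                   mask = mask, seed = cfg$seed, features = features,
                   predictor = cfg),
              class = "fin_sample")
  })
}

#' Summarise FIN samples entrywise
#'
#' @param samples A list of `fin_sample` objects from [impute_fin()].
#' @return A list with `mean` and `sd` matrices, the shared `mask`, and a
#'   long `table` tibble (`target, source, mean, sd, status`).
#' @export
summarize_fin_samples <- function(samples) {
  stopifnot(length(samples) >= 1)
  arr <- simplify2array(lapply(samples, `[[`, "w"))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- if (length(samples) > 1) apply(arr, c(1, 2), sd) else mean_m * 0
  mask <- samples[[1]]$mask
  tab <- tibble::tibble(
    target = rep(rownames(mean_m), times = ncol(mean_m)),
    source = rep(colnames(mean_m), each = nrow(mean_m)),
    mean = as.vector(mean_m), sd = as.vector(sd_m),
    status = as.vector(mask)
  )
  list(mean = mean_m, sd = sd_m, mask = mask,
       table = dplyr::filter(tab, .data$status != "diagonal"))
}

#' @export
print.fin_sample <- function(x, ...) {
  cat("<fin_sample> ", nrow(x$w), " x ", ncol(x$w), " (",
      sum(x$mask == "observed"), " observed entries, ",
      sum(x$mask == "imputed"), " imputed), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
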