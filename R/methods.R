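#' @importFrom broom tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
broom::tidy

#' @export
broom::glance

#' @export
ggplot2::autoplot

#' Tidy per-pair predictions of a binary cross-validation
#'
#' @param x A `cv_binary` object.
#' @param ... Unused.
#' @return The per-pair tibble (`source, target, y_true, w_true,
#'   score_mean, y_pred_mean, error, dist_mm`).
#' @export
tidy.cv_binary <- function(x, ...) x$pairs

#' One-row summary of a binary cross-validation
#'
#' @inheritParams tidy.cv_binary
#' @return A tibble with `auc`, `auc_sd`, `acc`, `threshold`, `k`, `R`.
#' @export
glance.cv_binary <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_sd = x$auc_sd, acc = x$acc,
                 threshold = x$threshold,
                 k = attr(x$plan, "k"), R = attr(x$plan, "R"))
}

#' Tidy per-pair predictions of a weighted cross-validation
#'
#' @param x A `cv_weighted` object.
#' @param ... Unused.
#' @return The per-pair tibble (`source, target, w_true, w_pred_mean, mae,
#'   rmae, dist_mm`).
#' @export
tidy.cv_weighted <- function(x, ...) x$pairs

#' One-row summary of a weighted cross-validation
#'
#' @inheritParams tidy.cv_weighted
#' @return A tibble with overall `mae`, all-links and nonlink `rmae`, `k`,
#'   `R`.
#' @export
glance.cv_weighted <- function(x, ...) {
  tab <- weighted_error_table(x)
  tibble::tibble(
    mae = x$mae,
    rmae_links = tab$rmae[tab$group == "all_links"],
    rmae_nonlinks = tab$rmae[tab$group == "nonlinks"],
    k = attr(x$plan, "k"), R = attr(x$plan, "R")
  )
}

#' ROC curve plot for a binary cross-validation
#'
#' @param object A `cv_binary` object.
#' @param ... Unused.
#' @return A ggplot: the pooled ROC curve with the maximum-accuracy point
#'   marked and the chance diagonal.
#' @export
autoplot.cv_binary <- function(object, ...) {
  best <- max_accuracy_threshold(object$roc)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, AUC = %.3f ± %.3f", object$auc, object$auc_sd)
    ) +
    ggplot2::coord_equal()
}

#' Error-profile plot for a weighted cross-validation
#'
#' @param object A `cv_weighted` object.
#' @param against `"weight"` or `"distance"`.
#' @param ... Passed to [error_profiles()].
#' @return A ggplot: mean RMAE with a one-standard-deviation ribbon.
#' @export
autoplot.cv_weighted <- function(object, against = "weight", ...) {
  prof <- error_profiles(object, against = against, ...)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$x_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         fill = "orange", alpha = 0.4) +
    ggplot2::geom_line(colour = "darkorange3") +
    ggplot2::labs(
      x = if (against == "weight") "Link weight (0-7 scale)"
          else "Projection distance (mm)",
      y = "RMAE"
    )
}

#' Heat-map of a prediction-error matrix
#'
#' @param object An [error_matrix()] result.
#' @param regional Plot the region-by-region average instead of the
#'   per-link matrix.
#' @param ... Unused.
#' @return A ggplot tile map (targets on rows, sources on columns).
#' @export
autoplot.error_matrix <- function(object, regional = FALSE, ...) {
  m <- if (regional) object$regional else object$link_matrix
  df <- tibble::tibble(
    target = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    source = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    error = as.vector(m)
  )
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$error)),
                  ggplot2::aes(x = .data$source, y = .data$target,
                               fill = .data$error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "Source area", y = "Target area",
                  fill = object$value) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Scaling-curve plot
#'
#' @param tab The tibble returned by [internal_error_scaling()].
#' @return A ggplot of internal RMAE versus subset size m, one line per
#'   weight group, log-scaled y axis.
#' @export
plot_scaling_curve <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$m, y = .data$rmae,
                                    colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Subset size m (targets)", y = "Internal RMAE",
                  colour = "Link group")
}
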