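FEATURE_SPECS <- c(
  "weighted_common_neighbors", "degree_plus_distance", "adjacency",
  "outdistance_source", "outdistance_target", "outdistance",
  "fln", "fln_plus_distance"
)

#' Length of a feature vector
#'
#' @param spec Feature id (see [build_design_matrix()]).
#' @param n_train Number of training targets |I_train|.
#' @return Integer vector length.
#' @export
feature_length <- function(spec, n_train) {
  spec <- match.arg(spec, FEATURE_SPECS)
  switch(spec,
    weighted_common_neighbors = 1L,
    degree_plus_distance = 3L,
    adjacency = 2L * n_train,
    outdistance_source = n_train,
    outdistance_target = n_train,
    outdistance = 2L * n_train,
    fln = 2L * n_train,
    fln_plus_distance = 2L * n_train + 1L
  )
}

# Per-target feature blocks are interleaved (f(i, u), f(i, v)) with i
# running over I_train in ascending global area order, so that every pair's
# vector has a fixed, learner-stable layout.
interleave <- function(A, B) {
  out <- matrix(0, nrow(A), 2L * ncol(A))
  out[, seq(1L, 2L * ncol(A), by = 2L)] <- A
  out[, seq(2L, 2L * ncol(A), by = 2L)] <- B
  out
}

#' Build the design matrix for a set of ordered pairs
#'
#' Constructs, for each ordered pair (source u, target v), the chosen
#' feature vector from training-row information only, plus (optionally) the
#' ground-truth label read from the target's observed row. Feature entries
#' indexed by one of the pair's own endpoints are masked to 0 so that a
#' training pair never sees its own label (or its own trivially-zero
#' diagonal) among its features.
#'
#' @param spec One of `"weighted_common_neighbors"`,
#'   `"degree_plus_distance"`, `"adjacency"`, `"outdistance_source"`,
#'   `"outdistance_target"`, `"outdistance"`, `"fln"`,
#'   `"fln_plus_distance"`.
#' @param pairs Data frame with character columns `source`, `target`.
#' @param w Weight matrix whose rows cover at least the training targets
#'   (label rows are looked up here too when labels are requested).
#' @param dfeat Scaled N x N distance feature matrix from
#'   [scale_distances()] (raw mm distances may be passed for ablations).
#' @param injected_train Character vector of training target areas; rows of
#'   `w` outside this set are never touched by feature construction.
#' @param ground_truth `"binary"` (0/1 link labels), `"weight"` (0--7
#'   weights) or `"none"`.
#' @param endpoint_policy `"mask"` (default; endpoint-indexed entries set to
#'   0) or `"keep"` (no masking, for ablations only -- leaks labels).
#' @return An object of class `design_matrix`: list with `pairs` (tibble),
#'   `x` (pairs x features numeric matrix), `y` (labels or NULL), `spec`,
#'   and `injected_train` (in global area order).
#' @export
build_design_matrix <- function(spec, pairs, w, dfeat, injected_train,
                                ground_truth = c("binary", "weight", "none"),
                                endpoint_policy = c("mask", "keep")) {
  spec <- match.arg(spec, FEATURE_SPECS)
  ground_truth <- match.arg(ground_truth)
  endpoint_policy <- match.arg(endpoint_policy)
  pairs <- tibble::as_tibble(pairs)[c("source", "target")]
  if (any(pairs$source == pairs$target)) {
    stop("ValueOutOfRange: self pairs (u, u) are not admissible")
  }
  areas <- colnames(w)
  injected_train <- as.character(injected_train)
  if (length(injected_train) == 0) stop("EmptyTrainingSet")
  # fixed ordering: ascending global area index
  injected_train <- areas[sort(match(injected_train, areas))]
  w_tr <- w[injected_train, , drop = FALSE]
  m <- length(injected_train)
  P <- nrow(pairs)

  u_idx <- match(pairs$source, areas)
  v_idx <- match(pairs$target, areas)
  if (anyNA(u_idx) || anyNA(v_idx)) {
    stop("MissingArea: pair endpoints outside the atlas")
  }

  # P x m blocks; column i corresponds to training target injected_train[i]
  A_u <- t(w_tr)[pairs$source, , drop = FALSE]
  A_v <- t(w_tr)[pairs$target, , drop = FALSE]
  D_u <- t(dfeat[injected_train, , drop = FALSE])[pairs$source, , drop = FALSE]
  D_v <- t(dfeat[injected_train, , drop = FALSE])[pairs$target, , drop = FALSE]
  if (endpoint_policy == "mask") {
    mask_u <- outer(pairs$source, injected_train, "==")
    mask_v <- outer(pairs$target, injected_train, "==")
    mask <- mask_u | mask_v
    A_u[mask] <- 0; A_v[mask] <- 0
    D_u[mask] <- 0; D_v[mask] <- 0
  }

  x <- switch(spec,
    weighted_common_neighbors = matrix(rowSums(A_u + A_v), ncol = 1L),
    degree_plus_distance = cbind(
      rowSums(A_u > 0), rowSums(A_v > 0),
      dfeat[cbind(u_idx, v_idx)]
    ),
    adjacency = interleave((A_u > 0) * 1, (A_v > 0) * 1),
    outdistance_source = D_u,
    outdistance_target = D_v,
    outdistance = interleave(D_u, D_v),
    fln = interleave(A_u, A_v),
    fln_plus_distance = cbind(interleave(A_u, A_v),
                              dfeat[cbind(u_idx, v_idx)])
  )
  if (P > 0 && any(!is.finite(x))) stop("NonFiniteFeature")
  colnames(x) <- paste0("f", seq_len(ncol(x)))

  y <- NULL
  if (ground_truth != "none") {
    unavailable <- setdiff(unique(pairs$target), rownames(w))
    if (length(unavailable)) {
      stop("LabelUnavailable: no observed row for target(s) ",
           paste(unavailable, collapse = ", "))
    }
    w_true <- w[cbind(match(pairs$target, rownames(w)),
                      match(pairs$source, areas))]
    y <- if (ground_truth == "binary") as.numeric(w_true > 0) else w_true
  }

  structure(
    list(pairs = pairs, x = x, y = y, spec = spec,
         injected_train = injected_train, ground_truth = ground_truth),
    class = "design_matrix"
  )
}

#' Single-pair feature vector
#'
#' @inheritParams build_design_matrix
#' @param u,v Source and target area names.
#' @return A numeric vector of length `feature_length(spec, |I_train|)`.
#' @export
build_feature_vector <- function(spec, u, v, w, dfeat, injected_train,
                                 endpoint_policy = "mask") {
  dm <- build_design_matrix(spec, tibble::tibble(source = u, target = v),
                            w, dfeat, injected_train,
                            ground_truth = "none",
                            endpoint_policy = endpoint_policy)
  drop(dm$x[1, ])
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$x), " pairs x ", ncol(x$x),
      " features (", x$spec, "), labels: ", x$ground_truth, "\n", sep = "")
  invisible(x)
}

#' Export a design matrix for audit
#'
#' @param dm A [build_design_matrix()] result.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_design_matrix <- function(dm, path) {
  df <- dplyr::bind_cols(dm$pairs, tibble::as_tibble(dm$x))
  if (!is.null(dm$y)) df$label <- dm$y
  readr::write_csv(df, path)
  invisible(path)
}
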