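#' @importFrom rlang .data %||%
#' @importFrom stats kmeans optimize quantile rbinom rmultinom rnorm runif sd
#'   setNames cor complete.cases dist predict uniroot
#' @importFrom utils head
NULL

# Nonlink cutoff weight: lowest statistically acceptable FLN of 8e-7 maps to
# w = 7 + log10(8e-7) ~= 0.903, reported at one decimal as 0.9.
W_CUT <- 0.9
W_CUT_UNROUNDED <- 7 + log10(8e-7)

#' Nonlink cutoff weight
#'
#' The denominator used for relative errors on nonlink pairs. The lowest
#' statistically acceptable FLN value (8e-7) corresponds to a log-weight of
#' about 0.9; the rounded value is the default throughout the package.
#'
#' @param unrounded If `TRUE` return `7 + log10(8e-7)` instead of 0.9.
#' @return A scalar weight on the 0--7 scale.
#' @export
#' @examples
#' w_cut()
w_cut <- function(unrounded = FALSE) {
  if (unrounded) W_CUT_UNROUNDED else W_CUT
}

#' Assemble and validate a tract-tracing dataset
#'
#' A tracing dataset is a partial observation of a weighted directed
#' interareal network: a T x N matrix of fraction-of-labeled-neurons (FLN)
#' weights whose rows are the injected target areas, an N x N interareal
#' barycenter distance matrix in mm, and an area atlas assigning each area to
#' a region (lobe).
#'
#' @param fln Numeric T x N matrix, entries in \[0, 1\]. Rownames are the
#'   injected target areas, colnames the full source-area atlas.
#' @param dist Numeric symmetric N x N matrix of non-negative distances (mm)
#'   with zero diagonal, dimnames matching the atlas order.
#' @param atlas Data frame with columns `area` and `region`, one row per
#'   area, in the column order of `fln` and `dist`.
#' @return An object of class `tracing_dataset`: a list with elements `fln`,
#'   `dist`, `atlas` (tibble) and `injected` (character vector of target
#'   areas, in FLN row order).
#' @export
tracing_dataset <- function(fln, dist, atlas) {
  fln <- as.matrix(fln)
  dist <- as.matrix(dist)
  atlas <- tibble::as_tibble(atlas)
  stopifnot(all(c("area", "region") %in% names(atlas)))
  areas <- as.character(atlas$area)
  if (anyDuplicated(areas)) {
    stop("MissingArea: duplicated area names in atlas: ",
         paste(unique(areas[duplicated(areas)]), collapse = ", "))
  }
  if (any(!nzchar(as.character(atlas$region))) || anyNA(atlas$region)) {
    stop("MissingArea: empty region labels in atlas")
  }
  if (is.null(colnames(fln)) || is.null(rownames(fln))) {
    stop("ShapeMismatch: fln must carry area dimnames")
  }
  if (!identical(colnames(fln), areas)) {
    bad <- setdiff(colnames(fln), areas)
    stop("MissingArea: fln columns do not match atlas order",
         if (length(bad)) paste0(" (unknown: ", paste(bad, collapse = ", "), ")"))
  }
  if (!all(rownames(fln) %in% areas)) {
    stop("MissingArea: injected areas absent from atlas: ",
         paste(setdiff(rownames(fln), areas), collapse = ", "))
  }
  if (!identical(dim(dist), c(length(areas), length(areas)))) {
    stop("ShapeMismatch: dist must be ", length(areas), " x ", length(areas))
  }
  if (!is.null(rownames(dist)) && !identical(rownames(dist), areas)) {
    stop("ShapeMismatch: dist row order differs from atlas")
  }
  dimnames(dist) <- list(areas, areas)
  bad <- which(fln < 0 | fln > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("ValueOutOfRange: FLN outside [0,1] at ",
         rownames(fln)[bad[1, 1]], " <- ", colnames(fln)[bad[1, 2]])
  }
  if (any(dist < 0)) {
    bad <- which(dist < 0, arr.ind = TRUE)
    stop("ValueOutOfRange: negative distance at ",
         areas[bad[1, 1]], " - ", areas[bad[1, 2]])
  }
  rel <- abs(dist - t(dist)) / pmax(abs(dist) + abs(t(dist)), 1)
  if (max(rel) > 1e-6) {
    bad <- which(rel == max(rel), arr.ind = TRUE)
    stop("ValueOutOfRange: dist asymmetric beyond tolerance at ",
         areas[bad[1, 1]], " - ", areas[bad[1, 2]])
  }
  if (any(diag(dist) != 0)) stop("ValueOutOfRange: dist diagonal must be 0")
  self <- intersect(rownames(fln), areas)
  for (a in self) {
    if (fln[a, a] != 0) {
      stop("ValueOutOfRange: self-link FLN must be 0 for injected area ", a)
    }
  }
  structure(
    list(fln = fln, dist = dist, atlas = atlas,
         injected = rownames(fln)),
    class = "tracing_dataset"
  )
}

#' @export
print.tracing_dataset <- function(x, ...) {
  cat("<tracing_dataset> ", nrow(x$fln), " injected targets x ",
      ncol(x$fln), " areas\n", sep = "")
  cat("  links: ", sum(x$fln > 0), "  binary density: ",
      round(binary_density(x), 3), "\n", sep = "")
  cat("  Dmax: ", max(x$dist), " mm; regions: ",
      paste(unique(x$atlas$region), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Binary connection density of the observed rows
#'
#' Fraction of off-diagonal (target, source) pairs in the observed T x N view
#' that carry a link.
#'
#' @param ds A [tracing_dataset()].
#' @return A scalar in \[0, 1\].
#' @export
binary_density <- function(ds) {
  n_pairs <- nrow(ds$fln) * (ncol(ds$fln) - 1)
  sum(ds$fln > 0) / n_pairs
}

#' Read a tracing dataset from CSV files
#'
#' Matrices are comma-separated UTF-8 with the first row and first column
#' holding area names; the atlas file has columns `area`, `region` and an
#' `injected` flag (or a separate one-column injected list).
#'
#' @param fln_path,dist_path Paths to the FLN and distance matrix CSVs.
#' @param atlas_path Path to the atlas CSV (`area,region[,injected]`).
#' @param injected_path Optional path to a one-column CSV of injected areas;
#'   overrides the atlas `injected` column.
#' @return A validated [tracing_dataset()].
#' @export
read_tracing_dataset <- function(fln_path, dist_path, atlas_path,
                                 injected_path = NULL) {
  fln <- read_matrix_csv(fln_path)
  dist <- read_matrix_csv(dist_path)
  atlas <- readr::read_csv(atlas_path, show_col_types = FALSE)
  if (!is.null(injected_path)) {
    injected <- readr::read_csv(injected_path, show_col_types = FALSE)[[1]]
  } else if ("injected" %in% names(atlas)) {
    injected <- atlas$area[as.logical(atlas$injected)]
  } else {
    injected <- rownames(fln)
  }
  if (!all(injected %in% atlas$area)) {
    stop("MissingArea: injected list names unknown areas: ",
         paste(setdiff(injected, atlas$area), collapse = ", "))
  }
  if (!setequal(rownames(fln), injected)) {
    stop("ShapeMismatch: FLN rows do not match the injected list")
  }
  fln <- fln[as.character(injected), , drop = FALSE]
  tracing_dataset(fln, dist, atlas[c("area", "region")])
}

#' Write a tracing dataset to CSV files
#'
#' Inverse of [read_tracing_dataset()]; numbers are written with
#' shortest-round-trip precision so that a write/read cycle is bit-exact.
#'
#' @param ds A [tracing_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_tracing_dataset <- function(ds, dir, prefix = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fln = file.path(dir, paste0(prefix, "_fln.csv")),
    dist = file.path(dir, paste0(prefix, "_dist.csv")),
    atlas = file.path(dir, paste0(prefix, "_atlas.csv"))
  )
  write_matrix_csv(ds$fln, paths[["fln"]])
  write_matrix_csv(ds$dist, paths[["dist"]])
  atlas <- dplyr::mutate(ds$atlas,
                         injected = as.integer(.data$area %in% ds$injected))
  readr::write_csv(atlas, paths[["atlas"]])
  invisible(paths)
}

read_matrix_csv <- function(path) {
  # base read.csv: correctly rounded strtod parsing, exact round trips
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

write_matrix_csv <- function(m, path) {
  # 17 significant digits: enough for a bit-exact double round trip
  if (is.numeric(m)) {
    chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  } else {
    chr <- m
  }
  df <- tibble::as_tibble(chr, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(area = rownames(m)), df)
  readr::write_csv(df, path)
}

#' Log-transform FLN weights to the 0--7 scale
#'
#' Nonzero FLN entries become `w = 7 + log10(FLN)`; zero entries (nonlinks,
#' diagonal) stay exactly 0. FLN values below 1e-7 yield negative weights,
#' which are retained but flagged with a warning since the 0--7 range is an
#' empirical property of the data, not an enforced one.
#'
#' @param ds A [tracing_dataset()], or a bare FLN matrix.
#' @return A T x N weight matrix with the same dimnames.
#' @export
#' @examples
#' transform_weights(matrix(c(1, 0, 8e-7, 0.1), 2, 2,
#'                   dimnames = list(c("A", "B"), c("A", "B"))))
transform_weights <- function(ds) {
  fln <- if (inherits(ds, "tracing_dataset")) ds$fln else as.matrix(ds)
  w <- fln
  nz <- fln > 0
  w[nz] <- 7 + log10(fln[nz])
  if (any(w[nz] < 0)) {
    warning("FLN values below 1e-7 give weights below 0; retained unclamped")
  }
  w
}

#' Invert the weight transform
#'
#' @param w A weight matrix from [transform_weights()].
#' @return The FLN matrix, with zeros preserved.
#' @export
inverse_transform_weights <- function(w) {
  fln <- w
  nz <- w != 0
  fln[nz] <- 10^(w[nz] - 7)
  fln
}

#' Scale distances onto the 0--31 feature range
#'
#' The distance feature matrix is `31 * D / Dmax`, spanning 0 to 31; the
#' maximum observed interareal distance maps exactly to 31 so that the
#' feature resolution is comparable across species.
#'
#' @param ds A [tracing_dataset()] or a bare distance matrix.
#' @return An N x N matrix with attribute `dmax` (the largest distance, mm).
#' @export
scale_distances <- function(ds) {
  d <- if (inherits(ds, "tracing_dataset")) ds$dist else as.matrix(ds)
  dmax <- max(d)
  if (dmax <= 0) stop("DegenerateDistances: all distances are zero")
  out <- 31 * (d / dmax)
  attr(out, "dmax") <- dmax
  out
}

WEIGHT_CLASSES <- c("strong", "strong_medium", "medium_weak", "weak")

#' Weight-class membership of links
#'
#' Classes are inclusive at their boundaries: strong (w >= 5),
#' strong-&-medium (w >= 3), medium-&-weak (0 < w <= 5) and weak
#' (0 < w <= 3). A boundary weight belongs to both adjacent classes;
#' nonlinks (w = 0) belong to none.
#'
#' @param w A weight matrix (or vector) on the 0--7 scale.
#' @return A named list of logical masks, one per class, same shape as `w`.
#' @export
#' @examples
#' assign_weight_classes(c(0, 2, 3, 5.3))
assign_weight_classes <- function(w) {
  link <- w > 0
  list(
    strong = link & w >= 5,
    strong_medium = link & w >= 3,
    medium_weak = link & w <= 5,
    weak = link & w <= 3
  )
}

#' Tidy per-pair table of a tracing dataset
#'
#' One row per ordered (source, target) pair with an observed target row,
#' excluding self pairs: FLN, log-weight, distance, scaled distance, binary
#' link indicator, and weight-class flags.
#'
#' @param ds A [tracing_dataset()].
#' @return A tibble with one row per directed pair.
#' @export
pair_table <- function(ds) {
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  targets <- rownames(w)
  sources <- colnames(w)
  grid <- tidyr::expand_grid(target = targets, source = sources)
  grid <- dplyr::filter(grid, .data$target != .data$source)
  idx <- cbind(match(grid$target, targets), match(grid$source, sources))
  didx <- cbind(match(grid$target, rownames(ds$dist)),
                match(grid$source, colnames(ds$dist)))
  out <- dplyr::mutate(grid,
    fln = ds$fln[idx],
    w = w[idx],
    dist_mm = ds$dist[didx],
    dist_feat = dfeat[didx],
    link = .data$w > 0
  )
  cls <- assign_weight_classes(out$w)
  dplyr::bind_cols(out, tibble::as_tibble(cls))
}
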