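# Empirical exponential-distance-rule decay rates (1/mean projection
# length): macaque-like 0.19 per mm, mouse-like 0.78 per mm.

#' EDR decay-rate presets
#'
#' @return Named numeric vector of decay rates in 1/mm.
#' @export
#' @examples
#' edr_lambda_presets()
edr_lambda_presets <- function() {
  c(macaque = 0.19, mouse = 0.78)
}

#' Generate a synthetic cortical geometry
#'
#' Uniform area barycenters in a box, with pairwise Euclidean distances
#' optionally rescaled so the largest interareal distance matches a stated
#' `dmax` (58.2 mm macaque-like, 12 mm mouse-like). Regions are spatial
#' k-means clusters, standing in for cortical lobes so that regional error
#' matrices have block structure to aggregate over.
#'
#' @param n_areas Number of areas (>= 3).
#' @param dimension Spatial dimension (2 or 3).
#' @param extent Box side length (mm); ignored when `dmax` is given.
#' @param dmax If non-`NULL`, rescale so `max(dist) == dmax` (mm).
#' @param n_regions Number of spatial clusters used as region labels.
#' @param seed Integer seed.
#' @return An object of class `synthetic_geometry`: list with `positions`
#'   (n x dim matrix), `dist` (named N x N matrix, mm) and `atlas` tibble.
#' @export
generate_geometry <- function(n_areas, dimension = 2, extent = 1,
                              dmax = NULL, n_regions = 4, seed = 1) {
  if (n_areas < 3) stop("BadDimension: need at least 3 areas")
  if (!dimension %in% c(1, 2, 3)) stop("BadDimension: dimension must be 1-3")
  set.seed(seed)
  pos <- matrix(runif(n_areas * dimension, 0, extent), n_areas, dimension)
  d <- as.matrix(dist(pos))
  if (!is.null(dmax)) {
    scale <- dmax / max(d)
    pos <- pos * scale
    d <- d * scale
  }
  areas <- sprintf("A%02d", seq_len(n_areas))
  dimnames(d) <- list(areas, areas)
  rownames(pos) <- areas
  km <- kmeans(pos, centers = min(n_regions, n_areas), nstart = 5)
  atlas <- tibble::tibble(area = areas,
                          region = paste0("R", km$cluster))
  structure(list(positions = pos, dist = d, atlas = atlas),
            class = "synthetic_geometry")
}

#' Sample projection counts under the exponential distance rule
#'
#' Each of `n_projections` axonal projections is assigned independently to
#' an ordered area pair (source u -> target v, u != v) with probability
#' proportional to `exp(-lambda * d(u, v))`; `lambda = 0` degenerates to a
#' uniform assignment.
#'
#' @param dist N x N distance matrix (mm) with area dimnames.
#' @param lambda Decay rate (1/mm), >= 0.
#' @param n_projections Total number of projections to place.
#' @param seed Integer seed.
#' @return An N x N integer count matrix (rows = targets, cols = sources).
#' @export
sample_edr_projections <- function(dist, lambda, n_projections, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (max(d) <= 0) stop("DegenerateDistances: all distances are zero")
  stopifnot(lambda >= 0, n_projections >= n)
  # probability over ordered pairs; target row v, source column u
  logp <- -lambda * d
  diag(logp) <- -Inf
  p <- exp(logp - max(logp[is.finite(logp)]))
  diag(p) <- 0
  set.seed(seed)
  counts <- rmultinom(1, size = n_projections, prob = as.vector(p))
  m <- matrix(as.integer(counts), n, n, dimnames = dimnames(d))
  m
}

#' Generate a full EDR network as an FLN-like matrix
#'
#' Projection counts from [sample_edr_projections()] are normalized within
#' each target row (counts divided by the row total), producing
#' fraction-of-labeled-neurons values per target; pairs with zero counts are
#' nonlinks. Rows that received no projections stay all-zero.
#'
#' @inheritParams sample_edr_projections
#' @return An N x N FLN matrix (rows = targets) with a `counts` attribute
#'   holding the raw projection counts.
#' @export
generate_edr_network <- function(dist, lambda, n_projections, seed = 1) {
  counts <- sample_edr_projections(dist, lambda, n_projections, seed)
  totals <- rowSums(counts)
  fln <- counts / ifelse(totals > 0, totals, 1)
  attr(fln, "counts") <- counts
  fln
}

#' Calibrate the projection count to a target binary density
#'
#' Finds (deterministically, from the expected coverage
#' `1 - exp(-n * p_ij)` summed over ordered pairs) the total projection
#' count whose expected fraction of pairs with at least one projection
#' matches the requested density.
#'
#' @param dist Distance matrix.
#' @param lambda Decay rate (1/mm).
#' @param target_density Desired fraction of off-diagonal ordered pairs
#'   carrying a link, in (0, 1).
#' @return The projection count (integer-valued double).
#' @export
calibrate_projections <- function(dist, lambda, target_density) {
  d <- as.matrix(dist)
  stopifnot(target_density > 0, target_density < 1)
  logp <- -lambda * d
  diag(logp) <- -Inf
  p <- exp(logp - max(logp[is.finite(logp)]))
  diag(p) <- 0
  p <- as.vector(p[p > 0]) / sum(p)
  expected_density <- function(log10n) mean(1 - exp(-(10^log10n) * p))
  sol <- uniroot(function(z) expected_density(z) - target_density,
                 lower = 0, upper = 12, tol = 1e-10)
  round(10^sol$root)
}

#' Estimate the EDR decay rate from projection counts
#'
#' Maximum-likelihood fit of the exponential decay rate under the EDR
#' sampling model: projections fall on ordered pairs with probability
#' proportional to `exp(-lambda * d)`, so the log-likelihood is
#' `sum_ij c_ij * (-lambda d_ij) - n log sum_ij exp(-lambda d_ij)`,
#' maximized over lambda by golden-section search.
#'
#' @param counts N x N projection count matrix (e.g. the `counts` attribute
#'   of [generate_edr_network()]).
#' @param dist Matching distance matrix (mm).
#' @param upper Upper bound of the search interval (1/mm).
#' @return The estimated decay rate (1/mm).
#' @export
estimate_edr_lambda <- function(counts, dist, upper = 10) {
  d <- as.matrix(dist)
  c_ <- as.matrix(counts)
  off <- row(d) != col(d)
  dv <- d[off]
  cv <- c_[off]
  n <- sum(cv)
  nll <- function(lambda) {
    z <- -lambda * dv
    m <- max(z)
    -(sum(cv * z) - n * (m + log(sum(exp(z - m)))))
  }
  optimize(nll, c(0, upper))$minimum
}

#' Observe a partial (injected-rows) dataset from a full network
#'
#' Emulates the observation pattern of retrograde tracing: each injection
#' reveals one full target row of the full interareal network, so the
#' observed data are a uniformly sampled row submatrix.
#'
#' @param fin N x N FLN matrix (full network).
#' @param dist N x N distance matrix.
#' @param atlas Atlas data frame (`area`, `region`).
#' @param n_injections Number of observed target rows T, `T <= N`.
#' @param seed Integer seed.
#' @return A [tracing_dataset()] whose `injected` records the sampled rows
#'   (in atlas order).
#' @export
make_partial_dataset <- function(fin, dist, atlas, n_injections, seed = 1) {
  fin <- as.matrix(fin)
  areas <- as.character(atlas$area)
  if (n_injections > nrow(fin) || n_injections < 1) {
    stop("BadT: need 1 <= T <= ", nrow(fin))
  }
  set.seed(seed)
  rows <- sort(sample(nrow(fin), n_injections))
  obs <- fin[rows, , drop = FALSE]
  dimnames(obs) <- list(areas[rows], areas)
  tracing_dataset(obs, dist, atlas)
}

#' Degree-preserving configuration-model rewiring
#'
#' Destroys the spatial and weight structure of the observed network while
#' preserving every node's binary in/out link counts on the observed
#' (target x source) view, by repeated double-edge swaps; weights travel
#' with their link. Used as the null control against which structural
#' predictability is judged: on the rewired network predictability collapses
#' in all weight categories.
#'
#' @param w Observed T x N weight matrix.
#' @param seed Integer seed.
#' @param n_swaps Target number of successful swaps (default 10 per link).
#' @param max_tries Attempt budget; exhausting it raises `RewireStall`.
#' @return A rewired weight matrix of identical shape and degree sequences.
#' @export
rewire_configuration <- function(w, seed = 1, n_swaps = NULL,
                                 max_tries = NULL) {
  w <- as.matrix(w)
  edges <- which(w > 0, arr.ind = TRUE)
  E <- nrow(edges)
  if (E < 2) stop("RewireStall: need at least 2 links to rewire")
  n_swaps <- n_swaps %||% (10L * E)
  max_tries <- max_tries %||% (200L * E)
  targets <- rownames(w)
  areas <- colnames(w)
  wt <- w[edges]
  adj <- w > 0
  set.seed(seed)
  done <- 0L; tries <- 0L
  while (done < n_swaps) {
    tries <- tries + 1L
    if (tries > max_tries) stop("RewireStall: swap attempts exhausted")
    ij <- sample.int(E, 2L)
    e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
    if (e1[1] == e2[1] || e1[2] == e2[2]) next
    # proposed: (t1, s2), (t2, s1); forbid self-links and duplicates
    if (targets[e1[1]] == areas[e2[2]] || targets[e2[1]] == areas[e1[2]]) next
    if (adj[e1[1], e2[2]] || adj[e2[1], e1[2]]) next
    adj[e1[1], e1[2]] <- FALSE; adj[e2[1], e2[2]] <- FALSE
    adj[e1[1], e2[2]] <- TRUE;  adj[e2[1], e1[2]] <- TRUE
    s1 <- edges[ij[1], 2]
    edges[ij[1], 2] <- edges[ij[2], 2]
    edges[ij[2], 2] <- s1
    done <- done + 1L
  }
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  out[edges] <- wt
  out
}

#' Perturb link weights with log-scale noise
#'
#' Adds zero-mean Gaussian noise to the base-10 log of every nonzero FLN
#' entry (equivalently, to its 0--7 log-weight); nonlinks are untouched and
#' perturbed values are capped at FLN = 1. The parameter-recovery harness:
#' an oracle predictor's error must track this injected noise floor.
#'
#' @param fin FLN matrix (any shape).
#' @param noise_sd Noise standard deviation on the log-weight scale, >= 0.
#' @param seed Integer seed.
#' @return The perturbed FLN matrix.
#' @export
synthetic_weight_noise <- function(fin, noise_sd, seed = 1) {
  stopifnot(noise_sd >= 0)
  fin <- as.matrix(fin)
  if (noise_sd == 0) return(fin)
  nz <- which(fin > 0)
  set.seed(seed)
  eps <- rnorm(length(nz), 0, noise_sd)
  fin[nz] <- pmin(10^(log10(fin[nz]) + eps), 1)
  fin
}

#' Simulate a complete species-scale EDR study
#'
#' Convenience wrapper assembling geometry, full EDR network, and the
#' partial injected-rows observation in one call, defaulting to the
#' macaque-like study scale: 91 areas with 29 injections, decay rate 0.19
#' per mm on a geometry rescaled to a 58.2 mm span, and a projection count
#' calibrated to a 0.66 binary density. `species = "mouse"` switches to 47
#' areas, 19 injections, 0.78 per mm, 12 mm span and 0.97 density.
#'
#' @param species `"macaque"` or `"mouse"`.
#' @param seed Integer seed.
#' @param n_areas,n_injections,lambda,dmax,target_density Overrides of the
#'   species defaults.
#' @return A list with `ds` (the [tracing_dataset()]), `fin` (full N x N
#'   FLN), `geometry`, `lambda`, and `n_projections`.
#' @export
simulate_edr_study <- function(species = c("macaque", "mouse"), seed = 1,
                               n_areas = NULL, n_injections = NULL,
                               lambda = NULL, dmax = NULL,
                               target_density = NULL) {
  species <- match.arg(species)
  def <- switch(species,
    macaque = list(n_areas = 91L, n_injections = 29L, lambda = 0.19,
                   dmax = 58.2, target_density = 0.66),
    mouse = list(n_areas = 47L, n_injections = 19L, lambda = 0.78,
                 dmax = 12, target_density = 0.97)
  )
  n_areas <- n_areas %||% def$n_areas
  n_injections <- n_injections %||% def$n_injections
  lambda <- lambda %||% def$lambda
  dmax <- dmax %||% def$dmax
  target_density <- target_density %||% def$target_density
  geom <- generate_geometry(n_areas, dimension = 2, dmax = dmax,
                            n_regions = 4, seed = seed)
  n_proj <- calibrate_projections(geom$dist, lambda, target_density)
  fin <- generate_edr_network(geom$dist, lambda, n_proj, seed = seed + 1)
  ds <- make_partial_dataset(fin, geom$dist, geom$atlas, n_injections,
                             seed = seed + 2)
  list(ds = ds, fin = fin, geometry = geom, lambda = lambda,
       n_projections = n_proj)
}
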