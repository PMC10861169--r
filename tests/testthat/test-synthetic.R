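test_that("geometries are reproducible and rescale to a stated span", {
  g1 <- generate_geometry(30, dmax = 58.2, seed = 3)
  g2 <- generate_geometry(30, dmax = 58.2, seed = 3)
  expect_identical(g1$dist, g2$dist)
  expect_identical(g1$atlas, g2$atlas)
  expect_equal(max(g1$dist), 58.2)
  expect_true(isSymmetric(g1$dist))
  expect_true(all(diag(g1$dist) == 0))
  g91 <- generate_geometry(91, dmax = 58.2, seed = 1)
  expect_lt(abs(max(g91$dist) - 58.2) / 58.2, 0.1)
  expect_gt(length(unique(g1$atlas$region)), 1)
  expect_error(generate_geometry(2), "BadDimension")
})

test_that("zero decay assigns projections uniformly over ordered pairs", {
  g <- generate_geometry(12, dmax = 20, seed = 5)
  counts <- sample_edr_projections(g$dist, lambda = 0, n_projections = 2e5,
                                   seed = 6)
  off <- counts[row(counts) != col(counts)]
  # chi-square goodness of fit against the uniform multinomial
  chi <- sum((off - mean(off))^2 / mean(off))
  expect_gt(stats::pchisq(chi, df = length(off) - 1, lower.tail = FALSE),
            0.01)
  expect_true(all(diag(counts) == 0))
})

test_that("projection lengths follow the exponential decay they were drawn from", {
  # distance design with near-uniform availability so the length histogram
  # is a truncated exponential
  n <- 80
  d <- matrix(0, n, n)
  vals <- seq(0.5, 30, length.out = n * (n - 1) / 2)
  d[upper.tri(d)] <- sample(vals)
  d <- d + t(d)
  dimnames(d) <- list(paste0("a", 1:n), paste0("a", 1:n))
  lambda <- 0.3
  counts <- sample_edr_projections(d, lambda, n_projections = 3000, seed = 8)
  lens <- rep(d[row(d) != col(d)], times = counts[row(counts) != col(counts)])
  a <- 0.5; b <- 30
  cdf <- function(q) (1 - exp(-lambda * (q - a))) / (1 - exp(-lambda * (b - a)))
  ks <- suppressWarnings(stats::ks.test(lens, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("the decay rate is recovered by maximum likelihood within 5%", {
  g <- generate_geometry(60, dmax = 58.2, seed = 9)
  counts <- sample_edr_projections(g$dist, lambda = 0.19,
                                   n_projections = 1e6, seed = 10)
  lam_hat <- estimate_edr_lambda(counts, g$dist)
  expect_lt(abs(lam_hat - 0.19) / 0.19, 0.05)
})

test_that("density falls with the decay rate at fixed projection count", {
  g <- generate_geometry(30, dmax = 58.2, seed = 11)
  dens <- vapply(c(0, 0.1, 0.3), function(lam) {
    fln <- generate_edr_network(g$dist, lam, 3000, seed = 12)
    mean(fln[row(fln) != col(fln)] > 0)
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})

test_that("density calibration hits its target in expectation", {
  g <- generate_geometry(40, dmax = 58.2, seed = 13)
  for (target in c(0.66, 0.9)) {
    np <- calibrate_projections(g$dist, 0.19, target)
    fln <- generate_edr_network(g$dist, 0.19, np, seed = 14)
    dens <- mean(fln[row(fln) != col(fln)] > 0)
    expect_lt(abs(dens - target), 0.06)
  }
})

test_that("generated FLN rows are normalized over their sources", {
  g <- generate_geometry(25, dmax = 58.2, seed = 15)
  fln <- generate_edr_network(g$dist, 0.19, 5000, seed = 16)
  sums <- rowSums(fln)
  active <- sums > 0
  expect_true(all(abs(sums[active] - 1) < 1e-12))
  expect_true(all(fln >= 0 & fln <= 1))
  counts <- attr(fln, "counts")
  expect_equal(sum(counts), 5000)
})

test_that("partial observation keeps full rows and records the injections", {
  g <- generate_geometry(91, dmax = 58.2, seed = 17)
  fln <- generate_edr_network(g$dist, 0.19, 5e4, seed = 18)
  ds <- make_partial_dataset(fln, g$dist, g$atlas, 29, seed = 19)
  expect_equal(dim(ds$fln), c(29L, 91L))
  expect_length(ds$injected, 29)
  for (t in ds$injected[1:3]) {
    expect_identical(ds$fln[t, ], fln[t, ]) # observed rows are full rows
  }
  full <- make_partial_dataset(fln, g$dist, g$atlas, 91, seed = 20)
  expect_identical(full$fln[, ], fln[, ]) # T = N observes the FIN itself
  expect_error(make_partial_dataset(fln, g$dist, g$atlas, 92), "BadT")
})

test_that("configuration rewiring preserves degree sequences and weights", {
  study <- small_edr_study(seed = 21, n_areas = 20, n_injections = 10)
  w <- transform_weights(study$ds)
  rw <- rewire_configuration(w, seed = 22)
  expect_identical(dim(rw), dim(w))
  expect_equal(rowSums(rw > 0), rowSums(w > 0))
  expect_equal(colSums(rw > 0), colSums(w > 0))
  expect_equal(sort(rw[rw > 0]), sort(w[w > 0]))
  for (t in rownames(rw)) expect_identical(rw[t, t], 0)
  expect_false(identical(rw, w))
  expect_identical(rewire_configuration(w, seed = 22), rw)
  expect_error(rewire_configuration(matrix(0, 2, 2)), "RewireStall")
})

test_that("log-weight noise perturbs links only, reproducibly", {
  study <- small_edr_study(seed = 23, n_areas = 15, n_injections = 8)
  fin <- study$fin
  expect_identical(synthetic_weight_noise(fin, 0, seed = 1), fin)
  pert <- synthetic_weight_noise(fin, 0.5, seed = 2)
  expect_identical(pert == 0, fin == 0)
  expect_identical(synthetic_weight_noise(fin, 0.5, seed = 2), pert)
  expect_true(all(pert <= 1))
  expect_false(identical(pert, fin))
})

test_that("an oracle predictor's RMAE tracks the injected noise floor", {
  study <- small_edr_study(seed = 24, n_areas = 20, n_injections = 10)
  fin <- study$fin
  w_true <- transform_weights(fin)
  link <- w_true > 0
  rmae_at <- vapply(c(0, 0.2, 0.5, 1), function(sd_) {
    noisy <- transform_weights(synthetic_weight_noise(fin, sd_, seed = 25))
    mean(abs(noisy[link] - w_true[link]) / w_true[link])
  }, numeric(1))
  expect_equal(rmae_at[1], 0)
  expect_true(all(diff(rmae_at) > 0))
})
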