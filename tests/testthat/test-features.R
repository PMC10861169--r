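# Toy from the feature definitions: I_train = (z1, z2); u links to z1 only,
# v links to z1 and z2; dfeat(u, v) = 10.
toy_feature_setup <- function() {
  areas <- c("z1", "z2", "u", "v")
  w <- matrix(0, 2, 4, dimnames = list(c("z1", "z2"), areas))
  w["z1", "u"] <- 2
  w["z1", "v"] <- 4
  w["z2", "v"] <- 6
  dfeat <- matrix(5, 4, 4, dimnames = list(areas, areas))
  diag(dfeat) <- 0
  dfeat["u", "v"] <- 10; dfeat["v", "u"] <- 10
  list(w = w, dfeat = dfeat, I = c("z1", "z2"))
}

test_that("feature vectors match the definitions on the toy pair", {
  s <- toy_feature_setup()
  adj <- build_feature_vector("adjacency", "u", "v", s$w, s$dfeat, s$I)
  expect_equal(unname(adj), c(1, 1, 0, 1)) # (A(z1,u)>0, A(z1,v)>0, A(z2,u)>0, A(z2,v)>0)
  dpd <- build_feature_vector("degree_plus_distance", "u", "v", s$w, s$dfeat, s$I)
  expect_equal(unname(dpd), c(1, 2, 10)) # d(u), d(v), D(u, v)
  flnv <- build_feature_vector("fln", "u", "v", s$w, s$dfeat, s$I)
  expect_equal(unname(flnv), c(2, 4, 0, 6))
  fpd <- build_feature_vector("fln_plus_distance", "u", "v", s$w, s$dfeat, s$I)
  expect_equal(unname(fpd), c(2, 4, 0, 6, 10))
  wcn <- build_feature_vector("weighted_common_neighbors", "u", "v",
                              s$w, s$dfeat, s$I)
  expect_equal(unname(wcn), (2 + 4) + (0 + 6))
})

test_that("feature lengths follow the stated arithmetic", {
  expect_equal(feature_length("fln_plus_distance", 19), 39)
  expect_equal(feature_length("adjacency", 19), 38)
  expect_equal(feature_length("degree_plus_distance", 19), 3)
  expect_equal(feature_length("weighted_common_neighbors", 19), 1)
  expect_equal(feature_length("outdistance", 10), 20)
  # k = 3 folds on 29 targets leave ~19 training rows -> length 39
  s <- toy_feature_setup()
  for (spec in c("fln", "outdistance_source", "outdistance_target",
                 "outdistance", "fln_plus_distance", "adjacency")) {
    v <- build_feature_vector(spec, "u", "v", s$w, s$dfeat, s$I)
    expect_length(v, feature_length(spec, 2))
  }
})

test_that("a training pair's own label is masked out of its features", {
  ds <- toy_dataset()
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  I_tr <- ds$injected[1:4]
  # pair whose target is itself a training row: label w[v, u]
  v <- I_tr[2]
  u <- setdiff(colnames(w), v)[1]
  pairs <- tibble::tibble(source = u, target = v)
  for (spec in c("fln", "fln_plus_distance", "adjacency",
                 "degree_plus_distance", "weighted_common_neighbors",
                 "outdistance")) {
    dm1 <- build_design_matrix(spec, pairs, w, dfeat, I_tr, "none")
    w2 <- w
    w2[v, u] <- w2[v, u] + 3 # perturb the would-be label
    dm2 <- build_design_matrix(spec, pairs, w2, dfeat, I_tr, "none")
    expect_identical(dm1$x, dm2$x, info = spec)
  }
})

test_that("features depend only on training rows (test-fold perturbation)", {
  ds <- toy_dataset()
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  I_tr <- ds$injected[1:3]
  held_out <- ds$injected[4:5]
  pairs <- tidyr::expand_grid(source = colnames(w), target = ds$injected[1]) |>
    dplyr::filter(source != target)
  dm1 <- build_design_matrix("fln_plus_distance", pairs, w, dfeat, I_tr,
                             "weight")
  w2 <- w
  set.seed(99)
  w2[held_out, ] <- matrix(runif(length(held_out) * ncol(w), 0, 7),
                           length(held_out))
  dm2 <- build_design_matrix("fln_plus_distance", pairs, w2, dfeat, I_tr,
                             "weight")
  expect_identical(dm1$x, dm2$x)
  expect_identical(dm1$y, dm2$y)
})

test_that("design matrices are deterministic and order-equivariant", {
  ds <- toy_dataset()
  w <- transform_weights(ds)
  dfeat <- scale_distances(ds)
  I_tr <- ds$injected[1:4]
  pairs <- tidyr::expand_grid(source = colnames(w), target = I_tr) |>
    dplyr::filter(source != target)
  dm1 <- build_design_matrix("fln", pairs, w, dfeat, I_tr, "binary")
  dm2 <- build_design_matrix("fln", pairs, w, dfeat, I_tr, "binary")
  expect_identical(dm1$x, dm2$x)
  perm <- sample(nrow(pairs))
  dm3 <- build_design_matrix("fln", pairs[perm, ], w, dfeat, I_tr, "binary")
  expect_identical(dm3$x, dm1$x[perm, ])
  expect_identical(dm3$y, dm1$y[perm])
  # training-set ordering is by global area index regardless of input order
  dm4 <- build_design_matrix("fln", pairs, w, dfeat, rev(I_tr), "binary")
  expect_identical(dm4$x, dm1$x)
})

test_that("label and input errors are raised cleanly", {
  s <- toy_feature_setup()
  expect_error(build_feature_vector("fln", "u", "u", s$w, s$dfeat, s$I))
  expect_error(build_design_matrix("fln", tibble::tibble(source = "z1",
                                                         target = "u"),
                                   s$w, s$dfeat, s$I, "binary"),
               "LabelUnavailable")
  expect_error(build_design_matrix("fln", tibble::tibble(source = "z1",
                                                         target = "u"),
                                   s$w, s$dfeat, character(0), "none"),
               "EmptyTrainingSet")
  empty <- build_design_matrix("fln", tibble::tibble(source = character(),
                                                     target = character()),
                               s$w, s$dfeat, s$I, "none")
  expect_equal(nrow(empty$x), 0)
})
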