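# Shared fixtures and independent oracles. All fixtures are built in code;
# nothing is read from disk.

# Deterministic toy tracing dataset: 8 areas, 5 injected, hand-set FLN.
toy_dataset <- function() {
  areas <- c("V1", "V2", "V4", "MT", "TEO", "FEF", "LIP", "A7a")
  injected <- c("V1", "V2", "V4", "MT", "TEO")
  set.seed(42)
  pos <- cbind(runif(8, 0, 30), runif(8, 0, 30))
  d <- as.matrix(dist(pos))
  dimnames(d) <- list(areas, areas)
  fln <- matrix(0, 5, 8, dimnames = list(injected, areas))
  set.seed(43)
  for (i in seq_len(5)) {
    src <- sample(setdiff(areas, injected[i]), 5)
    fln[i, src] <- 10^runif(5, -6, 0)
    fln[i, ] <- fln[i, ] / sum(fln[i, ])
  }
  atlas <- tibble::tibble(area = areas,
                          region = rep(c("occipital", "temporal",
                                         "frontal", "parietal"), each = 2))
  tracing_dataset(fln, d, atlas)
}

# The two-target classical-predictor toy: I_train = {z1, z2};
# w(z1,u)=2, w(z2,u)=0, w(z1,v)=4, w(z2,v)=6.
toy_classical_w <- function() {
  w <- matrix(0, 2, 4, dimnames = list(c("z1", "z2"),
                                       c("u", "v", "z1", "z2")))
  w["z1", "u"] <- 2
  w["z1", "v"] <- 4
  w["z2", "v"] <- 6
  w
}

# Small EDR study for CV-level tests: quick but structured.
small_edr_study <- function(seed = 1, n_areas = 25, n_injections = 13,
                            lambda = 0.19, target_density = 0.66) {
  simulate_edr_study("macaque", seed = seed, n_areas = n_areas,
                     n_injections = n_injections, lambda = lambda,
                     target_density = target_density)
}

# Concordant-pair (Mann-Whitney) AUC oracle, ties counted one half.
auc_mann_whitney <- function(y_true, score) {
  pos <- score[y_true == 1]
  neg <- score[y_true == 0]
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}

# Naive loop implementation of the classical predictors, straight from the
# formulas, used as the brute-force oracle for the vectorized versions.
naive_classical <- function(method, u, v, w_train,
                            gamma_includes_self = FALSE) {
  I <- rownames(w_train)
  areas <- colnames(w_train)
  wgt <- function(z, x) w_train[z, x]
  gamma_o <- function(x) {
    g <- I[vapply(I, function(z) wgt(z, x) > 0, logical(1))]
    n <- length(g)
    if (gamma_includes_self && x %in% I) n <- n + 1
    n
  }
  out_strength <- function(x) sum(vapply(I, function(z) wgt(z, x), numeric(1)))
  switch(method,
    CN2 = 0.5 * sum(vapply(I, function(z) wgt(z, u) + wgt(z, v), numeric(1))),
    PA2 = {
      gu <- gamma_o(u); gv <- gamma_o(v)
      fu <- if (gu > 0) out_strength(u) / gu else 0
      fv <- if (gv > 0) out_strength(v) / gv else 0
      fu * fv
    },
    AA2 = {
      tot <- 0
      for (z in I) {
        s <- out_strength(z)
        if (s > 1) tot <- tot + (wgt(z, u) + wgt(z, v)) / log(s)
      }
      0.5 * tot
    },
    RA2 = {
      tot <- 0
      for (z in I) {
        s <- out_strength(z)
        if (s > 0) tot <- tot + (wgt(z, u) + wgt(z, v)) / s
      }
      tot
    },
    JA2 = {
      num <- sum(vapply(I, function(z) min(wgt(z, u), wgt(z, v)), numeric(1)))
      den <- sum(vapply(I, function(z) max(wgt(z, u), wgt(z, v)), numeric(1)))
      if (den > 0) num / den else 0
    }
  )
}

# Minimal hand-built cv objects for the error-localisation functions.
fake_cv_binary <- function(pairs) {
  structure(list(pairs = pairs), class = "cv_binary")
}
fake_cv_weighted <- function(pairs, w_cut_value = finlink::w_cut()) {
  structure(list(pairs = pairs, w_cut = w_cut_value), class = "cv_weighted")
}
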