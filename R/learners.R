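ALGORITHMS <- c("KNN", "DT", "RF", "MLP", "GB", "ADA", "NBA")

default_params <- function(algorithm, mode) {
  switch(algorithm,
    KNN = list(n_neighbors = 5L, leaf = 30L),
    DT  = list(),
    RF  = list(n_estimators = 200L,
               criterion = if (mode == "classifier") "gini" else "variance"),
    MLP = list(hidden = 100L, tol = 1e-6, max_iter = 20L, decay = 1e-4),
    GB  = list(n_estimators = 100L, max_depth = 7L, learning_rate = 0.1),
    ADA = list(n_estimators = 50L, learning_rate = 1,
               base_depth = if (mode == "classifier") 1L else 3L),
    NBA = list()
  )
}

#' Configure a link predictor
#'
#' Uniform configuration for the seven prediction engines: k-nearest
#' neighbours (KNN), decision tree (DT), random forest (RF), multilayer
#' perceptron (MLP), gradient boosting (GB), AdaBoost (ADA) and naive Bayes
#' (NBA, classifier only). Default hyperparameters are the ones the
#' framework was characterised with: KNN 5 neighbours; RF 200 trees (Gini
#' impurity for classification); MLP one hidden layer of 100 units,
#' convergence tolerance 1e-6, at most 20 iterations (kept as stated even
#' though convergence warnings are expected; override via `params`); GB 100
#' boosting stages of depth 7; DT/ADA/NBA engine defaults.
#'
#' @param algorithm One of `"KNN"`, `"DT"`, `"RF"`, `"MLP"`, `"GB"`,
#'   `"ADA"`, `"NBA"`.
#' @param mode `"classifier"` (binary link prediction, probability-like
#'   scores) or `"regressor"` (weight prediction).
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed making seedable engines deterministic.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(algorithm = "GB",
                             mode = c("classifier", "regressor"),
                             params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  mode <- match.arg(mode)
  if (algorithm == "NBA" && mode == "regressor") {
    stop("UnknownMethod: NBA supports classification only")
  }
  p <- utils::modifyList(default_params(algorithm, mode), params)
  structure(list(algorithm = algorithm, mode = mode, params = p,
                 seed = as.integer(seed)),
            class = "predictor_config")
}

#' @export
print.predictor_config <- function(x, ...) {
  cat("<predictor_config> ", x$algorithm, " (", x$mode, "), seed ", x$seed,
      "\n  params: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

as_feature_df <- function(x) {
  df <- as.data.frame(x)
  names(df) <- colnames(x)
  df
}

#' Fit a configured predictor on a design matrix
#'
#' @param config A [predictor_config()].
#' @param dm A labelled [build_design_matrix()] result (binary labels for
#'   classifiers, real weights for regressors).
#' @return An object of class `fln_predictor` holding the fitted engine,
#'   the configuration and training metadata.
#' @export
fit_predictor <- function(config, dm) {
  stopifnot(inherits(config, "predictor_config"),
            inherits(dm, "design_matrix"))
  x <- dm$x
  y <- dm$y
  if (is.null(y) || nrow(x) == 0) stop("EmptyTrainingSet: no labelled pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("NonFiniteFeature")
  p <- config$params
  if (config$mode == "classifier") {
    if (length(unique(y)) < 2) {
      stop("DegenerateLabels: a classifier needs both classes in training")
    }
    yf <- factor(y, levels = c(0, 1))
  }
  set.seed(config$seed)
  model <- switch(config$algorithm,
    KNN = if (config$mode == "classifier") {
      caret::knn3(x, yf, k = p$n_neighbors)
    } else {
      caret::knnreg(x, y, k = p$n_neighbors)
    },
    DT = {
      df <- as_feature_df(x)
      df$.y <- if (config$mode == "classifier") yf else y
      rpart::rpart(.y ~ ., data = df,
                   method = if (config$mode == "classifier") "class" else "anova")
    },
    RF = randomForest::randomForest(
      x, if (config$mode == "classifier") yf else y,
      ntree = p$n_estimators
    ),
    MLP = {
      nw <- (ncol(x) + 1L) * p$hidden + (p$hidden + 1L)
      suppressWarnings(nnet::nnet(
        x, y, size = p$hidden, maxit = p$max_iter, reltol = p$tol,
        decay = p$decay, MaxNWts = nw + 10L, trace = FALSE,
        entropy = config$mode == "classifier",
        linout = config$mode == "regressor"
      ))
    },
    GB = xgboost::xgboost(
      x, if (config$mode == "classifier") yf else y,
      nrounds = p$n_estimators, max_depth = p$max_depth,
      learning_rate = p$learning_rate, nthreads = 1L, verbosity = 0,
      seed = config$seed
    ),
    ADA = if (config$mode == "classifier") {
      fit_adaboost_samme(x, y, p$n_estimators, p$learning_rate, p$base_depth)
    } else {
      fit_adaboost_r2(x, y, p$n_estimators, p$learning_rate, p$base_depth)
    },
    NBA = e1071::naiveBayes(as_feature_df(x), yf)
  )
  structure(
    list(config = config, model = model, spec = dm$spec,
         n_features = ncol(x), n_train = nrow(x),
         injected_train = dm$injected_train),
    class = "fln_predictor"
  )
}

#' Predict scores or weights for new pairs
#'
#' Classifiers return a probability-like score in \[0, 1\] per pair (the
#' positive-class probability where the engine provides one, else a
#' min-max-scaled decision value), suitable for ROC construction.
#' Regressors return real weights; outputs outside \[0, 7\] are kept but the
#' result carries an `out_of_range` attribute flagging them.
#'
#' @param handle A fitted [fit_predictor()] object.
#' @param dm A [build_design_matrix()] result (labels not required).
#' @return Numeric vector, one value per pair in `dm$pairs`.
#' @export
predict_pairs <- function(handle, dm) {
  stopifnot(inherits(handle, "fln_predictor"))
  x <- if (inherits(dm, "design_matrix")) dm$x else dm
  if (ncol(x) != handle$n_features) {
    stop("FeatureLengthMismatch: got ", ncol(x), " features, model expects ",
         handle$n_features)
  }
  if (nrow(x) == 0) return(numeric(0))
  cfg <- handle$config
  classifier <- cfg$mode == "classifier"
  out <- switch(cfg$algorithm,
    KNN = if (classifier) predict(handle$model, x, type = "prob")[, "1"]
          else predict(handle$model, x),
    DT = {
      df <- as_feature_df(x)
      if (classifier) predict(handle$model, df, type = "prob")[, "1"]
      else predict(handle$model, df)
    },
    RF = if (classifier) predict(handle$model, x, type = "prob")[, "1"]
         else predict(handle$model, x),
    MLP = {
      pr <- drop(predict(handle$model, x))
      if (classifier) pmin(pmax(pr, 0), 1) else pr
    },
    GB = predict(handle$model, x),
    ADA = predict_adaboost(handle$model, x),
    NBA = predict(handle$model, as_feature_df(x), type = "raw")[, "1"]
  )
  out <- unname(as.numeric(out))
  if (classifier) {
    if (any(out < 0 | out > 1)) { # decision values: rescale to a ranking
      rng <- range(out)
      out <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else rep(0.5, length(out))
    }
  } else {
    attr(out, "out_of_range") <- which(out < 0 | out > 7)
  }
  out
}

# --- AdaBoost over rpart base learners -------------------------------------
# No boosting-with-reweighting engine ships in the dependency stack, so the
# two textbook variants are implemented here: SAMME (discrete, classifier)
# and AdaBoost.R2 (regressor, linear loss, weighted-median aggregation).

rpart_weighted <- function(x, y, wts, depth, method) {
  df <- as_feature_df(x)
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, weights = wts, method = method,
               control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                              minsplit = 2, xval = 0))
}

fit_adaboost_samme <- function(x, y, n_estimators, learning_rate, depth) {
  n <- nrow(x)
  wts <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  for (b in seq_len(n_estimators)) {
    fit <- rpart_weighted(x, yf, wts * n, depth, "class")
    pred <- predict(fit, as_feature_df(x), type = "class")
    err <- sum(wts * (pred != yf)) / sum(wts)
    if (err >= 0.5) break
    if (err <= 0) { stumps[[b]] <- fit; alphas[b] <- 10; break }
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[b]] <- fit; alphas[b] <- alpha
    wts <- wts * exp(alpha * (pred != yf))
    wts <- wts / sum(wts)
  }
  if (length(stumps) == 0) { # unboostable: fall back to a single tree
    stumps <- list(rpart_weighted(x, yf, rep(1, n), depth, "class"))
    alphas <- 1
  }
  structure(list(kind = "samme", stumps = stumps, alphas = alphas),
            class = "finlink_ada")
}

fit_adaboost_r2 <- function(x, y, n_estimators, learning_rate, depth) {
  n <- nrow(x)
  wts <- rep(1 / n, n)
  stumps <- list(); betas <- numeric(0)
  for (b in seq_len(n_estimators)) {
    fit <- rpart_weighted(x, y, wts * n, depth, "anova")
    pred <- predict(fit, as_feature_df(x))
    ae <- abs(pred - y)
    emax <- max(ae)
    if (emax <= 0) { stumps[[b]] <- fit; betas[b] <- 1e-10; break }
    loss <- ae / emax
    ebar <- sum(wts * loss)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    stumps[[b]] <- fit; betas[b] <- beta
    wts <- wts * beta^(learning_rate * (1 - loss))
    wts <- wts / sum(wts)
  }
  if (length(stumps) == 0) {
    stumps <- list(rpart_weighted(x, y, rep(1, n), depth, "anova"))
    betas <- 0.5
  }
  structure(list(kind = "r2", stumps = stumps, betas = betas),
            class = "finlink_ada")
}

predict_adaboost <- function(model, x) {
  df <- as_feature_df(x)
  if (model$kind == "samme") {
    votes <- vapply(model$stumps, function(s) {
      as.numeric(predict(s, df, type = "class") == "1")
    }, numeric(nrow(df)))
    votes <- matrix(votes, nrow = nrow(df))
    drop(votes %*% model$alphas) / sum(model$alphas)
  } else {
    preds <- vapply(model$stumps, function(s) predict(s, df),
                    numeric(nrow(df)))
    preds <- matrix(preds, nrow = nrow(df))
    lw <- log(1 / model$betas)
    # weighted median over estimators, per observation
    apply_weighted_median(preds, lw)
  }
}

apply_weighted_median <- function(preds, lw) {
  vapply(seq_len(nrow(preds)), function(i) {
    v <- preds[i, ]
    o <- order(v)
    cw <- cumsum(lw[o])
    v[o][which(cw >= 0.5 * sum(lw))[1]]
  }, numeric(1))
}

#' @export
print.fln_predictor <- function(x, ...) {
  cat("<fln_predictor> ", x$config$algorithm, " (", x$config$mode,
      "), trained on ", x$n_train, " pairs x ", x$n_features,
      " features (", x$spec, ")\n", sep = "")
  invisible(x)
}
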