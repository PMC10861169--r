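CLASSICAL_METHODS <- c("CN2", "PA2", "AA2", "RA2", "JA2")

# Shared quantities over the training view w_train (rows = observed targets,
# columns = all areas). w(z, x) is the weight of the out-link x -> z, i.e.
# entry w_train[z, x]; out-strength S(x) and out-neighbourhood size g(x) are
# therefore column sums over the training rows.
classical_env <- function(w_train, gamma_includes_self = FALSE) {
  if (nrow(w_train) == 0) stop("EmptyTrainingSet: no training targets")
  S <- colSums(w_train)
  g <- colSums(w_train > 0)
  if (gamma_includes_self) {
    # the self term carries zero weight but enlarges |Gamma_o(x)| by one
    # whenever x is itself an observed target
    g[colnames(w_train) %in% rownames(w_train)] <-
      g[colnames(w_train) %in% rownames(w_train)] + 1
  }
  list(w = w_train, S = S, g = g, targets = rownames(w_train))
}

#' Classical out-neighbourhood link-predictor scores
#'
#' Scores every requested ordered pair (u, v) with one of the five classical
#' predictors adapted to retrograde-tracing data, where only out-link
#' information (rows of injected targets) is available for every area:
#' common neighbours (CN2), preferential attachment (PA2), Adamic-Adar
#' (AA2), resource allocation (RA2) and Jaccard (JA2). All five are
#' symmetric in (u, v).
#'
#' @param method One of `"CN2"`, `"PA2"`, `"AA2"`, `"RA2"`, `"JA2"`.
#' @param pairs Data frame with character columns `source` and `target`
#'   (area names, no self pairs).
#' @param w_train Weight matrix restricted to the training targets (rows).
#' @param gamma_includes_self If `TRUE`, the out-neighbourhood of an area
#'   that is itself an observed target counts the area once more (a
#'   zero-weight self term). Default `FALSE`.
#' @return A tibble `source, target, method, score`.
#' @details AA2 uses the natural logarithm and skips common-neighbour terms
#'   whose out-strength is at most 1 (non-positive log); RA2 skips zero
#'   out-strength terms; a PA2 factor with empty out-neighbourhood is 0;
#'   JA2 is 0 when both endpoint profiles are empty.
#' @export
#' @examples
#' w <- matrix(c(2, 0, 4, 6), 2, 2,
#'             dimnames = list(c("z1", "z2"), c("u", "v")))
#' w <- cbind(w, z1 = c(0, 0), z2 = c(0, 0))
#' classical_score_all("CN2", data.frame(source = "u", target = "v"), w)
classical_score_all <- function(method, pairs, w_train,
                                gamma_includes_self = FALSE) {
  method <- match.arg(method, CLASSICAL_METHODS)
  pairs <- tibble::as_tibble(pairs)[c("source", "target")]
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, method = character(), score = numeric()))
  }
  env <- classical_env(w_train, gamma_includes_self)
  areas <- colnames(w_train)
  miss <- setdiff(unique(c(pairs$source, pairs$target)), areas)
  if (length(miss)) stop("MissingArea: ", paste(miss, collapse = ", "))
  U <- env$w[, pairs$source, drop = FALSE] # |I_train| x P, columns w(., u)
  V <- env$w[, pairs$target, drop = FALSE]
  score <- switch(method,
    CN2 = 0.5 * (env$S[pairs$source] + env$S[pairs$target]),
    PA2 = {
      f <- ifelse(env$g > 0, env$S / pmax(env$g, 1), 0)
      unname(f[pairs$source] * f[pairs$target])
    },
    AA2 = {
      str_z <- env$S[env$targets]
      keep <- str_z > 1
      if (!any(keep)) rep(0, nrow(pairs)) else {
        inv <- 1 / log(str_z[keep])
        0.5 * colSums((U[keep, , drop = FALSE] + V[keep, , drop = FALSE]) * inv)
      }
    },
    RA2 = {
      str_z <- env$S[env$targets]
      keep <- str_z > 0
      if (!any(keep)) rep(0, nrow(pairs)) else {
        inv <- 1 / str_z[keep]
        colSums((U[keep, , drop = FALSE] + V[keep, , drop = FALSE]) * inv)
      }
    },
    JA2 = {
      num <- colSums(pmin(U, V))
      den <- colSums(pmax(U, V))
      ifelse(den > 0, num / den, 0)
    }
  )
  dplyr::mutate(pairs, method = method, score = unname(score))
}

#' Score a single ordered pair with a classical predictor
#'
#' @inheritParams classical_score_all
#' @param u,v Source and target area names (u != v).
#' @return A scalar score.
#' @export
classical_score <- function(method, u, v, w_train,
                            gamma_includes_self = FALSE) {
  stopifnot(u != v)
  classical_score_all(method, tibble::tibble(source = u, target = v),
                      w_train, gamma_includes_self)$score
}
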