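# Model-agnostic Shapley attribution with marginal (background
# replacement) imputation: absent features take their value from a
# background row, so a coalition's value is the model's prediction on
# the spliced point. Two estimators: exhaustive coalition enumeration
# (exact, n <= ~12) and antithetic permutation sampling.

as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  function(X) as.numeric(predict(model, X))
}

#' Shapley values of model predictions
#'
#' Estimates per-sample, per-feature Shapley values of `model` at the
#' rows of `X`, with absent features imputed from `background`. The
#' default estimator walks random feature permutations in antithetic
#' pairs (each sampled order and its reverse), accumulating the
#' marginal change in prediction as each feature switches from its
#' background value to the explained row's value. `exact = TRUE`
#' enumerates all 2^n coalitions against the full background instead
#' (feasible for small n; used as the oracle in tests).
#'
#' @param model a fitted model with a `predict` method (e.g.
#'   [leafstack()]), or a function `X -> predictions`.
#' @param X data.frame of rows to explain.
#' @param background data.frame of reference rows (same columns).
#' @param n_perm number of sampled permutations (rounded up to even).
#' @param seed RNG seed.
#' @param exact enumerate all coalitions instead of sampling.
#' @return object of class `shap_matrix`: `values` (m x n), `base_value`
#'   (mean background prediction), `residuals` (per-row additivity
#'   residual `base + sum(phi) - prediction`), `prediction`, `X`.
#' @export
shapley_values <- function(model, X, background, n_perm = 200L, seed = 1L,
                           exact = FALSE) {
  pf <- as_predict_fun(model)
  X <- as.data.frame(X); background <- as.data.frame(background)
  if (!identical(names(X), names(background)))
    stop_input("X and background must have identical columns")
  if (nrow(background) < 1L) stop_input("background must have >= 1 row")
  n <- ncol(X); m <- nrow(X)
  base_value <- mean(pf(background))
  pred <- pf(X)
  phi <- if (exact) {
    shap_exact(pf, X, background)
  } else {
    shap_sample(pf, X, background, n_perm, seed)
  }
  dimnames(phi) <- list(NULL, names(X))
  structure(list(values = phi, base_value = base_value,
                 prediction = pred,
                 residuals = base_value + rowSums(phi) - pred,
                 X = X), class = "shap_matrix")
}

shap_sample <- function(pf, X, background, n_perm, seed) {
  n <- ncol(X); m <- nrow(X)
  P <- 2L * ceiling(n_perm / 2)
  b <- nrow(background)
  bg <- as.matrix(background)
  phi <- matrix(0, m, n)
  with_seed(seed, {
    perms <- lapply(seq_len(P / 2L), function(p) sample(n))
    # cycle a shuffled background for even coverage (variance reduction
    # over iid draws; with P/2 a multiple of b the background mean is
    # matched exactly)
    zi <- rep_len(sample(b), P / 2L)
    for (i in seq_len(m)) {
      x <- as.numeric(X[i, ])
      # one evaluation batch per explained row: P chains of n+1 points
      pts <- matrix(0, P * (n + 1L), n)
      row_at <- 0L
      for (p in seq_len(P / 2L)) {
        z <- bg[zi[p], ]
        for (ord in list(perms[[p]], rev(perms[[p]]))) {
          cur <- z
          pts[row_at + 1L, ] <- cur
          for (s in seq_len(n)) {
            cur[ord[s]] <- x[ord[s]]
            pts[row_at + 1L + s, ] <- cur
          }
          row_at <- row_at + n + 1L
        }
      }
      v <- pf(as.data.frame(`colnames<-`(pts, names(X))))
      row_at <- 0L
      acc <- numeric(n)
      for (p in seq_len(P / 2L)) {
        for (ord in list(perms[[p]], rev(perms[[p]]))) {
          d <- diff(v[row_at + seq_len(n + 1L)])
          acc[ord] <- acc[ord] + d
          row_at <- row_at + n + 1L
        }
      }
      phi[i, ] <- acc / P
    }
  })
  phi
}

shap_exact <- function(pf, X, background) {
  n <- ncol(X); m <- nrow(X)
  if (n > 14L) stop_input("exact enumeration limited to 14 features")
  b <- nrow(background)
  bg <- as.matrix(background)
  nS <- 2L^n
  masks <- matrix(FALSE, nS, n)
  for (j in seq_len(n))
    masks[, j] <- bitwAnd(seq_len(nS) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  sizes <- rowSums(masks)
  # Shapley kernel weights |S|! (n-|S|-1)! / n!
  wt <- exp(lfactorial(sizes) + lfactorial(n - sizes - 1) - lfactorial(n))
  phi <- matrix(0, m, n)
  for (i in seq_len(m)) {
    x <- as.numeric(X[i, ])
    # value of every coalition: mean over the full background
    pts <- matrix(0, nS * b, n)
    for (k in seq_len(b)) {
      block <- matrix(bg[k, ], nS, n, byrow = TRUE)
      block[masks] <- matrix(x, nS, n, byrow = TRUE)[masks]
      pts[(k - 1L) * nS + seq_len(nS), ] <- block
    }
    v_all <- pf(as.data.frame(`colnames<-`(pts, names(X))))
    v <- rowMeans(matrix(v_all, nS, b))
    idx <- seq_len(nS) - 1L
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(idx, bit) == 0L)
      phi[i, j] <- sum(wt[without] * (v[without + bit] - v[without]))
    }
  }
  phi
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d samples x %d features, base %.4f, max |residual| %.2g\n",
              nrow(x$values), ncol(x$values), x$base_value,
              max(abs(x$residuals))))
  invisible(x)
}

#' Relative average absolute Shapley contributions
#'
#' For each feature j, \eqn{RV_j = 100 \cdot \overline{|\phi_j|} /
#' \sum_k \overline{|\phi_k|}} -- the feature's share of the total mean
#' absolute attribution, in percent. Features are also summed by
#' surface group (front `_f`, rear `_r`, leaf `LP`/`AP`).
#'
#' @param shap a [shapley_values()] result.
#' @return object of class `contribution_report`: `rv` (named percent
#'   vector summing to 100), `ranking` (feature names by decreasing
#'   contribution), `groups` (percent per front/rear/leaf/other).
#' @export
rv_contributions <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  mean_abs <- colMeans(abs(shap$values))
  tot <- sum(mean_abs)
  if (tot == 0) stop_input("all attributions are zero; RV undefined")
  rv <- 100 * mean_abs / tot
  nm <- names(rv)
  grp <- ifelse(nm %in% c("LP", "AP"), "leaf",
                ifelse(endsWith(nm, "_f"), "front",
                       ifelse(endsWith(nm, "_r"), "rear", "other")))
  groups <- vapply(split(rv, grp), sum, numeric(1))
  structure(list(rv = rv, ranking = nm[order(-rv)], groups = groups),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("<contribution_report> group shares (%):\n")
  print(round(x$groups, 1))
  cat("top features:", paste(head(x$ranking, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Dependence profile of a feature's Shapley values
#'
#' Tabulates one feature's Shapley value against another feature's
#' value (by default the airing-period code), the raw material of a
#' partial-dependence-style interaction plot. Per-level means of the
#' conditioning feature are attached for discrete conditioners.
#'
#' @param shap a [shapley_values()] result.
#' @param feature_b feature whose attribution is profiled.
#' @param feature_a conditioning feature (default `"AP"`).
#' @return list with `samples` (data.frame `a`, `b`, `phi_b`, one row
#'   per explained sample) and `level_means` (mean `phi_b` per distinct
#'   `a`).
#' @export
dependence_profile <- function(shap, feature_b, feature_a = "AP") {
  stopifnot(inherits(shap, "shap_matrix"))
  for (f in c(feature_a, feature_b))
    if (!f %in% colnames(shap$values)) stop_input("no such feature: ", f)
  d <- data.frame(a = shap$X[[feature_a]], b = shap$X[[feature_b]],
                  phi_b = shap$values[, feature_b])
  lm_ <- aggregate(phi_b ~ a, d, mean)
  names(lm_) <- c(feature_a, "mean_phi_b")
  list(samples = d, level_means = lm_)
}
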