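# Cross-validated evaluation of candidate learners and entropy-weight
# composite scoring.

#' Seeded k-fold assignment
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold labels `1..k`, a true partition,
#'   reproducible under `seed`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (n < 2L * k) stop_input("need at least 2k rows for ", k, "-fold CV")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

indicator_names <- function() {
  m <- c("r2", "mse", "mae", "mape", "evs")
  c(paste0(m, "_mean"), paste0(m, "_std"), paste0(m, "_cv"))
}

#' 5-fold cross-validation indicator report
#'
#' Fits a learner on each training fold, scores the held-out fold with
#' the five regression metrics, and summarizes each metric by its mean,
#' standard deviation and coefficient of variation across folds -- 15
#' indicators in all. The out-of-fold prediction vector is retained for
#' stacking, and wall-clock runtime is recorded as a complexity proxy
#' (reported, never scored).
#'
#' @param spec a [learner_spec()].
#' @param train data.frame with the target column.
#' @param target target column name.
#' @param k folds (default 5).
#' @param seed RNG seed for the fold assignment and learner fits.
#' @return object of class `cv_report`: `learner`, `family`, `folds`
#'   (per-fold [regression_metrics()]), `indicators` (named length-15),
#'   `oof` (out-of-fold predictions, length `nrow(train)`),
#'   `fold_id`, `runtime` seconds.
#' @export
cv_indicators <- function(spec, train, target = "moisture", k = 5L,
                          seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  folds <- make_folds(nrow(train), k, seed)
  X <- train[setdiff(names(train), target)]
  y <- train[[target]]
  oof <- numeric(nrow(train))
  per_fold <- vector("list", k)
  t0 <- proc.time()[["elapsed"]]
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- spec$fit(X[tr, , drop = FALSE], y[tr], spec$params,
                    child_seed(seed, fold))
    pred <- spec$predict(fit, X[!tr, , drop = FALSE])
    oof[!tr] <- pred
    per_fold[[fold]] <- regression_metrics(y[!tr], pred)
  }
  runtime <- proc.time()[["elapsed"]] - t0
  M <- vapply(per_fold, function(m) unlist(m), numeric(5))  # 5 x k
  means <- rowMeans(M)
  stds <- apply(M, 1, sd)
  cvs <- ifelse(means != 0, stds / means, NA_real_)
  ind <- setNames(c(means, stds, cvs), indicator_names())
  structure(list(learner = spec$name, family = spec$family,
                 folds = per_fold, indicators = ind, oof = oof,
                 fold_id = folds, runtime = runtime),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s): R2 %.4f +/- %.4f, %.2fs\n",
              x$learner, x$family, x$indicators[["r2_mean"]],
              x$indicators[["r2_std"]], x$runtime))
  invisible(x)
}

#' Entropy weights for a multi-indicator decision matrix
#'
#' The entropy weight method: each indicator column is min--max
#' normalized with its direction ("positive": larger is better;
#' "negative": smaller is better), column shares are formed with an
#' epsilon shift, the Shannon entropy \eqn{e_j = -\frac{1}{\ln
#' n}\sum_i p_{ij}\ln p_{ij}} measures how little the indicator
#' discriminates between alternatives, and the weight is the
#' normalized complement \eqn{w_j = (1-e_j)/\sum_j(1-e_j)}. An
#' indicator identical across alternatives gets weight 0.
#'
#' @param M numeric matrix, alternatives (models) x indicators.
#' @param directions character vector, `"positive"` or `"negative"` per
#'   column.
#' @param eps shift applied before logarithms.
#' @return list with `weights` (sum to 1), `normalized` matrix and
#'   `entropy` per indicator.
#' @export
entropy_weights <- function(M, directions, eps = 1e-12) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2L) stop_input("entropy weights need at least 2 alternatives")
  if (length(directions) != ncol(M))
    stop_input("one direction per indicator column required")
  if (!all(directions %in% c("positive", "negative")))
    stop_input("directions must be 'positive' or 'negative'")
  norm <- M
  for (j in seq_len(ncol(M))) {
    rng <- range(M[, j])
    norm[, j] <- if (rng[1] == rng[2]) rep(0.5, n)
    else if (directions[j] == "positive") (M[, j] - rng[1]) / diff(rng)
    else (rng[2] - M[, j]) / diff(rng)
  }
  P <- sweep(norm + eps, 2, colSums(norm + eps), "/")
  e <- -colSums(P * log(P)) / log(n)
  d <- 1 - e
  d[abs(d) < 1e-12] <- 0
  if (sum(d) == 0) stop_input("no indicator discriminates the alternatives")
  list(weights = d / sum(d), normalized = norm, entropy = e)
}

#' Entropy-weighted composite score of candidate learners
#'
#' Stacks every report's 15 indicators into a models x 15 decision
#' matrix (R2_mean and EVS_mean positive, the remaining 13 negative),
#' weights the indicators by the entropy weight method and returns the
#' weighted normalized sum per model. Runtime is excluded from the
#' score and reported alongside.
#'
#' @param reports list of [cv_indicators()] reports (>= 2).
#' @return list with `scores` (named, in `[0, 1]`, higher is better),
#'   `weights`, `matrix`, `runtime`.
#' @export
composite_score <- function(reports) {
  if (length(reports) < 2L)
    stop_input("composite score needs at least 2 models")
  stopifnot(all(vapply(reports, inherits, logical(1), "cv_report")))
  M <- t(vapply(reports, function(r) r$indicators,
                numeric(length(indicator_names()))))
  rownames(M) <- vapply(reports, `[[`, character(1), "learner")
  directions <- ifelse(colnames(M) %in% c("r2_mean", "evs_mean"),
                       "positive", "negative")
  ew <- entropy_weights(M, directions)
  scores <- drop(ew$normalized %*% ew$weights)
  list(scores = setNames(scores, rownames(M)), weights = ew$weights,
       matrix = M,
       runtime = setNames(vapply(reports, `[[`, numeric(1), "runtime"),
                          rownames(M)))
}

#' Select base learners by family, plus a meta-learner
#'
#' Picks the top-scoring learner within each of the three families
#' (single, bagging, boosting) as the stacking base learners; ties go
#' to registry order. The meta-learner is the least complex adequate
#' single-family model: `"LR"` when present, otherwise the
#' single-family model with the shortest recorded runtime.
#'
#' @param scores named score vector from [composite_score()].
#' @param specs named list of [learner_spec()]s covering the scored
#'   models.
#' @param runtime optional named runtime vector used for the meta
#'   tie-break.
#' @return list with `bases` (character, one per family) and `meta`.
#' @export
select_base_learners <- function(scores, specs, runtime = NULL) {
  fam <- vapply(specs, `[[`, character(1), "family")
  fam <- fam[names(scores)]
  bases <- character(0)
  for (f in c("single", "bagging", "boosting")) {
    members <- names(scores)[fam == f]
    if (length(members) == 0L) stop_input("no candidate in family: ", f)
    bases <- c(bases, members[which.max(scores[members])])
  }
  singles <- names(scores)[fam == "single"]
  meta <- if ("LR" %in% singles) "LR"
  else if (!is.null(runtime)) singles[which.min(runtime[singles])]
  else singles[1]
  list(bases = bases, meta = meta)
}
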