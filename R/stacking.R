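#' Two-layer stacking ensemble for leaf moisture
#'
#' Fits the package's core estimator: a heterogeneous two-layer
#' stacking ensemble. Each base learner is cross-validated on the
#' training data and its out-of-fold predictions become one column of a
#' new feature set; the meta-learner is fitted on those columns against
#' the target, so it never sees a base prediction made by a model that
#' was trained on the same sample. For inference the base learners are
#' refitted on the full training set (or, optionally, fold models are
#' averaged) and the meta-learner combines their predictions.
#'
#' @param formula model formula, e.g. `moisture ~ .`.
#' @param data training data.frame.
#' @param base_learners names of the base learners (default the trio
#'   MLP, RF, GBDT chosen by entropy-weight scoring on the synthetic
#'   campaign).
#' @param meta meta-learner name (default `"LR"`).
#' @param registry learner registry, see [learner_registry()].
#' @param params optional named list of per-learner hyperparameter
#'   overrides, e.g. `list(RF = list(num_trees = 100))`.
#' @param k folds used to build the out-of-fold meta features.
#' @param seed RNG seed (folds and learner fits).
#' @param clip length-2 numeric; predictions are clipped into this
#'   range with a message (moisture is a fraction). `NULL` disables.
#' @param inference `"refit"` (default) predicts with base learners
#'   refitted on the full training set; `"fold_average"` averages the k
#'   fold models instead.
#' @return object of class `leafstack` with methods `print`, `summary`,
#'   `predict`, `coef`, `fitted`, `residuals` and `plot`.
#' @export
leafstack <- function(formula, data, base_learners = c("MLP", "RF", "GBDT"),
                      meta = "LR", registry = learner_registry(),
                      params = list(), k = 5L, seed = 1L, clip = c(0, 1),
                      inference = c("refit", "fold_average")) {
  inference <- match.arg(inference)
  mf <- stats::model.frame(formula, data)
  y <- unname(stats::model.response(mf))
  X <- mf[-1]
  missing <- setdiff(c(base_learners, meta), names(registry))
  if (length(missing))
    stop_input("unknown learner(s): ", paste(missing, collapse = ", "))
  specs <- registry[base_learners]
  for (nm in names(params)) {
    if (nm %in% names(specs))
      specs[[nm]]$params[names(params[[nm]])] <- params[[nm]]
  }
  folds <- make_folds(nrow(X), k, seed)
  oof <- matrix(NA_real_, nrow(X), length(specs),
                dimnames = list(NULL, base_learners))
  fold_models <- list()
  for (b in seq_along(specs)) {
    sp <- specs[[b]]
    fm <- vector("list", k)
    for (fold in seq_len(k)) {
      tr <- folds != fold
      fit <- sp$fit(X[tr, , drop = FALSE], y[tr], sp$params,
                    child_seed(seed, b * 100L + fold))
      oof[!tr, b] <- sp$predict(fit, X[!tr, , drop = FALSE])
      fm[[fold]] <- fit
    }
    fold_models[[base_learners[b]]] <- fm
  }
  stopifnot(!anyNA(oof))                    # no-leakage bookkeeping
  meta_spec <- registry[[meta]]
  meta_fit <- meta_spec$fit(as.data.frame(oof), y, meta_spec$params,
                            child_seed(seed, 999L))
  full_models <- lapply(seq_along(specs), function(b) {
    specs[[b]]$fit(X, y, specs[[b]]$params, child_seed(seed, b * 100L))
  })
  names(full_models) <- base_learners
  obj <- structure(list(
    call = match.call(), terms = stats::terms(mf),
    base_learners = base_learners, meta = meta,
    specs = specs, meta_spec = meta_spec,
    full_models = full_models, fold_models = fold_models,
    meta_fit = meta_fit, oof = oof, fold_id = folds,
    y = y, clip = clip, inference = inference, seed = seed,
    feature_names = names(X)), class = "leafstack")
  obj$fitted <- predict(obj, data)
  obj
}

base_predictions <- function(object, X) {
  out <- matrix(NA_real_, nrow(X), length(object$base_learners),
                dimnames = list(NULL, object$base_learners))
  for (b in seq_along(object$base_learners)) {
    sp <- object$specs[[b]]
    if (object$inference == "refit") {
      out[, b] <- sp$predict(object$full_models[[b]], X)
    } else {
      P <- vapply(object$fold_models[[b]], function(f) sp$predict(f, X),
                  numeric(nrow(X)))
      out[, b] <- rowMeans(matrix(P, nrow = nrow(X)))
    }
  }
  out
}

#' Predict moisture from a fitted stacking ensemble
#'
#' @param object a [leafstack()] model.
#' @param newdata data.frame containing the training feature columns.
#' @param layers `"meta"` (default) for the final prediction,
#'   `"bases"` for the base-learner prediction matrix.
#' @param ... unused.
#' @return numeric predictions (or a matrix for `layers = "bases"`).
#' @export
predict.leafstack <- function(object, newdata,
                              layers = c("meta", "bases"), ...) {
  layers <- match.arg(layers)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss))
    stop_input("newdata lacks feature column(s): ",
               paste(miss, collapse = ", "))
  X <- newdata[object$feature_names]
  bp <- base_predictions(object, X)
  if (layers == "bases") return(bp)
  p <- object$meta_spec$predict(object$meta_fit, as.data.frame(bp))
  if (!is.null(object$clip)) {
    n_out <- sum(p < object$clip[1] | p > object$clip[2])
    if (n_out > 0) {
      message("clipping ", n_out, " prediction(s) into [",
              object$clip[1], ", ", object$clip[2], "]")
      p <- pmin(pmax(p, object$clip[1]), object$clip[2])
    }
  }
  as.numeric(p)
}

#' @export
print.leafstack <- function(x, ...) {
  cat("Two-layer stacking ensemble\n")
  cat("  bases:", paste(x$base_learners, collapse = ", "),
      " | meta:", x$meta, "\n")
  cat(sprintf("  trained on %d samples, %d features, %d-fold meta features\n",
              length(x$y), length(x$feature_names),
              max(x$fold_id)))
  invisible(x)
}

#' @export
coef.leafstack <- function(object, ...) {
  f <- object$meta_fit
  if (inherits(f, "lm")) coef(f) else
    stop_input("meta-learner '", object$meta, "' has no coefficients")
}

#' @export
fitted.leafstack <- function(object, ...) object$fitted

#' @export
residuals.leafstack <- function(object, ...) object$y - object$fitted

#' @export
summary.leafstack <- function(object, ...) {
  oof_meta <- object$meta_spec$predict(object$meta_fit,
                                       as.data.frame(object$oof))
  structure(list(model = object,
                 train_metrics = regression_metrics(object$y,
                                                    object$fitted),
                 oof_metrics = regression_metrics(object$y, oof_meta),
                 base_oof = lapply(
                   setNames(object$base_learners, object$base_learners),
                   function(b) regression_metrics(object$y,
                                                  object$oof[, b]))),
            class = "summary.leafstack")
}

#' @export
print.summary.leafstack <- function(x, ...) {
  print(x$model)
  cat("training fit:      "); print(x$train_metrics)
  cat("out-of-fold stack: "); print(x$oof_metrics)
  for (b in names(x$base_oof)) {
    cat(sprintf("out-of-fold %-5s: ", b)); print(x$base_oof[[b]])
  }
  invisible(x)
}

#' @export
plot.leafstack <- function(x, newdata = NULL, ...) {
  obs <- x$y; pred <- x$fitted; main <- "training set"
  if (!is.null(newdata)) {
    resp <- all.vars(x$terms)[1]
    obs <- newdata[[resp]]
    pred <- predict(x, newdata)
    main <- "new data"
  }
  plot(obs, pred, xlab = "observed moisture", ylab = "predicted moisture",
       main = paste("stacking ensemble,", main), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Evaluate feature-combination schemes
#'
#' Trains and tests the stacking ensemble once per named column scheme
#' under a shared period-stratified split and standardization, and
#' tabulates the test metrics. The default schemes contrast front-only,
#' rear-only, both-surface, surface+leaf, all 36 features, and the
#' filtered subset.
#'
#' @param table feature table with `moisture` and `AP` columns.
#' @param schemes named list of character vectors of feature columns;
#'   `NULL` builds the seven standard schemes (the last being the
#'   two-step filter's subset).
#' @param test_per_period test rows per period for the shared split.
#' @param seed shared RNG seed.
#' @param ... passed to [leafstack()] (e.g. `base_learners`, `params`,
#'   `k`).
#' @return data.frame with one row per scheme: n features and the five
#'   test metrics.
#' @export
run_feature_schemes <- function(table, schemes = NULL,
                                test_per_period = 35L, seed = 1L, ...) {
  if (is.null(schemes)) {
    g <- feature_groups()
    subset15 <- select_features(
      table[c(feature_names(), "moisture")])$retained
    schemes <- list(
      front = g$front,
      rear = g$rear,
      front_rear = c(g$front, g$rear),
      front_leaf = c(g$front, g$leaf),
      rear_leaf = c(g$rear, g$leaf),
      original = feature_names(),
      optimized_subset = subset15)
  }
  for (s in schemes) {
    bad <- setdiff(s, names(table))
    if (length(bad)) stop_input("unknown scheme column(s): ",
                                paste(bad, collapse = ", "))
  }
  sp <- stratified_split(table, test_per_period, seed = seed)
  out <- lapply(names(schemes), function(nm) {
    cols <- schemes[[nm]]
    tr <- sp$train[c(cols, "moisture")]
    te <- sp$test[c(cols, "moisture")]
    std <- standardize_features(tr, te)
    fit <- leafstack(moisture ~ ., std$train, seed = seed, ...)
    m <- regression_metrics(std$test$moisture, predict(fit, std$test))
    data.frame(scheme = nm, n_features = length(cols),
               r2 = m$r2, mse = m$mse, mae = m$mae, mape = m$mape,
               evs = m$evs)
  })
  do.call(rbind, out)
}

#' Score stacking configurations by entropy weights
#'
#' Fits one stacking ensemble per configuration (a base-learner set
#' plus meta-learner), evaluates the five metrics on the training and
#' test sets and the train-test gaps, and scores every configuration
#' with the entropy weight method (test R2/EVS positive; test errors
#' and all absolute gaps negative).
#'
#' @param configs list of `list(bases = c(...), meta = "...")` (>= 2).
#' @param train,test standardized feature tables with `moisture`.
#' @param seed RNG seed shared across configurations.
#' @param ... passed to [leafstack()].
#' @return list with `scores` (named by configuration), `table` of
#'   per-config metrics, `weights`.
#' @export
score_configurations <- function(configs, train, test, seed = 1L, ...) {
  if (length(configs) < 2L) stop_input("need at least 2 configurations")
  nm <- vapply(configs, function(cf)
    paste0(paste(cf$bases, collapse = "+"), "->", cf$meta), character(1))
  rows <- lapply(configs, function(cf) {
    fit <- leafstack(moisture ~ ., train, base_learners = cf$bases,
                     meta = cf$meta, seed = seed, ...)
    mtr <- regression_metrics(train$moisture, predict(fit, train))
    mte <- regression_metrics(test$moisture, predict(fit, test))
    c(test_r2 = mte$r2, test_mse = mte$mse, test_mae = mte$mae,
      test_mape = mte$mape, test_evs = mte$evs,
      gap_r2 = abs(mtr$r2 - mte$r2), gap_mse = abs(mtr$mse - mte$mse),
      gap_mae = abs(mtr$mae - mte$mae),
      gap_mape = abs(mtr$mape - mte$mape),
      gap_evs = abs(mtr$evs - mte$evs))
  })
  M <- do.call(rbind, rows)
  rownames(M) <- nm
  directions <- ifelse(colnames(M) %in% c("test_r2", "test_evs"),
                       "positive", "negative")
  ew <- entropy_weights(M, directions)
  scores <- drop(ew$normalized %*% ew$weights)
  list(scores = setNames(scores, nm), table = as.data.frame(M),
       weights = ew$weights)
}
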