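# Candidate learner registry. Eight regressors in three families:
# single (LR, SVR, MLP), bagging (RF, ET) and boosting (GBDT, XGBoost,
# AdaBoost). Each spec carries fit/predict closures, a hyperparameter
# search space and resolved default hyperparameters. GBDT (least-squares
# gradient boosting) and AdaBoost.R2 are implemented here over rpart
# base trees.

#' Construct a learner specification
#'
#' @param name learner name.
#' @param family one of `"single"`, `"bagging"`, `"boosting"`.
#' @param fit function `(X, y, params, seed)` returning a fitted state.
#' @param predict function `(fit, X)` returning predictions.
#' @param space named list of hyperparameter ranges, each
#'   `list(type = "int"|"num"|"log", min, max)`.
#' @param params named list of resolved hyperparameters.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(name, family, fit, predict, space = list(),
                         params = list()) {
  family <- match.arg(family, c("single", "bagging", "boosting"))
  structure(list(name = name, family = family, fit = fit,
                 predict = predict, space = space, params = params),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("<learner_spec> %s (%s family), %d tunable parameter(s)\n",
              x$name, x$family, length(x$space)))
  invisible(x)
}

# ---- in-package boosting learners ------------------------------------

#' Least-squares gradient boosting over regression trees
#'
#' Classic stagewise gradient boosting: starting from the target mean,
#' each iteration fits an rpart regression tree to the current
#' residuals and adds a shrunken copy of its prediction.
#'
#' @param X data.frame of predictors.
#' @param y numeric target.
#' @param n_trees number of boosting iterations.
#' @param shrinkage learning rate.
#' @param max_depth tree depth limit.
#' @param subsample row fraction sampled (without replacement) per
#'   iteration.
#' @param seed RNG seed for subsampling.
#' @return object of class `gbdt`.
#' @export
gbdt_fit <- function(X, y, n_trees = 150L, shrinkage = 0.1,
                     max_depth = 3L, subsample = 1, seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = 10, xval = 0)
  f <- rep(mean(y), n)
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      rows <- if (subsample < 1) sample(n, max(2L, round(subsample * n)))
      else seq_len(n)
      d <- X[rows, , drop = FALSE]
      d$.resid <- y[rows] - f[rows]
      tree <- rpart::rpart(.resid ~ ., data = d, control = ctrl)
      f <- f + shrinkage * predict(tree, X)
      trees[[t]] <- tree
    }
  })
  structure(list(init = mean(y), trees = trees, shrinkage = shrinkage),
            class = "gbdt")
}

#' @export
predict.gbdt <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  p <- rep(object$init, nrow(newdata))
  for (tree in object$trees) p <- p + object$shrinkage * predict(tree, newdata)
  p
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' AdaBoost.R2 over regression trees
#'
#' Drucker's regression boosting: each round fits an rpart tree on a
#' sample-weight bootstrap, measures linear relative loss, reweights
#' hard samples up, and predicts with the weighted median of the
#' rounds.
#'
#' @inheritParams gbdt_fit
#' @param n_estimators maximum boosting rounds; stops early when the
#'   weighted loss reaches 0.5.
#' @return object of class `adaboost_r2`.
#' @export
adaboost_r2_fit <- function(X, y, n_estimators = 50L, max_depth = 4L,
                            seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = 10, xval = 0)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(n_estimators)) {
      rows <- sample(n, n, replace = TRUE, prob = w)
      d <- X[rows, , drop = FALSE]
      d$.y <- y[rows]
      tree <- rpart::rpart(.y ~ ., data = d, control = ctrl)
      pred <- predict(tree, X)
      err <- abs(pred - y)
      D <- max(err)
      if (D == 0) {                        # perfect fit this round
        trees[[length(trees) + 1L]] <- tree
        betas[length(betas) + 1L] <- 1e-10
        break
      }
      L <- err / D
      ebar <- sum(w * L)
      if (ebar >= 0.5) break
      beta <- ebar / (1 - ebar)
      trees[[length(trees) + 1L]] <- tree
      betas[length(betas) + 1L] <- beta
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  if (length(trees) == 0L) stop_input("AdaBoost.R2 found no usable round")
  structure(list(trees = trees, log_inv_beta = log(1 / betas)),
            class = "adaboost_r2")
}

#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  P <- vapply(object$trees, function(tr) predict(tr, newdata),
              numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  apply(P, 1, weighted_median, w = object$log_inv_beta)
}

# ---- registry --------------------------------------------------------

#' The candidate learner registry
#'
#' Eight regression learners: LR, SVR and MLP (single family), RF and
#' ET (bagging), GBDT, XGBoost and AdaBoost (boosting). Default
#' hyperparameters are modest; each spec's `space` defines the range
#' explored by [ga_tune()].
#'
#' @return named list of [learner_spec()] objects.
#' @export
learner_registry <- function() {
  specs <- list(
    LR = learner_spec(
      "LR", "single",
      fit = function(X, y, params, seed) {
        d <- as.data.frame(X); d$.y <- y
        lm(.y ~ ., data = d)
      },
      predict = function(fit, X) unname(predict(fit, as.data.frame(X)))),
    SVR = learner_spec(
      "SVR", "single",
      fit = function(X, y, params, seed) {
        e1071::svm(x = as.matrix(X), y = y, type = "eps-regression",
                   kernel = "radial", cost = params$cost,
                   gamma = params$gamma, epsilon = params$epsilon)
      },
      predict = function(fit, X) unname(predict(fit, as.matrix(X))),
      space = list(cost = list(type = "log", min = 0.1, max = 100),
                   gamma = list(type = "log", min = 0.005, max = 1),
                   epsilon = list(type = "log", min = 0.001, max = 0.1)),
      params = list(cost = 10, gamma = 0.05, epsilon = 0.01)),
    MLP = learner_spec(
      "MLP", "single",
      fit = function(X, y, params, seed) {
        with_seed(seed,
          nnet::nnet(x = as.matrix(X), y = y, size = params$size,
                     decay = params$decay, linout = TRUE, maxit = 500,
                     trace = FALSE, MaxNWts = 5000))
      },
      predict = function(fit, X) as.numeric(predict(fit, as.matrix(X))),
      space = list(size = list(type = "int", min = 2, max = 16),
                   decay = list(type = "log", min = 1e-4, max = 0.1)),
      params = list(size = 8L, decay = 0.01)),
    RF = learner_spec(
      "RF", "bagging",
      fit = function(X, y, params, seed) {
        X <- as.data.frame(X)
        mtry <- max(1L, min(ncol(X), ceiling(params$mtry_frac * ncol(X))))
        ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                       mtry = mtry, min.node.size = params$min_node,
                       seed = seed, num.threads = 1)
      },
      predict = function(fit, X)
        predict(fit, as.data.frame(X), num.threads = 1)$predictions,
      space = list(num_trees = list(type = "int", min = 50, max = 400),
                   mtry_frac = list(type = "num", min = 0.2, max = 1),
                   min_node = list(type = "int", min = 1, max = 10)),
      params = list(num_trees = 300L, mtry_frac = 0.5, min_node = 3L)),
    ET = learner_spec(
      "ET", "bagging",
      fit = function(X, y, params, seed) {
        X <- as.data.frame(X)
        mtry <- max(1L, min(ncol(X), ceiling(params$mtry_frac * ncol(X))))
        ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                       mtry = mtry, min.node.size = params$min_node,
                       splitrule = "extratrees", replace = FALSE,
                       sample.fraction = 1, seed = seed, num.threads = 1)
      },
      predict = function(fit, X)
        predict(fit, as.data.frame(X), num.threads = 1)$predictions,
      space = list(num_trees = list(type = "int", min = 50, max = 400),
                   mtry_frac = list(type = "num", min = 0.2, max = 1),
                   min_node = list(type = "int", min = 1, max = 10)),
      params = list(num_trees = 300L, mtry_frac = 0.7, min_node = 3L)),
    GBDT = learner_spec(
      "GBDT", "boosting",
      fit = function(X, y, params, seed) {
        gbdt_fit(X, y, n_trees = params$n_trees,
                 shrinkage = params$shrinkage,
                 max_depth = params$max_depth,
                 subsample = params$subsample, seed = seed)
      },
      predict = function(fit, X) predict(fit, X),
      space = list(n_trees = list(type = "int", min = 50, max = 300),
                   shrinkage = list(type = "log", min = 0.02, max = 0.3),
                   max_depth = list(type = "int", min = 2, max = 6),
                   subsample = list(type = "num", min = 0.5, max = 1)),
      params = list(n_trees = 150L, shrinkage = 0.1, max_depth = 3L,
                    subsample = 0.9)),
    XGBoost = learner_spec(
      "XGBoost", "boosting",
      fit = function(X, y, params, seed) {
        xgboost::xgboost(x = as.matrix(X), y = y,
                         nrounds = params$nrounds,
                         learning_rate = params$eta,
                         max_depth = params$max_depth,
                         subsample = params$subsample,
                         nthreads = 1, seed = seed, verbosity = 0)
      },
      predict = function(fit, X) predict(fit, as.matrix(X)),
      space = list(nrounds = list(type = "int", min = 50, max = 300),
                   eta = list(type = "log", min = 0.02, max = 0.3),
                   max_depth = list(type = "int", min = 2, max = 8),
                   subsample = list(type = "num", min = 0.5, max = 1)),
      params = list(nrounds = 150L, eta = 0.1, max_depth = 4L,
                    subsample = 0.9)),
    AdaBoost = learner_spec(
      "AdaBoost", "boosting",
      fit = function(X, y, params, seed) {
        adaboost_r2_fit(X, y, n_estimators = params$n_estimators,
                        max_depth = params$max_depth, seed = seed)
      },
      predict = function(fit, X) predict(fit, X),
      space = list(n_estimators = list(type = "int", min = 20, max = 100),
                   max_depth = list(type = "int", min = 2, max = 8)),
      params = list(n_estimators = 50L, max_depth = 5L))
  )
  specs
}
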