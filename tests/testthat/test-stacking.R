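stack_table <- function(n = 220, seed = 71) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  data.frame(x1 = x1, x2 = x2, x3 = x3,
             moisture = pmin(pmax(0.5 + 0.15 * x1 - 0.1 * x2 +
                                    0.05 * x3^2 + rnorm(n, 0, 0.02),
                                  0.02), 0.98))
}

test_that("stacking builds out-of-fold meta features without leakage", {
  d <- stack_table()
  fit <- leafstack(moisture ~ ., d, base_learners = c("LR", "XGBoost"),
                   meta = "LR", k = 5, seed = 2)
  expect_identical(dim(fit$oof), c(nrow(d), 2L))
  expect_false(anyNA(fit$oof))
  expect_true(all(sort(unique(fit$fold_id)) == 1:5))
  # out-of-fold column reproduces a manual fold-wise refit (no sample
  # predicts itself): recompute fold 1 by hand for the LR base
  tr <- fit$fold_id != 1
  X <- d[c("x1", "x2", "x3")]
  spec <- learner_registry()$LR
  manual <- spec$predict(spec$fit(X[tr, ], d$moisture[tr], spec$params,
                                  leafcure:::child_seed(2, 101L)),
                         X[!tr, ])
  expect_equal(unname(fit$oof[!tr, "LR"]), unname(manual), tolerance = 1e-9)
})

test_that("a single-base stack with a linear meta tracks its base", {
  d <- stack_table(180, 73)
  fit <- leafstack(moisture ~ ., d, base_learners = "LR", meta = "LR",
                   k = 5, seed = 3)
  base_pred <- predict(fit, d, layers = "bases")[, "LR"]
  stack_pred <- predict(fit, d)
  expect_gt(cor(base_pred, stack_pred), 0.999)
  expect_length(coef(fit), 2)                         # intercept + one base
  # residuals/fitted accessors agree
  expect_equal(fitted(fit) + residuals(fit), d$moisture)
})

test_that("stack predictions are clipped into the moisture range", {
  d <- stack_table(150, 74)
  fit <- leafstack(moisture ~ ., d, base_learners = "LR", meta = "LR",
                   k = 5, seed = 4)
  extreme <- data.frame(x1 = 40, x2 = 0, x3 = 0)
  expect_message(p <- predict(fit, extreme), "clipping")
  expect_true(p >= 0 && p <= 1)
  expect_error(predict(fit, data.frame(x1 = 1)), "lacks feature")
})

test_that("summary reports base and stack out-of-fold quality", {
  d <- stack_table(160, 75)
  fit <- leafstack(moisture ~ ., d, base_learners = c("LR", "RF"),
                   meta = "LR", k = 5, seed = 5,
                   params = list(RF = list(num_trees = 80)))
  s <- summary(fit)
  expect_s3_class(s$oof_metrics, "metric_set")
  expect_named(s$base_oof, c("LR", "RF"))
  expect_gt(s$oof_metrics$r2, 0.8)
  expect_output(print(s), "out-of-fold")
})

test_that("feature schemes produce one metric row per scheme", {
  ds <- make_dataset(generator_config(period_counts = rep(60L, 5),
                                      position_counts = c(100L, 100L, 100L),
                                      seed = 6))
  tab <- synth_feature_table(ds, seed = 7)
  schemes <- list(colour = c("G_f", "a_f", "B_f"),
                  texture = c("ASM_f", "CON_f", "IDM_f", "AP"),
                  both = c("G_f", "a_f", "B_f", "ASM_f", "AP"),
                  both_again = c("G_f", "a_f", "B_f", "ASM_f", "AP"))
  res <- run_feature_schemes(tab, schemes, test_per_period = 20,
                             seed = 8, base_learners = "LR", k = 3)
  expect_identical(nrow(res), 4L)
  expect_identical(res$scheme, names(schemes))
  # duplicate scheme definitions give identical rows
  expect_equal(res[res$scheme == "both", -1],
               res[res$scheme == "both_again", -1],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(run_feature_schemes(tab, list(bad = "nope"), 20, 8),
               "unknown scheme")
})

test_that("configuration scoring ranks a dominated stack lowest", {
  ds <- make_dataset(generator_config(period_counts = rep(50L, 5),
                                      position_counts = c(90L, 80L, 80L),
                                      seed = 9))
  tab <- synth_feature_table(ds, seed = 10)
  sp <- stratified_split(tab, 15, seed = 11)
  keep <- c("G_f", "a_f", "ASM_f", "AP", "moisture")
  std <- standardize_features(sp$train[keep], sp$test[keep])
  configs <- list(list(bases = c("LR", "XGBoost"), meta = "LR"),
                  list(bases = c("LR", "XGBoost"), meta = "LR"),
                  list(bases = "SVR", meta = "LR"))
  out <- score_configurations(configs, std$train, std$test, seed = 12,
                              k = 3)
  expect_length(out$scores, 3)
  expect_equal(unname(out$scores[1]), unname(out$scores[2]),
               tolerance = 1e-9)                      # identical configs
  expect_identical(nrow(out$table), 3L)
})
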