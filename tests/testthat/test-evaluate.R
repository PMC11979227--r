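fake_report <- function(name, family, ind, runtime = 1) {
  structure(list(learner = name, family = family,
                 indicators = setNames(ind, leafcure:::indicator_names()),
                 runtime = runtime, oof = numeric(0), folds = list()),
            class = "cv_report")
}

test_that("cv_indicators produces the 15 summary indicators", {
  set.seed(61)
  d <- data.frame(x = rnorm(60), moisture = runif(60, 0.2, 0.9))
  d$moisture <- 0.4 + 0.3 * d$x + rnorm(60, 0, 0.02)
  d$moisture <- pmin(pmax(d$moisture, 0.05), 0.95)
  rep_ <- cv_indicators(learner_registry()$LR, d, k = 5, seed = 3)
  expect_length(rep_$indicators, 15)
  expect_identical(names(rep_$indicators), leafcure:::indicator_names())
  expect_length(rep_$oof, nrow(d))                    # partition property
  expect_true(all(sort(unique(rep_$fold_id)) == 1:5))
  # cv = std / mean
  expect_equal(rep_$indicators[["mse_cv"]],
               rep_$indicators[["mse_std"]] / rep_$indicators[["mse_mean"]])
})

test_that("a perfectly predictable target yields r2_mean 1 with no spread", {
  set.seed(62)
  d <- data.frame(x = runif(50, 0.1, 0.9))
  d$moisture <- d$x                                    # target duplicated
  rep_ <- cv_indicators(learner_registry()$LR, d, k = 5, seed = 1)
  expect_equal(rep_$indicators[["r2_mean"]], 1, tolerance = 1e-9)
  expect_equal(rep_$indicators[["r2_std"]], 0, tolerance = 1e-9)
  expect_error(cv_indicators(learner_registry()$LR, d[1:8, ], k = 5),
               "2k rows")
})

test_that("entropy weights follow the hand-computed recipe", {
  # 2 models x 2 indicators, both positive direction
  M <- rbind(c(1, 3), c(2, 3))
  # column 1 normalizes to (0,1); column 2 is constant -> weight 0
  ew <- entropy_weights(M, c("positive", "positive"))
  expect_equal(unname(ew$weights), c(1, 0))
  expect_equal(sum(ew$weights), 1)
  # hand-computed 2x2 with both columns informative
  M2 <- rbind(c(0, 10), c(4, 2))
  ew2 <- entropy_weights(M2, c("positive", "negative"))
  norm <- cbind(c(0, 1), c(0, 1))                      # by min-max + flip
  expect_equal(unname(ew2$normalized), norm)
  # equal discrimination in both columns -> equal weights
  expect_equal(unname(ew2$weights), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(entropy_weights(M[1, , drop = FALSE], c("positive", "positive")),
               "at least 2")
  expect_error(entropy_weights(M, c("up", "down")), "directions")
})

test_that("composite scoring rewards dominance and ties equals", {
  set.seed(63)
  for (rep in 1:10) {
    base <- runif(15, 0.1, 1)
    # model A dominates B on every indicator (positive up, negative down)
    pos <- c(1, 5)                                     # r2_mean, evs_mean
    a <- base; b <- base
    a[pos] <- a[pos] + 0.2; b[pos] <- b[pos] - 0.2
    a[-pos] <- a[-pos] - 0.05; b[-pos] <- b[-pos] + 0.05
    c_ <- (a + b) / 2
    reports <- list(fake_report("A", "single", a),
                    fake_report("B", "single", b),
                    fake_report("C", "single", c_))
    cs <- composite_score(reports)
    expect_identical(names(which.max(cs$scores)), "A")
    expect_true(all(cs$scores >= 0 & cs$scores <= 1))
  }
  twins <- list(fake_report("A", "single", rep(0.5, 15)),
                fake_report("B", "single", rep(0.5, 15)),
                fake_report("C", "single", c(rep(0.4, 5), rep(0.6, 10))))
  cs2 <- composite_score(twins)
  expect_equal(unname(cs2$scores["A"]), unname(cs2$scores["B"]))
})

test_that("composite score is invariant to affine rescaling of an indicator", {
  set.seed(64)
  M <- matrix(runif(45), 3, 15)
  dirs <- ifelse(seq_len(15) %in% c(1, 5), "positive", "negative")
  s1 <- {
    ew <- entropy_weights(M, dirs)
    drop(ew$normalized %*% ew$weights)
  }
  M2 <- M
  M2[, 7] <- 100 * M2[, 7] + 3                        # positive affine map
  s2 <- {
    ew <- entropy_weights(M2, dirs)
    drop(ew$normalized %*% ew$weights)
  }
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("base-learner selection is a per-family argmax", {
  specs <- learner_registry()
  scores <- c(LR = 0.3, SVR = 0.2, MLP = 0.6, RF = 0.7, ET = 0.5,
              GBDT = 0.8, XGBoost = 0.4, AdaBoost = 0.1)
  sel <- select_base_learners(scores, specs)
  expect_identical(sel$bases, c("MLP", "RF", "GBDT"))
  expect_identical(sel$meta, "LR")
  # tie within a family: first by registry order
  scores2 <- scores; scores2[["ET"]] <- scores2[["RF"]]
  expect_identical(select_base_learners(scores2, specs)$bases[2], "RF")
  expect_error(select_base_learners(scores[c("LR", "RF")],
                                    specs[c("LR", "RF")]), "boosting")
})
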