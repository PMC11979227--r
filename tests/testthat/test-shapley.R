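linear_case <- function(n = 120, p = 5, seed = 81) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("x", seq_len(p))
  beta <- c(2, -1, 0.5, 0, 3)[seq_len(p)]
  list(X = X, beta = beta,
       f = function(d) drop(as.matrix(d) %*% beta) + 1)
}

test_that("linear-model attributions match the closed form", {
  lc <- linear_case()
  bg <- lc$X[1:50, ]
  sh <- shapley_values(lc$f, lc$X[51:60, ], bg, n_perm = 500, seed = 1)
  closed <- sweep(as.matrix(lc$X[51:60, ]), 2, colMeans(bg)) %*%
    diag(lc$beta)
  rng <- diff(range(lc$f(lc$X)))
  expect_lt(max(abs(sh$values - closed)), 0.02 * rng)
  expect_lt(max(abs(sh$residuals)), 0.05 * rng)       # additivity
})

test_that("a single-feature model attributes its full deviation", {
  f <- function(d) 3 * d$x + 1
  X <- data.frame(x = c(0.2, 0.9))
  bg <- data.frame(x = c(0, 0.5, 1))
  sh <- shapley_values(f, X, bg, n_perm = 30, seed = 2)
  expect_equal(unname(sh$values[, 1]), f(X) - mean(f(bg)),
               tolerance = 1e-9)
  rv <- rv_contributions(sh)
  expect_equal(unname(rv$rv), 100)
})

test_that("sampling agrees with exhaustive enumeration for small n", {
  set.seed(83)
  n <- 6
  X <- as.data.frame(matrix(rnorm(60 * n), 60, n))
  names(X) <- paste0("x", 1:n)
  y <- 0.4 * X$x1 - 0.3 * X$x2 * X$x3 + 0.2 * abs(X$x4) +
    rnorm(60, 0, 0.05)
  fit <- gbdt_fit(X, y, n_trees = 60, seed = 3)
  bg <- X[1:25, ]
  exact <- shapley_values(fit, X[26:31, ], bg, exact = TRUE)
  # Monte-Carlo spread of the sampler across independent seeds
  reps <- lapply(1:5, function(s)
    shapley_values(fit, X[26:31, ], bg, n_perm = 200, seed = 10 + s)$values)
  est <- Reduce(`+`, reps) / length(reps)
  se <- sqrt(Reduce(`+`, lapply(reps, function(r) (r - est)^2)) /
               (length(reps) * (length(reps) - 1)))
  # floor at 0.1% of the prediction range: antithetic pairing leaves a
  # tiny bias smaller than that while collapsing the replicate spread
  tol <- 3 * se + 0.001 * diff(range(predict(fit, X)))
  expect_true(all(abs(est - exact$values) <= tol))
  expect_lt(max(abs(exact$residuals)), 1e-8)          # exact additivity
})

test_that("symmetric features share credit and dummies get none", {
  set.seed(84)
  X <- data.frame(a = rnorm(80), b = rnorm(80), dummy = rnorm(80))
  f <- function(d) d$a + d$b                          # ignores `dummy`
  twin <- X; twin$b <- twin$a                          # identical columns
  sh <- shapley_values(f, twin[1:30, ], twin[31:80, ], n_perm = 200,
                       seed = 4)
  ma <- colMeans(abs(sh$values))
  expect_equal(unname(ma[["a"]]), unname(ma[["b"]]), tolerance = 0.05)
  expect_lt(ma[["dummy"]], 1e-9)
  rv <- rv_contributions(sh)
  expect_equal(sum(rv$rv), 100, tolerance = 1e-9)
  expect_equal(unname(rv$rv["a"]), 50, tolerance = 3)
})

test_that("dependence profiles expose planted interactions only", {
  set.seed(85)
  n <- 150
  X <- data.frame(AP = sample(0:4, n, replace = TRUE), g = rnorm(n))
  bg <- X[1:60, ]; Xe <- X[61:110, ]
  additive <- function(d) 0.3 * d$AP + 0.5 * d$g
  inter <- function(d) 0.3 * d$AP + 0.5 * d$g * (d$AP - 2)
  sh_add <- shapley_values(additive, Xe, bg, n_perm = 200, seed = 5)
  sh_int <- shapley_values(inter, Xe, bg, n_perm = 200, seed = 5)
  pr_add <- dependence_profile(sh_add, "g")
  pr_int <- dependence_profile(sh_int, "g")
  expect_identical(nrow(pr_add$samples), nrow(Xe))
  expect_identical(nrow(pr_int$level_means), 5L)
  # additive model: the g-attribution depends on g alone, so the
  # conditioning feature carries no extra signal; the planted product
  # term shows up as a strong phi_b x AP interaction
  inter_coef <- function(pr) unname(coef(lm(phi_b ~ b * a,
                                            pr$samples))["b:a"])
  expect_lt(abs(inter_coef(pr_add)), 0.02)
  expect_gt(abs(inter_coef(pr_int)), 0.1)
  expect_error(dependence_profile(sh_add, "nope"), "no such feature")
})
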