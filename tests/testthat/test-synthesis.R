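test_that("leaf rendering is deterministic and period-graded", {
  a <- make_leaf_image(0, "middle", size = c(98, 80), seed = 9)
  b <- make_leaf_image(0, "middle", size = c(98, 80), seed = 9)
  expect_identical(a, b)
  wilting <- make_leaf_image(0, "middle", size = c(98, 80), seed = 10)
  fixation <- make_leaf_image(3, "middle", size = c(98, 80), seed = 10)
  dry <- make_leaf_image(4, "middle", size = c(98, 80), seed = 10)
  gmean <- function(s) mean(s$front[, , 2][s$mask])
  expect_gt(gmean(wilting), gmean(dry))               # green decays
  expect_gt(sum(wilting$mask), sum(fixation$mask))    # shrinkage
  # rear surface is dimmer than the front over the leaf
  expect_gt(mean(wilting$front[, , 2][wilting$mask]),
            mean(wilting$rear[, , 2][wilting$mask]))
})

test_that("the campaign matches the configured composition", {
  ds <- make_dataset(generator_config(seed = 21))
  expect_identical(nrow(ds), 880L)
  expect_identical(as.integer(table(ds$AP)), c(164L, 172L, 177L, 211L, 156L))
  expect_identical(as.integer(table(ds$LP)), c(280L, 320L, 280L))
  st <- default_moisture_stats()
  for (p in 0:4) {
    m <- ds$moisture[ds$AP == p] * 100
    expect_gte(min(m), st$min[p + 1])
    expect_lte(max(m), st$max[p + 1])
    expect_equal(mean(m), st$mean[p + 1], tolerance = 0.6)
  }
  # weights reproduce moisture through the wet-basis formula
  expect_equal(moisture_content(ds$m_leaf, ds$m_dry, ds$m0), ds$moisture,
               tolerance = 1e-9)
  # byte-identical regeneration under the same seed
  expect_identical(ds, make_dataset(generator_config(seed = 21)))
  expect_error(make_dataset(generator_config(period_counts = rep(10L, 5))),
               "sum")
})

test_that("segment-then-extract recovers the period colour drift", {
  ds <- make_dataset(generator_config(seed = 22))
  gf <- vapply(0:4, function(p) {
    rows <- which(ds$AP == p)[1:2]
    mean(vapply(rows, function(i) {
      s <- render_sample(ds, i, c(98, 80))
      f <- segment_leaf(s$front); r <- segment_leaf(s$rear)
      extract_features(f, r, ds$position[i], ds$period[i])[["G_f"]]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(0:4, gf, method = "spearman"), -0.9)
})

test_that("the engineered table realizes planted correlations", {
  tab <- make_feature_table(c(strong = 0.9, none = 0), n = 880, seed = 23)
  r_strong <- abs(cor(tab$strong, tab$moisture))
  expect_true(r_strong >= 0.85 && r_strong <= 0.95)
  expect_lt(abs(cor(tab$none, tab$moisture)), 0.1)
  # redundancy blocks land near their planted pairwise value
  tab2 <- make_feature_table(c(a = 0.6, b = 0.55),
                             groups = list(g1 = c(a = 0.7, b = 0.7)),
                             n = 880, seed = 24)
  expect_equal(cor(tab2$a, tab2$b), 0.6 * 0.55 + 0.49, tolerance = 0.05)
  # unrealizable loading structure is rejected
  expect_error(make_feature_table(c(a = 0.9), list(g = c(a = 0.6))),
               "unrealizable")
  expect_error(make_feature_table(c(a = 1.2)), "< 1")
  expect_error(make_feature_table(c(a = 0.5), n = 50), ">= 100")
})

test_that("the analytic feature table supports near-perfect recovery", {
  ds <- make_dataset(generator_config(seed = 25))
  tab <- synth_feature_table(ds, seed = 26)
  expect_identical(names(tab), c(feature_names(), "moisture"))
  # the latent link bounds achievable R2 just below 1
  fit <- lm(moisture ~ G_f + a_f + ASM_f + AP, tab)
  r2 <- summary(fit)$r.squared
  expect_gt(r2, 0.95)
  expect_lt(r2, 0.9999)
  # G_f is monotone in moisture
  expect_gt(cor(tab$G_f, tab$moisture), 0.95)
})

test_that("a campaign writes images and metadata to disk", {
  dir <- file.path(tempdir(), "campaign-test")
  cfg <- generator_config(period_counts = rep(21L, 5),
                          position_counts = c(35L, 35L, 35L), seed = 27)
  ds <- write_campaign(dir, cfg, indices = 1:2, size = c(72, 64))
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "leaf0001_front.png")))
  img <- read_leaf_image(file.path(dir, "leaf0001_front.png"))
  expect_identical(dim(img), c(72L, 64L, 3L))
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_identical(nrow(meta), 105L)
  unlink(dir, recursive = TRUE)
})
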