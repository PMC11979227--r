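test_that("colour statistics over the mask match direct computation", {
  roi <- uniform_roi(c(10, 200, 30))
  cs <- color_stats(roi)
  expect_equal(unname(cs[c("R", "G", "B")]), c(10, 200, 30))
  expect_equal(unname(cs[c("StdB", "StdG", "StdR")]), c(0, 0, 0))
  green <- color_stats(uniform_roi(c(0, 255, 0)))
  expect_lt(green[["a"]], 0)                # green is negative a*
})

test_that("sRGB to CIELAB matches the reference conversion", {
  # black + white: L* endpoints are exact by construction
  lab <- srgb_to_lab(rbind(c(0, 0, 0), c(255, 255, 255)))
  expect_equal(lab[1, ], c(L = 0, a = 0, b = 0), tolerance = 1e-4)
  expect_equal(unname(lab[2, "L"]), 100, tolerance = 1e-4)
  # independent route: grDevices' colour engine (slightly different D65
  # adaptation, hence the loose tolerance)
  set.seed(12)
  rgb <- matrix(sample(0:255, 30, replace = TRUE), 10, 3)
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_equal(unname(srgb_to_lab(rgb)), unname(ref), tolerance = 0.02)
})

test_that("GLCM matches hand enumeration and the brute-force oracle", {
  cfg <- texture_config(levels = 2, angles = 0)
  g <- glcm_matrix(matrix(c(0, 1, 0, 1), 2, 2), cfg = cfg, quantize = FALSE)
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  const <- glcm_matrix(matrix(3, 4, 4), cfg = texture_config(levels = 8),
                       quantize = FALSE)
  expect_equal(const$matrix[4, 4], 1)       # single diagonal cell
  set.seed(21)
  for (rep in 1:15) {
    q <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) > 0.3, 8, 8)
    cfg <- texture_config(levels = 4, distance = 1,
                          angles = c(0, 45, 90, 135))
    got <- tryCatch(glcm_matrix(q, mask, cfg, quantize = FALSE),
                    error = function(e) NULL)
    if (is.null(got)) next                  # no valid pairs this draw
    want <- glcm_bruteforce(q, mask, 4, 1, c(0, 45, 90, 135))
    expect_equal(got$matrix, want, tolerance = 1e-12)
    expect_equal(sum(got$matrix), 1, tolerance = 1e-9)
    expect_equal(got$matrix, t(got$matrix)) # symmetry
  }
})

test_that("Haralick statistics match their definitions", {
  h <- haralick_features(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(unname(h), c(0.5, 0, 1, log(2), 1))
  const <- haralick_features(diag(c(1, 0, 0)))
  expect_equal(unname(const[c("ASM", "CON", "Entr", "IDM")]), c(1, 0, 0, 1))
  k <- 4
  unif <- haralick_features(matrix(1 / k^2, k, k))
  expect_equal(unname(unif[["ASM"]]), 1 / k^2)
  set.seed(22)
  for (rep in 1:100) {
    p <- random_glcm_matrix(sample(2:8, 1))
    expect_equal(unname(haralick_features(p)),
                 unname(haralick_bruteforce(p)), tolerance = 1e-10)
  }
})

test_that("metadata label encoding follows the fixed vocabularies", {
  expect_identical(encode_metadata("lower", "wilting period"),
                   c(LP = 0L, AP = 0L))
  expect_identical(encode_metadata("upper", "dry tendon period"),
                   c(LP = 2L, AP = 4L))
  expect_identical(encode_metadata("middle", "browning"),
                   c(LP = 1L, AP = 2L))
  expect_error(encode_metadata("apex", "wilting period"), "position")
  expect_error(encode_metadata("lower", "resting period"), "period")
})

test_that("extract_features yields the 36 named descriptors", {
  s <- make_leaf_image(1, "middle", size = c(98, 80), seed = 61)
  f <- segment_leaf(s$front); r <- segment_leaf(s$rear)
  fv <- extract_features(f, r, "middle", "yellowing period")
  expect_identical(names(fv), feature_names())
  expect_true(fv[["ASM_f"]] > 0 && fv[["ASM_f"]] <= 1)
  expect_gte(fv[["CON_f"]], 0)
  expect_true(fv[["IDM_f"]] > 0 && fv[["IDM_f"]] <= 1)
  # identical surfaces give identical f/r features
  sym <- extract_features(f, f, "lower", "wilting period")
  front_part <- sym[paste0(sub("_r$", "", names(sym)[18:34]), "_f")]
  expect_equal(unname(front_part), unname(sym[18:34]))
  # deterministic
  expect_identical(fv, extract_features(f, r, "middle", "yellowing period"))
})

test_that("later-period leaves are less green on the front surface", {
  g <- sapply(c("wilting period", "dry tendon period"), function(p) {
    s <- make_leaf_image(p, "middle", size = c(98, 80),
                         seed = 90 + nchar(p))
    roi <- segment_leaf(s$front)
    extract_features(roi, roi, "middle", p)[["G_f"]]
  })
  expect_gt(g[1], g[2])
})

test_that("feature tables round-trip through CSV", {
  ds <- make_dataset(generator_config(period_counts = rep(30L, 5),
                                      position_counts = c(50L, 50L, 50L),
                                      seed = 3))
  tab <- synth_feature_table(ds, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back, tab, tolerance = 1e-12)
  expect_error(read_feature_table({
    f2 <- tempfile(fileext = ".csv")
    write.csv(tab[1:5], f2, row.names = FALSE)
    f2
  }), "missing feature columns")
})
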