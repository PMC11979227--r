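# Synthetic-data module: renders leaf photographs with known ground
# truth, draws a full air-curing campaign with the composition and
# per-period moisture moments of the real study design, and builds
# correlation-engineered feature tables for exercising the feature
# filter.

#' Generator configuration for the synthetic campaign
#'
#' Defaults encode the study composition: 880 leaves over five airing
#' periods (164/172/177/211/156) and three stalk positions
#' (280/320/280), with per-period moisture mean, standard deviation and
#' range (percent) matching the campaign's descriptive statistics.
#' Images default to 1/4 the capture resolution.
#'
#' @param period_counts integer 5-vector of samples per period.
#' @param position_counts integer 3-vector lower/middle/upper.
#' @param moisture_stats data.frame with columns `mean`, `sd`, `min`,
#'   `max` (percent), one row per period.
#' @param image_size `c(height, width)` of rendered images, >= 64.
#' @param noise_sd latent moisture-to-feature link noise (fraction).
#' @param seed base RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(period_counts = c(164L, 172L, 177L, 211L, 156L),
                             position_counts = c(280L, 320L, 280L),
                             moisture_stats = default_moisture_stats(),
                             image_size = c(780L, 520L),
                             noise_sd = 0.015,
                             seed = 1L) {
  if (length(period_counts) != 5L || any(period_counts < 0L))
    stop_input("period_counts must be 5 non-negative integers")
  if (length(position_counts) != 3L)
    stop_input("position_counts must have 3 entries")
  if (sum(period_counts) != sum(position_counts))
    stop_input("period and position counts must sum to the same total")
  if (any(image_size < 64L)) stop_input("image_size must be >= 64 x 64")
  stopifnot(all(c("mean", "sd", "min", "max") %in% names(moisture_stats)),
            nrow(moisture_stats) == 5L,
            all(moisture_stats$min <= moisture_stats$mean),
            all(moisture_stats$mean <= moisture_stats$max))
  structure(list(period_counts = period_counts,
                 position_counts = position_counts,
                 moisture_stats = moisture_stats,
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_moisture_stats <- function() {
  data.frame(period = period_levels(),
             mean = c(86.73, 73.54, 42.78, 21.91, 16.59),
             sd = c(2.80, 6.31, 10.27, 2.79, 0.79),
             min = c(81.70, 60.23, 27.78, 18.03, 15.15),
             max = c(92.87, 81.64, 60.14, 27.72, 18.00))
}

# Per-period appearance anchors of the green->brown drift: front-surface
# RGB, leaf shrinkage (linear scale) and vein-texture roughness.
period_appearance <- function() {
  list(rgb = rbind(c(60, 150, 55),     # wilting: saturated green
                   c(160, 135, 60),    # yellowing
                   c(140, 110, 65),    # browning
                   c(120, 85, 55),     # fixation
                   c(100, 65, 45)),    # dry tendon: dark brown
       shrink = c(1.00, 0.95, 0.85, 0.75, 0.65),
       roughness = c(3, 5, 8, 11, 14))
}

#' Render a synthetic suspended-leaf photograph pair
#'
#' Draws a smooth random blob (a low-order harmonic perturbation of an
#' ellipse) on a near-white background. Appearance follows the airing
#' period: the mean green level decreases strictly and the red/green
#' ratio rises period by period, later periods shrink the leaf and add
#' stronger vein texture. The rear surface is a dimmed, hue-shifted
#' variant. Deterministic under `seed`.
#'
#' @param period airing-period name or 0-based code.
#' @param position leaf position name or 0-based code (mild size
#'   effect).
#' @param moisture optional moisture fraction modulating colour within
#'   the period.
#' @param size `c(height, width)` in pixels.
#' @param seed RNG seed.
#' @return list with `front`, `rear` (H x W x 3 integer RGB arrays) and
#'   `mask` (logical ground-truth leaf mask).
#' @export
make_leaf_image <- function(period, position = "middle", moisture = NULL,
                            size = c(195L, 130L), seed = 1L) {
  ap <- if (is.numeric(period)) as.integer(period) else
    encode_metadata("lower", period)[["AP"]]
  if (ap < 0L || ap > 4L) stop_input("period code must be in 0..4")
  lp <- if (is.numeric(position)) as.integer(position) else
    encode_metadata(position, "wilting period")[["LP"]]
  if (lp < 0L || lp > 2L) stop_input("position code must be in 0..2")
  H <- size[1]; W <- size[2]
  app <- period_appearance()
  with_seed(seed, {
    cy <- H / 2 + runif(1, -0.02, 0.02) * H
    cx <- W / 2 + runif(1, -0.02, 0.02) * W
    scale <- app$shrink[ap + 1L] * (1 + 0.04 * (lp - 1))
    ay <- 0.40 * H * scale
    ax <- 0.32 * W * scale
    amp <- runif(3, 0.02, 0.07)
    ph <- runif(3, 0, 2 * pi)
    rr <- matrix(seq_len(H), H, W) - cy
    cc <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    rho <- sqrt((rr / ay)^2 + (cc / ax)^2)
    theta <- atan2(cc / ax, rr / ay)
    bound <- 1 + amp[1] * cos(2 * theta + ph[1]) +
      amp[2] * cos(3 * theta + ph[2]) + amp[3] * cos(5 * theta + ph[3])
    mask <- rho <= bound
    base <- app$rgb[ap + 1L, ]
    if (!is.null(moisture)) {
      mu <- default_moisture_stats()$mean[ap + 1L] / 100
      base[2] <- base[2] + 60 * (moisture - mu)    # greener when wetter
      base[1] <- base[1] - 30 * (moisture - mu)
    }
    rough <- app$roughness[ap + 1L]
    vein <- rough * sin(2 * pi * 9 * rr / H) * sin(2 * pi * 5 * cc / W) +
      rough * 0.6 * sin(2 * pi * 23 * rr / H)
    grain <- matrix(rnorm(H * W, 0, rough / 2), H, W)
    bgnoise <- matrix(rnorm(H * W, 0, 1.5), H, W)
    build <- function(mult) {
      img <- array(0, dim = c(H, W, 3))
      for (ch in 1:3) {
        leaf <- base[ch] * mult[ch] + vein + grain
        img[, , ch] <- ifelse(mask, leaf, 245 + bgnoise)
      }
      array(as.integer(pmin(pmax(round(img), 0), 255)), dim = c(H, W, 3))
    }
    front <- build(c(1, 1, 1))
    rear <- build(c(0.92, 0.80, 0.88))     # dimmer, browner rear
    list(front = front, rear = rear, mask = mask)
  })
}

# Truncated-normal draw by inverse-CDF, vectorized.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Draw a full synthetic air-curing campaign
#'
#' Produces one record per leaf with the configured per-period and
#' per-position composition. Moisture is drawn from a per-period
#' truncated normal with the configured mean/sd clipped to
#' \[min, max\]; weights (container 10 g, wet mass 100 g) reproduce the
#' moisture exactly through the wet-basis formula. Each record carries
#' its own image seed so photographs can be rendered on demand with
#' [render_sample()]. Regeneration under a fixed seed is identical.
#'
#' @param cfg a [generator_config()].
#' @return data.frame of class `leaf_campaign`: `id`, `period`, `AP`,
#'   `position`, `LP`, `moisture` (fraction), `m_leaf`, `m_dry`, `m0`,
#'   `img_seed`.
#' @export
make_dataset <- function(cfg = generator_config()) {
  n <- sum(cfg$period_counts)
  ap <- rep(0:4, cfg$period_counts)
  st <- cfg$moisture_stats
  with_seed(cfg$seed, {
    lp <- sample(rep(0:2, cfg$position_counts))
    moist_pct <- numeric(n)
    for (p in 0:4) {
      rows <- ap == p
      moist_pct[rows] <- rtruncnorm_inv(sum(rows), st$mean[p + 1],
                                        st$sd[p + 1], st$min[p + 1],
                                        st$max[p + 1])
    }
    moisture <- moist_pct / 100
    m0 <- 10; wet_mass <- 100
    m_leaf <- m0 + wet_mass
    m_dry <- m0 + wet_mass * (1 - moisture)
    out <- data.frame(id = seq_len(n),
                      period = period_levels()[ap + 1L], AP = ap,
                      position = position_levels()[lp + 1L], LP = lp,
                      moisture = moisture,
                      m_leaf = m_leaf, m_dry = m_dry, m0 = m0,
                      img_seed = vapply(seq_len(n), child_seed,
                                        numeric(1), seed = cfg$seed))
    class(out) <- c("leaf_campaign", "data.frame")
    out
  })
}

#' @rdname make_dataset
#' @param dataset a `leaf_campaign` from [make_dataset()].
#' @param i row index to render.
#' @param size image size passed to [make_leaf_image()].
#' @export
render_sample <- function(dataset, i, size = c(195L, 130L)) {
  r <- dataset[i, ]
  make_leaf_image(r$AP, r$LP, r$moisture, size = size, seed = r$img_seed)
}

#' Analytic feature table for a campaign
#'
#' Maps each leaf's moisture to the 36 descriptors through a latent
#' monotone link: a noisy copy of moisture (sd `noise_sd`, the
#' irreducible error floor) drives near-linear monotone curves for the
#' informative colour/texture features, while the features the filter
#' is expected to discard are noise-dominated. `AP` and `LP` are the
#' true integer codes. This is the fast path for model training
#' experiments; [render_sample()] plus [extract_features()] is the
#' image path.
#'
#' @param dataset a `leaf_campaign` from [make_dataset()].
#' @param noise_sd latent link noise, moisture-fraction units.
#' @param seed RNG seed.
#' @return data.frame with the 36 [feature_names()] columns plus
#'   `moisture`.
#' @export
synth_feature_table <- function(dataset, noise_sd = 0.015, seed = 1L) {
  n <- nrow(dataset)
  m <- dataset$moisture
  with_seed(seed, {
    u <- m + rnorm(n, 0, noise_sd)          # latent appearance state
    e <- function(s) rnorm(n, 0, s)
    tab <- data.frame(
      B_f = 45 + 15 * u + e(2),
      G_f = 45 + 115 * u + e(2.5),
      R_f = 150 - 85 * u + e(3),
      StdB_f = 8 + 4 * u + e(1.5),
      StdG_f = 12 + e(3),
      StdR_f = 11 + e(3),
      L_f = 32 + 26 * u + e(1.5),
      a_f = 14 - 36 * u + e(1.2),
      b_f = 38 - 12 * u + e(1.5),
      StdL_f = 6 + e(1.5),
      Stda_f = 2.5 + 3 * u + e(0.5),
      Stdb_f = 3 + 2.5 * u + e(0.5),
      ASM_f = 0.55 - 0.35 * u + e(0.02),
      CON_f = 2.2 + 5.5 * u + e(0.5),
      Corr_f = 0.92 + e(0.03),
      Entr_f = 1.4 + 1.6 * u + e(0.12),
      IDM_f = 0.45 + 0.30 * (1 - u) + e(0.02),
      B_r = 40 + 13 * u + e(3),
      G_r = 38 + 100 * u + e(5),
      R_r = 120 + e(8),
      StdB_r = 9 + e(2.5),
      StdG_r = 13 + e(3),
      StdR_r = 12 + e(3),
      L_r = 28 + 22 * u + e(3),
      a_r = 12 - 30 * u + e(2.5),
      b_r = 34 - 10 * u + e(2),
      StdL_r = 7 + e(2),
      Stda_r = 2.2 + 2.6 * u + e(0.8),
      Stdb_r = 3.2 + e(1),
      ASM_r = 0.50 - 0.28 * u + e(0.04),
      CON_r = 2.0 + 4.5 * u + e(1),
      Corr_r = 0.90 + e(0.04),
      Entr_r = 1.3 + 1.4 * u + e(0.25),
      IDM_r = 0.42 + 0.26 * (1 - u) + e(0.04),
      LP = dataset$LP,
      AP = dataset$AP)
    tab <- tab[feature_names()]
    tab$moisture <- m
    tab
  })
}

#' Correlation-engineered Gaussian feature table
#'
#' Builds a table whose columns realize a requested correlation
#' structure with a latent standard-normal target, by an explicit
#' factor construction: column j is
#' \eqn{x_j = r_j t + c_j g_{G(j)} + \sqrt{1 - r_j^2 - c_j^2}\,
#' \epsilon_j} with t the target factor and g independent group
#' factors. Pairwise correlation is \eqn{r_j r_k} across groups and
#' \eqn{r_j r_k + c_j c_k} within a group, so planted redundancy blocks
#' and target relevances are exact in expectation (positive
#' semidefinite by construction). The `moisture` column is an affine
#' map of t into the moisture-fraction range.
#'
#' @param planted_pcc named numeric vector of target correlations,
#'   `|r| < 1`.
#' @param groups optional named list of redundancy blocks:
#'   `list(block = c(feature = loading, ...))`; loadings must satisfy
#'   `r^2 + c^2 <= 1` per feature (violations are rejected as an
#'   unrealizable request).
#' @param n rows (>= 100).
#' @param seed RNG seed.
#' @return data.frame with one column per planted feature plus
#'   `moisture`.
#' @export
make_feature_table <- function(planted_pcc, groups = list(), n = 880L,
                               seed = 1L) {
  if (n < 100L) stop_input("n must be >= 100")
  if (is.null(names(planted_pcc)) || any(names(planted_pcc) == ""))
    stop_input("planted_pcc must be a fully named vector")
  if (any(abs(planted_pcc) >= 1))
    stop_input("planted correlations must satisfy |r| < 1")
  feats <- names(planted_pcc)
  cload <- setNames(numeric(length(feats)), feats)
  gid <- setNames(rep(NA_character_, length(feats)), feats)
  for (g in names(groups)) {
    for (f in names(groups[[g]])) {
      if (!f %in% feats) stop_input("group feature not planted: ", f)
      cload[f] <- groups[[g]][[f]]
      gid[f] <- g
    }
  }
  resid_var <- 1 - planted_pcc^2 - cload^2
  if (any(resid_var < 0))
    stop_input("unrealizable request (r^2 + c^2 > 1) for: ",
               paste(feats[resid_var < 0], collapse = ", "))
  with_seed(seed, {
    t_ <- rnorm(n)
    gf <- lapply(setNames(names(groups), names(groups)),
                 function(g) rnorm(n))
    X <- vapply(feats, function(f) {
      g <- if (is.na(gid[f])) 0 else gf[[gid[f]]]
      planted_pcc[f] * t_ + cload[f] * g + sqrt(resid_var[f]) * rnorm(n)
    }, numeric(n))
    tab <- as.data.frame(X)
    tab$moisture <- pmin(pmax(0.50 + 0.13 * t_, 0.02), 0.98)
    tab
  })
}

#' The engineered selection fixture
#'
#' A [make_feature_table()] design over all 36 features whose planted
#' target relevances and redundancy blocks are arranged so that the
#' two-step filter (relevance categorization at 0.45/0.75, greedy
#' redundancy pruning at 0.80 with the texture backstops) retains
#' exactly the canonical 15-feature subset: B_f, G_f, R_f, StdB_f,
#' a_f, Stda_f, Stdb_f, ASM_f, IDM_f, B_r, G_r, b_r, Stda_r, LP, AP.
#'
#' @param n rows (default 880).
#' @param seed RNG seed.
#' @return data.frame with the 36 feature columns plus `moisture`.
#' @export
make_selection_fixture <- function(n = 880L, seed = 1L) {
  r <- c(
    # retained: strong-to-moderate target relevance, mutually compatible
    G_f = 0.92, a_f = -0.80, G_r = 0.78, ASM_f = -0.76, B_f = 0.72,
    AP = -0.70, R_f = -0.69, StdB_f = 0.68, Stda_f = 0.66,
    Stdb_f = 0.64, B_r = 0.62, b_r = -0.60, Stda_r = 0.58, LP = 0.56,
    IDM_f = -0.55,
    # redundant relatives, pinned to a retained partner via blocks
    a_r = -0.86, L_f = 0.82, b_f = -0.74, CON_f = 0.55, Entr_f = 0.54,
    ASM_r = -0.53, CON_r = 0.52, Entr_r = 0.51, L_r = 0.55,
    IDM_r = -0.47,
    # unimportant: below the 0.45 relevance boundary
    R_r = -0.32, StdB_r = 0.30, Stdb_r = 0.28, Corr_f = 0.26,
    StdG_f = 0.24, Corr_r = -0.22, StdG_r = 0.20, StdR_f = -0.18,
    StdL_f = 0.16, StdR_r = -0.14, StdL_r = 0.12)
  groups <- list(
    green = c(G_f = 0.35, a_r = -0.35, L_f = 0.35),
    chroma = c(a_f = 0.55, b_f = 0.55),
    texture = c(ASM_f = 0.60, CON_f = -0.74, Entr_f = -0.74,
                ASM_r = 0.74, CON_r = -0.78, Entr_r = -0.78),
    homogeneity = c(IDM_f = 0.78, IDM_r = 0.76),
    rear_light = c(G_r = 0.55, L_r = 0.78))
  tab <- make_feature_table(r, groups, n = n, seed = seed)
  tab[c(feature_names(), "moisture")]
}

#' Write a synthetic campaign to disk
#'
#' Renders every sampled leaf's front/rear image and ground-truth mask
#' as PNG and writes `metadata.csv` and `weights.csv`.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [generator_config()].
#' @param indices which campaign rows to render (default all).
#' @param size image size.
#' @return the campaign data.frame, invisibly.
#' @export
write_campaign <- function(dir, cfg = generator_config(),
                           indices = NULL, size = c(195L, 130L)) {
  ds <- make_dataset(cfg)
  if (is.null(indices)) indices <- seq_len(nrow(ds))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in indices) {
    s <- render_sample(ds, i, size)
    for (part in c("front", "rear")) {
      img <- s[[part]] / 255
      png::writePNG(aperm(array(img, dim = dim(s[[part]])), c(1, 2, 3)),
                    file.path(dir, sprintf("leaf%04d_%s.png", i, part)))
    }
    write_mask_png(s$mask, file.path(dir, sprintf("leaf%04d_mask.png", i)))
  }
  write.csv(ds[c("id", "period", "AP", "position", "LP", "moisture")],
            file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(ds[c("id", "m_leaf", "m_dry", "m0")],
            file.path(dir, "weights.csv"), row.names = FALSE)
  invisible(ds)
}
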