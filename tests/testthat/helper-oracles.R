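# Independent brute-force oracles used to validate the fast
# implementations.

# Otsu: exhaustive search over all 256 thresholds, naive two-class
# statistics per candidate.
otsu_bruteforce <- function(gray) {
  g <- as.vector(pmin(pmax(floor(gray), 0), 255))
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:255) {
    c0 <- g[g <= t]; c1 <- g[g > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(g); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# GLCM: literal pair enumeration over every pixel and offset.
glcm_bruteforce <- function(q, mask, levels, distance, angles) {
  H <- nrow(q); W <- ncol(q)
  offs <- list("0" = c(0, distance), "45" = c(-distance, distance),
               "90" = c(-distance, 0), "135" = c(-distance, -distance))
  acc <- matrix(0, levels, levels)
  n_used <- 0
  for (ang in angles) {
    o <- offs[[as.character(ang)]]
    cnt <- matrix(0, levels, levels)
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
        if (!mask[r, c] || !mask[r2, c2]) next
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        cnt[i, j] <- cnt[i, j] + 1
        cnt[j, i] <- cnt[j, i] + 1
      }
    }
    if (sum(cnt) > 0) {
      acc <- acc + cnt / sum(cnt)
      n_used <- n_used + 1
    }
  }
  acc / n_used
}

# Haralick: scalar double-loop evaluation of the five definitions.
haralick_bruteforce <- function(p) {
  L <- nrow(p)
  asm <- 0; con <- 0; entr <- 0; idm <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in 1:L) for (j in 1:L) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + (i - j)^2 * v
    if (v > 0) entr <- entr - v * log(v)
    idm <- idm + v / (1 + (i - j)^2)
    var_i <- var_i + (i - 1 - mu_i)^2 * v
    var_j <- var_j + (j - 1 - mu_j)^2 * v
    cov_ij <- cov_ij + (i - 1 - mu_i) * (j - 1 - mu_j) * v
  }
  corr <- if (var_i * var_j == 0) 1 else cov_ij / sqrt(var_i * var_j)
  c(ASM = asm, CON = con, Corr = corr, Entr = entr, IDM = idm)
}

# Random normalized symmetric co-occurrence matrix.
random_glcm_matrix <- function(L) {
  m <- matrix(runif(L * L), L, L)
  m <- m + t(m)
  m / sum(m)
}

# Small random leaf-like test image: dark blob on a bright background.
random_blob_image <- function(H = 16, W = 16) {
  img <- matrix(sample(180:250, H * W, replace = TRUE), H, W)
  r0 <- sample(seq(3, H - 5), 1); c0 <- sample(seq(3, W - 5), 1)
  img[r0:(r0 + 3), c0:(c0 + 3)] <- sample(20:90, 16, replace = TRUE)
  img
}

# The canonical 15-feature retained subset of the two-step filter.
canonical_subset <- function() {
  c("B_f", "G_f", "R_f", "StdB_f", "a_f", "Stda_f", "Stdb_f", "ASM_f",
    "IDM_f", "B_r", "G_r", "b_r", "Stda_r", "LP", "AP")
}

# Uniform-colour ROI helper.
uniform_roi <- function(rgb, H = 10, W = 10) {
  img <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  roi_image(img, matrix(TRUE, H, W))
}
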