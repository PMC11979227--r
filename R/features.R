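#' The 36 feature names
#'
#' Column order of the feature table: the 17 front-surface descriptors
#' (`_f`), the 17 rear-surface descriptors (`_r`), then the two leaf
#' descriptors `LP` (leaf position code) and `AP` (airing period code).
#' `L`, `a`, `b` denote the CIELAB L*, a*, b* components; `ASM`, `CON`,
#' `Corr`, `Entr`, `IDM` the five Haralick statistics of the grey-level
#' co-occurrence matrix.
#'
#' @return character vector of length 36.
#' @export
feature_names <- function() {
  base <- c("B", "G", "R", "StdB", "StdG", "StdR",
            "L", "a", "b", "StdL", "Stda", "Stdb",
            "ASM", "CON", "Corr", "Entr", "IDM")
  c(paste0(base, "_f"), paste0(base, "_r"), "LP", "AP")
}

#' Group the 36 features by surface
#'
#' @return named list with `front`, `rear` and `leaf` character vectors
#'   partitioning [feature_names()].
#' @export
feature_groups <- function() {
  nm <- feature_names()
  list(front = nm[endsWith(nm, "_f")],
       rear  = nm[endsWith(nm, "_r")],
       leaf  = c("LP", "AP"))
}

#' Convert sRGB values to CIELAB
#'
#' Standard sRGB companding, D65 white point; L* on `[0, 100]`, a*/b*
#' unscaled.
#'
#' @param rgb n x 3 matrix of sRGB values in `[0, 255]`.
#' @return n x 3 matrix with columns L, a, b.
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- rbind(rgb) / 255
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1, 1.08883)
  t3 <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t3 > eps, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Colour statistics over the leaf mask
#'
#' Means and standard deviations of the B, G, R channels and of the
#' CIELAB L*, a*, b* components, computed over foreground pixels only.
#'
#' @param roi a [roi_image()].
#' @return named numeric vector of 12 values `(B, G, R, StdB, StdG,
#'   StdR, L, a, b, StdL, Stda, Stdb)`.
#' @export
color_stats <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  m <- roi$mask
  if (!any(m)) stop_input("empty mask")
  rgb <- cbind(roi$image[, , 1][m], roi$image[, , 2][m], roi$image[, , 3][m])
  lab <- srgb_to_lab(rgb)
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  c(B = mean(rgb[, 3]), G = mean(rgb[, 2]), R = mean(rgb[, 1]),
    StdB = sd0(rgb[, 3]), StdG = sd0(rgb[, 2]), StdR = sd0(rgb[, 1]),
    L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]),
    StdL = sd0(lab[, 1]), Stda = sd0(lab[, 2]), Stdb = sd0(lab[, 3]))
}

#' Texture configuration for the co-occurrence matrix
#'
#' Defaults: masked gray values quantized to 64 levels, pixel pairs at
#' distance 1, the four principal directions averaged into one symmetric
#' matrix, entropy in natural log.
#'
#' @param levels number of gray levels after quantization, in
#'   `[8, 256]`.
#' @param distance pair offset in pixels, >= 1.
#' @param angles directions in degrees, subset of `{0, 45, 90, 135}`.
#' @param log_base base of the logarithm used for entropy.
#' @return object of class `texture_config`.
#' @export
texture_config <- function(levels = 64L, distance = 1L,
                           angles = c(0, 45, 90, 135),
                           log_base = exp(1)) {
  levels <- as.integer(levels)
  if (levels < 2L || levels > 256L) stop_input("levels must be in [2, 256]")
  if (distance < 1L) stop_input("distance must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop_input("angles must be a subset of {0, 45, 90, 135}")
  structure(list(levels = levels, distance = as.integer(distance),
                 angles = angles, log_base = log_base),
            class = "texture_config")
}

glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop_input("unsupported angle: ", angle))
}

#' Grey-level co-occurrence matrix over a masked region
#'
#' Gray values are quantized to `cfg$levels` equal bins of `[0, 255]`;
#' pairs are counted only when both endpoints are foreground; each
#' direction's count matrix is symmetrized and normalized, and the
#' configured directions are averaged with equal weight.
#'
#' @param gray numeric matrix of gray values in `[0, 255]`.
#' @param mask logical matrix of the same shape (`NULL` for all-pixels).
#' @param cfg a [texture_config()].
#' @param quantize if `FALSE`, `gray` is taken to hold integer level
#'   indices in `[0, levels - 1]` already.
#' @return object of class `glcm` with fields `matrix` (levels x levels,
#'   symmetric, sums to 1), `levels`, `distance`, `angles`.
#' @export
glcm_matrix <- function(gray, mask = NULL, cfg = texture_config(),
                        quantize = TRUE) {
  if (is.null(mask)) mask <- array(TRUE, dim(gray))
  if (!identical(dim(gray), dim(mask))) stop_input("gray/mask shape mismatch")
  L <- cfg$levels
  q <- if (quantize) {
    matrix(pmin(floor(gray / 256 * L), L - 1L), nrow(gray))
  } else {
    if (min(gray) < 0 || max(gray) > L - 1L)
      stop_input("pre-quantized gray values must lie in [0, levels - 1]")
    matrix(as.integer(gray), nrow(gray))
  }
  H <- nrow(gray); W <- ncol(gray)
  acc <- matrix(0, L, L)
  n_used <- 0L
  for (ang in cfg$angles) {
    off <- glcm_offset(ang, cfg$distance)
    r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
    c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2],
                                            drop = FALSE]
    if (!any(ok)) next
    i <- a[ok]; j <- b[ok]
    cnt <- matrix(tabulate(i * L + j + 1L, nbins = L * L), L, byrow = TRUE)
    cnt <- cnt + t(cnt)                     # symmetric pairs
    acc <- acc + cnt / sum(cnt)
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop_input("no valid pixel pairs inside the mask at this offset")
  structure(list(matrix = acc / n_used, levels = L,
                 distance = cfg$distance, angles = cfg$angles),
            class = "glcm")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Angular second moment (energy), contrast, correlation, entropy and
#' inverse difference moment. Correlation is defined as 1 when both
#' marginal variances vanish (a constant region is perfectly
#' self-correlated).
#'
#' @param g a [glcm_matrix()] result, or a plain normalized square
#'   matrix.
#' @param log_base base of the entropy logarithm (natural by default).
#' @return named numeric vector `(ASM, CON, Corr, Entr, IDM)`.
#' @export
haralick_features <- function(g, log_base = exp(1)) {
  p <- if (inherits(g, "glcm")) g$matrix else as.matrix(g)
  if (nrow(p) != ncol(p) || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop_input("expected a normalized square co-occurrence matrix")
  L <- nrow(p)
  idx <- seq_len(L) - 1
  I <- matrix(idx, L, L); J <- t(I)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(idx * pi_); mu_j <- sum(idx * pj_)
  var_i <- sum((idx - mu_i)^2 * pi_); var_j <- sum((idx - mu_j)^2 * pj_)
  asm <- sum(p^2)
  con <- sum((I - J)^2 * p)
  corr <- if (var_i * var_j == 0) 1 else
    sum((I - mu_i) * (J - mu_j) * p) / sqrt(var_i * var_j)
  pz <- p[p > 0]
  entr <- -sum(pz * log(pz, base = log_base))
  idm <- sum(p / (1 + (I - J)^2))
  c(ASM = asm, CON = con, Corr = corr, Entr = entr, IDM = idm)
}

position_levels <- function() c("lower", "middle", "upper")
period_levels <- function() {
  c("wilting period", "yellowing period", "browning period",
    "fixation period", "dry tendon period")
}

#' Encode leaf position and airing period as integer codes
#'
#' Label encoding: position lower/middle/upper to 0/1/2; period wilting
#' through dry tendon to 0--4. Period names are accepted with or without
#' the trailing "period".
#'
#' @param position one of `"lower"`, `"middle"`, `"upper"`.
#' @param period one of the five airing-period names.
#' @return named integer vector `(LP, AP)`.
#' @export
encode_metadata <- function(position, period) {
  lp <- match(position, position_levels())
  per <- ifelse(grepl(" period$", period), period, paste(period, "period"))
  ap <- match(per, period_levels())
  if (is.na(lp)) stop_input("unknown leaf position: ", position)
  if (is.na(ap)) stop_input("unknown airing period: ", period)
  c(LP = lp - 1L, AP = ap - 1L)
}

#' Extract the 36-feature vector from a front/rear ROI pair
#'
#' Twelve colour statistics and five GLCM Haralick statistics per
#' surface, plus the encoded leaf position and airing period. All image
#' statistics are computed over mask pixels only.
#'
#' @param front,rear [roi_image()] objects for the two surfaces.
#' @param position,period leaf metadata, see [encode_metadata()].
#' @param cfg a [texture_config()].
#' @return named numeric vector of the 36 values of [feature_names()].
#' @export
extract_features <- function(front, rear, position, period,
                             cfg = texture_config()) {
  surf <- function(roi) {
    cs <- color_stats(roi)
    g <- glcm_matrix(rgb_to_gray(roi$image), roi$mask, cfg)
    c(cs, haralick_features(g, log_base = cfg$log_base))
  }
  f <- surf(front); r <- surf(rear)
  meta <- encode_metadata(position, period)
  out <- c(setNames(f, paste0(names(f), "_f")),
           setNames(r, paste0(names(r), "_r")),
           meta)
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Write / read a feature table as CSV
#'
#' The header is the 36 abbreviations of [feature_names()] plus a
#' `moisture` column holding the wet-basis moisture fraction in
#' `[0, 1]`.
#'
#' @param table data.frame with the 36 feature columns and `moisture`.
#' @param path CSV file path.
#' @return `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  miss <- setdiff(feature_names(), names(tab))
  if (length(miss)) stop_input("missing feature columns: ",
                               paste(miss, collapse = ", "))
  tab
}
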