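#' Segmentation configuration
#'
#' Parameters of the dual-mask leaf segmentation. The HSV window defaults
#' to `t_min = c(15, 20, 15)`, `t_max = c(175, 255, 255)` on the integer
#' HSV scale (hue 0--179, saturation/value 0--255), which passes the green
#' through brown hues a curing leaf traverses while excluding the
#' near-white, low-saturation background. Both bounds are inclusive.
#'
#' @param t_min,t_max integer 3-vectors `(h, s, v)`; lower and upper
#'   inclusive bounds of the HSV foreground window.
#' @param median_kernel odd integer >= 3, side of the median smoothing
#'   window applied to the grayscale image before Otsu thresholding.
#' @param min_component_fraction minimum mask area as a fraction of image
#'   area below which segmentation reports "no leaf found".
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(t_min = c(15, 20, 15),
                                t_max = c(175, 255, 255),
                                median_kernel = 5,
                                min_component_fraction = 0.01) {
  t_min <- as.numeric(t_min); t_max <- as.numeric(t_max)
  if (length(t_min) != 3L || length(t_max) != 3L)
    stop_input("t_min and t_max must be 3-vectors (h, s, v)")
  if (any(t_min > t_max))
    stop_input("t_min must be componentwise <= t_max")
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 3L || median_kernel %% 2L == 0L)
    stop_input("median_kernel must be an odd integer >= 3")
  structure(list(t_min = t_min, t_max = t_max,
                 median_kernel = median_kernel,
                 min_component_fraction = min_component_fraction),
            class = "segmentation_config")
}

check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input("expected an H x W x 3 RGB array")
  if (dim(img)[1] < 8L || dim(img)[2] < 8L)
    stop_input("image must be at least 8 x 8 pixels")
  if (min(img) < 0 || max(img) > 255)
    stop_input("RGB values must lie in [0, 255]")
  invisible(img)
}

#' Convert an RGB image to integer-scaled HSV
#'
#' Standard hexcone conversion with hue mapped to the integer scale
#' 0--179 (degrees / 2) and saturation/value to 0--255.
#'
#' @param img H x W x 3 RGB array, values 0--255.
#' @return H x W x 3 integer array; hue in `[0, 179]`, s and v in
#'   `[0, 255]`.
#' @export
rgb_to_hsv_int <- function(img) {
  check_rgb_image(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- floor(hsv[1, ] * 180 + 0.5) %% 180
  s <- round(hsv[2, ] * 255)
  v <- round(hsv[3, ] * 255)
  out <- array(0L, dim = d)
  out[, , 1] <- as.integer(h); out[, , 2] <- as.integer(s)
  out[, , 3] <- as.integer(v)
  out
}

#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img H x W x 3 RGB array, values 0--255.
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
rgb_to_gray <- function(img) {
  check_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' HSV window threshold mask
#'
#' A pixel is foreground iff all three HSV channels lie inclusively
#' between `t_min` and `t_max` of the configuration.
#'
#' @param hsv H x W x 3 integer HSV array from [rgb_to_hsv_int()].
#' @param cfg a [segmentation_config()].
#' @return H x W logical mask.
#' @export
hsv_threshold_mask <- function(hsv, cfg = segmentation_config()) {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    stop_input("expected an H x W x 3 HSV array")
  if (max(hsv[, , 1]) > 179 || min(hsv) < 0)
    stop_input("HSV channels out of range (hue 0-179, s/v 0-255)")
  ok <- hsv[, , 1] >= cfg$t_min[1] & hsv[, , 1] <= cfg$t_max[1] &
    hsv[, , 2] >= cfg$t_min[2] & hsv[, , 2] <= cfg$t_max[2] &
    hsv[, , 3] >= cfg$t_min[3] & hsv[, , 3] <= cfg$t_max[3]
  ok
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustively maximizes the between-class variance over the 256
#' candidate gray levels and returns both the threshold and a binary
#' mask. With `polarity = "dark"` (the default) the mask marks the
#' darker class -- the leaf, when the background is bright.
#'
#' @param gray numeric matrix with values in `[0, 255]`; needs at least
#'   two distinct values.
#' @param polarity `"dark"` to mark the class at or below the threshold,
#'   `"bright"` for the class above it.
#' @return list with `level` (integer threshold) and `mask` (logical
#'   matrix).
#' @export
otsu_threshold <- function(gray, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  g <- pmin(pmax(floor(gray), 0), 255)
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop_input("Otsu threshold undefined for a constant image")
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                      # pixels <= t
  sum0 <- cumsum(counts * lev)
  total <- sum0[256]
  valid <- w0 > 0L & w0 < n                 # both classes non-empty
  mu0 <- sum0 / w0
  mu1 <- (total - sum0) / (n - w0)
  bcv <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  level <- which.max(bcv) - 1L              # lowest argmax on ties
  mask <- if (polarity == "dark") g <= level else g > level
  list(level = level, mask = mask)
}

#' Combine two binary masks by logical OR
#'
#' @param a,b logical matrices of identical shape.
#' @return logical matrix, foreground where either input is foreground.
#' @export
combine_masks <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_input("masks must have identical dimensions")
  a | b
}

# Median smoothing through EBImage's fast C implementation.
median_smooth <- function(gray, kernel = 5L) {
  r <- (as.integer(kernel) - 1L) %/% 2L
  out <- EBImage::medianFilter(EBImage::Image(gray / 255), size = r)
  EBImage::imageData(out) * 255
}

# Largest 8-connected foreground component, via a pixel-adjacency graph.
largest_component <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(mask & FALSE)
  H <- nrow(mask); W <- ncol(mask)
  id <- integer(H * W); id[idx] <- seq_along(idx)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(offs)) {
    nr <- row + offs[[k]][1]; nc <- col + offs[[k]][2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nidx <- (nc[ok] - 1L) * H + nr[ok]
    ok2 <- mask[nidx]
    edges[[k]] <- rbind(id[idx[ok]][ok2], id[nidx[ok2]])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(em), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- mask & FALSE
  out[idx[keep]] <- TRUE
  out
}

# Fill interior holes of a binary mask.
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(filled) > 0.5
}

#' Segment the leaf region of a photograph
#'
#' The dual-mask procedure: an HSV window threshold produces one binary
#' mask; in parallel the image is converted to grayscale, median
#' smoothed, and Otsu-thresholded (dark class) to produce a second; the
#' two are OR-combined, reduced to the largest 8-connected component,
#' and interior holes are filled. Combining a colour window with an
#' intensity split keeps the segmentation robust as the leaf turns from
#' saturated green to dark brown over the curing process.
#'
#' @param img H x W x 3 RGB array, values 0--255.
#' @param cfg a [segmentation_config()].
#' @return an object of class `roi_image`: list with `image` (the input)
#'   and `mask` (logical H x W matrix with at least one foreground
#'   pixel).
#' @export
segment_leaf <- function(img, cfg = segmentation_config()) {
  check_rgb_image(img)
  hsv <- rgb_to_hsv_int(img)
  m_hsv <- hsv_threshold_mask(hsv, cfg)
  gray <- rgb_to_gray(img)
  smoothed <- median_smooth(gray, cfg$median_kernel)
  m_otsu <- tryCatch(otsu_threshold(smoothed, polarity = "dark")$mask,
                     error = function(e) m_hsv & FALSE)
  combined <- combine_masks(m_hsv, m_otsu)
  cleaned <- fill_holes(largest_component(combined))
  if (sum(cleaned) < cfg$min_component_fraction * length(cleaned))
    stop_input("no leaf found: mask area below ",
               cfg$min_component_fraction, " of the image")
  roi_image(img, cleaned)
}

#' Construct a region-of-interest image
#'
#' @param image H x W x 3 RGB array.
#' @param mask logical H x W matrix, at least one foreground pixel.
#' @return object of class `roi_image`.
#' @export
roi_image <- function(image, mask) {
  check_rgb_image(image)
  if (!identical(dim(mask), dim(image)[1:2]))
    stop_input("mask shape must match the image")
  if (!any(mask)) stop_input("mask has no foreground pixels")
  structure(list(image = image, mask = mask), class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<roi_image> %d x %d px, %d leaf pixels (%.1f%%)\n",
              d[1], d[2], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Read a leaf photograph from disk
#'
#' @param path a PNG or JPG file.
#' @return H x W x 3 integer RGB array, values 0--255.
#' @export
read_leaf_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_input("reading JPEG requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else stop_input("unsupported image format: ", ext)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
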