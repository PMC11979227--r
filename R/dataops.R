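#' Wet-basis moisture content from weighings
#'
#' A leaf is weighed before and after oven drying to constant weight,
#' together with its container; moisture is the lost water mass over
#' the wet leaf mass:
#' \deqn{MC = \frac{(M_{leaf}-M_0) - (M_{dry}-M_0)}{M_{leaf}-M_0}}
#'
#' @param m_leaf grams, container + wet leaf.
#' @param m_dry grams, container + dried leaf.
#' @param m0 grams, container alone.
#' @return moisture fraction in `[0, 1)`.
#' @export
moisture_content <- function(m_leaf, m_dry, m0) {
  if (any(m_leaf <= m0)) stop_input("invalid weights: m_leaf must exceed m0")
  if (any(m_dry > m_leaf) || any(m_dry < m0))
    stop_input("invalid weights: need m_leaf >= m_dry >= m0")
  ((m_leaf - m0) - (m_dry - m0)) / (m_leaf - m0)
}

#' Period-stratified train/test split
#'
#' Uniformly samples a fixed number of test rows without replacement
#' within every airing period, so the test set mirrors the moisture
#' distribution of the full campaign; the remainder form the training
#' set.
#'
#' @param table data.frame with a period column.
#' @param test_per_period test rows per period (default 35).
#' @param seed RNG seed; the split is reproducible under it.
#' @param period_col name of the period column (integer codes or
#'   names).
#' @return list with `train` and `test` data.frames (disjoint,
#'   exhaustive) and `test_idx`, the sampled row indices.
#' @export
stratified_split <- function(table, test_per_period = 35L, seed = 1L,
                             period_col = "AP") {
  if (!period_col %in% names(table))
    stop_input("no period column '", period_col, "' in the table")
  if (test_per_period < 1L) stop_input("test_per_period must be >= 1")
  per <- table[[period_col]]
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), per), function(rows) {
      if (length(rows) <= test_per_period)
        stop_input("a period has only ", length(rows),
                   " samples; nothing would be left for training")
      sample(rows, test_per_period)
    }), use.names = FALSE)
  })
  list(train = table[-idx, , drop = FALSE],
       test = table[idx, , drop = FALSE],
       test_idx = sort(idx))
}

#' Standardize features to zero mean, unit variance
#'
#' Means and (sample, n-1) standard deviations are learned from the
#' training table only and the same affine transform is applied to the
#' test table, avoiding test-set leakage.
#'
#' @param train,test data.frames; `test` may be `NULL`.
#' @param exclude column names left untouched (e.g. the target).
#' @return list with `train`, `test` (transformed) and `standardizer`
#'   (per-feature `mean` and `sd`). The standardizer can be re-applied
#'   with [apply_standardizer()].
#' @export
standardize_features <- function(train, test = NULL,
                                 exclude = "moisture") {
  cols <- setdiff(names(train), exclude)
  mu <- vapply(train[cols], mean, numeric(1))
  s <- vapply(train[cols], sd, numeric(1))
  if (any(s == 0))
    stop_input("constant training feature(s): ",
               paste(cols[s == 0], collapse = ", "))
  std <- structure(list(mean = mu, sd = s, cols = cols),
                   class = "standardizer")
  list(train = apply_standardizer(std, train),
       test = if (!is.null(test)) apply_standardizer(std, test),
       standardizer = std)
}

#' @rdname standardize_features
#' @param std a `standardizer`.
#' @param table data.frame to transform.
#' @export
apply_standardizer <- function(std, table) {
  stopifnot(inherits(std, "standardizer"))
  for (c in std$cols) {
    table[[c]] <- (table[[c]] - std$mean[[c]]) / std$sd[[c]]
  }
  table
}
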