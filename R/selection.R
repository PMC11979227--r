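#' Pearson correlation coefficient
#'
#' Thin, validating wrapper around the Pearson product-moment
#' correlation used throughout the feature filter.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_input("pcc needs two vectors of equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop_input("pcc undefined for a zero-variance vector")
  cor(x, y, method = "pearson")
}

#' Categorize features by correlation with the target
#'
#' Each feature's Pearson correlation with the target is computed and
#' the feature is classed by |PCC|: above 0.75 "important", between
#' 0.45 and 0.75 "relatively important", at or below 0.45
#' "unimportant". Constant features cannot be correlated and are
#' classed unimportant with an audit note. The full feature-feature
#' |PCC| matrix is retained for the redundancy step.
#'
#' @param table data.frame of feature columns plus the target column.
#' @param target name of the target column (default `"moisture"`).
#' @param important,relevant the two |PCC| category boundaries.
#' @return object of class `correlation_report`: `target_pcc` (named,
#'   sorted by |PCC| descending, ties in original column order),
#'   `category` (named factor-like character), `autocorr` (|PCC|
#'   matrix), `notes`.
#' @export
categorize_by_target <- function(table, target = "moisture",
                                 important = 0.75, relevant = 0.45) {
  if (!target %in% names(table)) stop_input("no such target column: ", target)
  if (nrow(table) < 3L) stop_input("need at least 3 samples")
  feats <- setdiff(names(table), target)
  y <- table[[target]]
  notes <- character(0)
  r <- vapply(feats, function(f) {
    x <- table[[f]]
    if (sd(x) == 0) {
      notes[[f]] <<- "constant feature; correlation undefined"
      return(0)
    }
    pcc(x, y)
  }, numeric(1))
  cat_of <- function(a) {
    ifelse(a > important, "important",
           ifelse(a > relevant, "relatively_important", "unimportant"))
  }
  category <- setNames(cat_of(abs(r)), feats)
  category[names(notes)] <- "unimportant"
  X <- as.matrix(table[feats])
  keepable <- apply(X, 2, sd) > 0
  ac <- matrix(0, length(feats), length(feats),
               dimnames = list(feats, feats))
  if (any(keepable)) {
    sub <- abs(cor(X[, keepable, drop = FALSE]))
    ac[keepable, keepable] <- sub
  }
  diag(ac) <- 1
  ord <- order(-abs(r), seq_along(feats))   # ties: original column order
  structure(list(target_pcc = r[ord], category = category[ord],
                 autocorr = ac, notes = notes,
                 thresholds = c(important = important, relevant = relevant)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  tab <- table(x$category)
  cat("<correlation_report>", length(x$target_pcc), "features:",
      paste(names(tab), unname(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Prune redundant features
#'
#' Second step of the two-step filter. Unimportant features are dropped
#' outright. The remainder are visited in descending |PCC|-with-target
#' order (ties broken by original column order); a feature is dropped
#' when its |PCC| with any already-retained feature reaches
#' `autocorr_threshold`. Two texture-feature backstops mirror the
#' filter's rationale: the texture feature most correlated with the
#' target, and the texture feature least correlated with the retained
#' set, are kept even if the greedy pass would drop them.
#'
#' @param report a [categorize_by_target()] result.
#' @param autocorr_threshold |PCC| at or above which two features are
#'   considered redundant (default 0.80).
#' @param texture_names names treated as texture features for the
#'   backstop rule; defaults to the GLCM statistics of both surfaces.
#' @return object of class `feature_subset`: `retained` (ordered names),
#'   `removed` (data.frame of name + reason).
#' @export
prune_redundant <- function(report, autocorr_threshold = 0.80,
                            texture_names = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  if (all(report$category == "unimportant"))
    stop_input("no feature passes the relevance step")
  if (is.null(texture_names)) {
    tex <- c("ASM", "CON", "Corr", "Entr", "IDM")
    texture_names <- c(paste0(tex, "_f"), paste0(tex, "_r"))
  }
  ac <- report$autocorr
  removed <- data.frame(feature = character(0), reason = character(0))
  drop_note <- function(f, why) {
    removed <<- rbind(removed, data.frame(feature = f, reason = why))
  }
  for (f in names(report$category)[report$category == "unimportant"]) {
    why <- if (f %in% names(report$notes)) report$notes[[f]] else
      sprintf("unimportant: |PCC| with target %.3f <= %.2f",
              abs(report$target_pcc[[f]]), report$thresholds[["relevant"]])
    drop_note(f, why)
  }
  cand <- names(report$category)[report$category != "unimportant"]
  retained <- character(0)
  for (f in cand) {
    clash <- retained[ac[f, retained] >= autocorr_threshold]
    if (length(clash)) {
      drop_note(f, sprintf("redundant: |PCC| %.3f with retained %s",
                           ac[f, clash[1]], clash[1]))
    } else {
      retained <- c(retained, f)
    }
  }
  # Texture backstops: keep the most target-relevant texture feature and
  # the texture feature least correlated with everything retained.
  tex_cand <- intersect(cand, texture_names)
  if (length(tex_cand)) {
    top_tex <- tex_cand[1]                  # cand is |PCC|-ordered
    if (!top_tex %in% retained) {
      retained <- c(retained, top_tex)
      removed <- removed[removed$feature != top_tex, ]
    }
    max_ac <- vapply(tex_cand, function(f) {
      others <- setdiff(retained, f)
      if (length(others) == 0L) 0 else max(ac[f, others])
    }, numeric(1))
    least <- tex_cand[which.min(max_ac)]
    if (!least %in% retained) {
      retained <- c(retained, least)
      removed <- removed[removed$feature != least, ]
    }
  }
  # Restore original column order for the retained list.
  orig <- rownames(ac)
  retained <- orig[orig %in% retained]
  structure(list(retained = retained, removed = removed,
                 autocorr_threshold = autocorr_threshold),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("<feature_subset>", length(x$retained), "retained,",
      nrow(x$removed), "removed\n")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Two-step correlation feature filter
#'
#' Convenience wrapper: relevance categorization followed by redundancy
#' pruning.
#'
#' @inheritParams categorize_by_target
#' @inheritParams prune_redundant
#' @return a [prune_redundant()] `feature_subset`.
#' @export
select_features <- function(table, target = "moisture",
                            important = 0.75, relevant = 0.45,
                            autocorr_threshold = 0.80) {
  rep <- categorize_by_target(table, target, important, relevant)
  prune_redundant(rep, autocorr_threshold)
}
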