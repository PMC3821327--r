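#' Maximum resistance-change feature of an e-nose record
#'
#' The per-sensor feature is the maximum over the 180 s trace of the
#' absolute deviation from the pre-injection baseline,
#' `max_t |R_s(t) - baseline_s|` (metal-oxide sensors can rise or fall).
#' `mode = "relative"` divides by the baseline; `mode = "signed"` keeps the
#' sign of the largest deviation.
#'
#' @param record an [enose_record()].
#' @param mode `"absolute"` (default), `"relative"` or `"signed"`.
#' @return numeric vector of 18 features.
#' @export
max_delta_r <- function(record, mode = c("absolute", "relative", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "enose_record"))
  delta <- record$resistances - record$baseline # recycles baseline by row
  if (mode == "signed") {
    apply(delta, 1L, function(d) d[which.max(abs(d))])
  } else {
    f <- apply(abs(delta), 1L, max)
    if (mode == "relative") {
      if (any(record$baseline <= 0)) stop_format("non-positive baseline")
      f <- f / record$baseline
    }
    f
  }
}

#' Principal component analysis of a feature matrix
#'
#' Column-mean-centered PCA (no scaling by default; `scale. = TRUE` for
#' unit-variance scaling), with components ordered by explained variance.
#' Thin wrapper around [stats::prcomp()] exposing scores, loadings and
#' explained-variance fractions.
#'
#' @param features numeric matrix, samples x variables (>= 2 samples).
#' @param scale. logical, scale columns to unit variance.
#' @return a `pca_result`: `scores`, `loadings`,
#'   `explained_variance_fraction`.
#' @export
pca <- function(features, scale. = FALSE) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop_format("PCA needs >= 2 samples")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- fit$sdev^2
  structure(
    list(scores = fit$x, loadings = fit$rotation,
         explained_variance_fraction = ev / sum(ev),
         center = fit$center),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d component(s); PC1 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance_fraction[1]))
  invisible(x)
}

#' Build the e-nose feature matrix for a cohort
#'
#' One row per injection (replicate), 18 max resistance-change features
#' each, plus the replicate grouping and per-row labels needed by [loocv()].
#'
#' @param records_by_sample named list (sample id -> list of
#'   [enose_record()] replicates).
#' @param labels group label per sample (aligned with
#'   `names(records_by_sample)`).
#' @param mode feature mode, see [max_delta_r()].
#' @param average_replicates if `TRUE`, replicates are averaged into one
#'   feature row per sample instead of being kept and grouped.
#' @return list with `features` (matrix), `labels`, `groups`.
#' @export
enose_feature_matrix <- function(records_by_sample, labels,
                                 mode = "absolute",
                                 average_replicates = FALSE) {
  stopifnot(length(records_by_sample) == length(labels))
  ids <- names(records_by_sample)
  rows <- list(); row_labels <- character(0); row_groups <- character(0)
  for (i in seq_along(records_by_sample)) {
    feats <- lapply(records_by_sample[[i]], max_delta_r, mode = mode)
    if (average_replicates) feats <- list(Reduce(`+`, feats) / length(feats))
    for (f in feats) {
      rows[[length(rows) + 1L]] <- f
      row_labels <- c(row_labels, as.character(labels[i]))
      row_groups <- c(row_groups, ids[i])
    }
  }
  list(features = do.call(rbind, rows),
       labels = as_group_label(row_labels),
       groups = row_groups)
}

#' Classify an e-nose cohort by replicate-grouped leave-one-out LDA + KNN
#'
#' Features are the per-sensor maximum resistance changes; all replicates of
#' a biological sample are held out together and vote by majority.
#'
#' @inheritParams enose_feature_matrix
#' @param k KNN neighbourhood size.
#' @param regularization LDA ridge factor.
#' @return a `classification_report`.
#' @export
enose_classify <- function(records_by_sample, labels, mode = "absolute",
                           k = 3L, regularization = 1e-6,
                           average_replicates = FALSE) {
  fm <- enose_feature_matrix(records_by_sample, labels, mode = mode,
                             average_replicates = average_replicates)
  loocv(fm$features, fm$labels, groups = fm$groups, k = k,
        regularization = regularization)
}
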