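#' Analytic chance null for random reclassification
#'
#' Under prior-proportional random assignment (each sample independently
#' assigned class `c` with probability `p_c`, the observed class
#' proportion), the expected accuracy is `sum_c p_c^2` and its standard
#' deviation `sqrt(mean (1 - mean) / n)`. A permutation alternative
#' (reshuffle the labels and score agreement, `n_perm` times) is available
#' as a cross-check; its mean agrees with the analytic value.
#'
#' @param labels vector of class labels, length >= 1.
#' @param method `"analytic"` (default) or `"permutation"`.
#' @param n_perm permutations for `method = "permutation"` (>= 200 advised).
#' @return a `chance_null`: `mean`, `sd`, `n`, `class_proportions`, and for
#'   the permutation method `se` (Monte-Carlo standard error of the mean).
#' @export
chance_null <- function(labels, method = c("analytic", "permutation"),
                        n_perm = 200L) {
  method <- match.arg(method)
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0L) stop_format("empty labels")
  p <- as.numeric(table(labels)) / n
  mean_an <- sum(p^2)
  sd_an <- sqrt(mean_an * (1 - mean_an) / n)
  out <- list(mean = mean_an, sd = sd_an, n = n,
              class_proportions = stats::setNames(p, names(table(labels))),
              method = method)
  if (method == "permutation") {
    acc <- vapply(seq_len(n_perm), function(i) mean(sample(labels) == labels),
                  numeric(1))
    out$mean <- mean(acc)
    out$sd <- stats::sd(acc)
    out$se <- out$sd / sqrt(n_perm)
    out$analytic_mean <- mean_an
  }
  structure(out, class = "chance_null")
}

#' @export
print.chance_null <- function(x, ...) {
  cat(sprintf("<chance_null> mean %.4f, sd %.4f (n = %d, %s)\n",
              x$mean, x$sd, x$n, x$method))
  invisible(x)
}

#' Collapse three-class predictions to BAM vs non-BAM and score agreement
#'
#' Relabels `UC` and `CONTROL` (truth and prediction alike) as non-BAM
#' before scoring, so a UC sample predicted CONTROL counts as correct.
#'
#' @param truth,predicted vectors of group labels.
#' @return binary accuracy in `[0, 1]`.
#' @export
collapse_binary <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  mean((truth == "BAD") == (predicted == "BAD"))
}

classification_report <- function(truth, predicted, config = list()) {
  truth <- factor(as.character(truth), levels = union(levels(factor(truth)),
                                                      unique(predicted)))
  predicted <- factor(as.character(predicted), levels = levels(truth))
  confusion <- table(truth = truth, predicted = predicted)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(
    list(confusion = confusion,
         per_class_accuracy = per_class,
         overall_accuracy = sum(diag(confusion)) / length(truth),
         binary_accuracy = collapse_binary(truth, predicted),
         truth = as.character(truth), predicted = as.character(predicted),
         config_echo = config),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat(sprintf("  overall accuracy: %.3f\n", x$overall_accuracy))
  cat(sprintf("  BAM vs non-BAM:  %.3f\n", x$binary_accuracy))
  for (g in names(x$per_class_accuracy)) {
    cat(sprintf("  %-8s %.3f\n", g, x$per_class_accuracy[[g]]))
  }
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out reclassification with LDA + KNN
#'
#' For every held-out unit, any configured variable selection and the LDA
#' fit use the remaining samples only (no information leakage), the
#' held-out rows are projected into the refit discriminant space and
#' classified by KNN, and -- when a unit has several rows (technical
#' replicates of one biological sample) -- the rows are held out together
#' and vote by majority on the unit's label (ties resolved in label-level
#' order).
#'
#' @param features numeric matrix, rows = measurements.
#' @param labels class label per row.
#' @param groups optional biological-sample id per row; rows sharing an id
#'   are held out together. Default: every row is its own unit.
#' @param select optional selection config: a list with `within_threshold`,
#'   `between_threshold` and optional `within_dir`, `between_dir`; refit per
#'   fold via [compute_scatter_stats()] + [select_variables()].
#' @param k KNN neighbourhood size (default 3).
#' @param regularization LDA ridge factor.
#' @param knn_space `"lda"` (classify in the discriminant projection,
#'   default) or `"raw"` (selected-variable space).
#' @return a `classification_report` scored over units.
#' @export
loocv <- function(features, labels, groups = NULL, select = NULL, k = 3L,
                  regularization = 1e-6, knn_space = c("lda", "raw")) {
  knn_space <- match.arg(knn_space)
  x <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (is.null(groups)) groups <- seq_len(nrow(x))
  groups <- as.character(groups)
  stopifnot(length(labels) == nrow(x), length(groups) == nrow(x))
  units <- unique(groups)
  unit_rows <- split(seq_len(nrow(x)), factor(groups, levels = units))
  unit_label <- vapply(unit_rows, function(r) {
    ul <- unique(as.character(labels[r]))
    if (length(ul) != 1L) stop_format("unit with inconsistent labels")
    ul
  }, character(1))
  # every class must keep >= 2 rows when its largest unit is held out
  for (cl in levels(labels)) {
    rows_cl <- sum(labels == cl)
    max_unit <- max(vapply(unit_rows[unit_label == cl], length, integer(1)))
    if (rows_cl - max_unit < 2L) {
      stop_format("class %s would retain < 2 samples when a unit is held out", cl)
    }
  }
  preds <- character(length(units))
  for (u in seq_along(units)) {
    test_rows <- unit_rows[[u]]
    train_rows <- setdiff(seq_len(nrow(x)), test_rows)
    cols <- seq_len(ncol(x))
    if (!is.null(select)) {
      st <- compute_scatter_stats(x[train_rows, , drop = FALSE],
                                  labels[train_rows])
      cols <- select_variables(
        st, select$within_threshold, select$between_threshold,
        within_dir = select$within_dir %||% "<",
        between_dir = select$between_dir %||% ">")
      if (length(cols) == 0L) {
        stop_format("variable selection left 0 variables for unit %s", units[u])
      }
    }
    preds[u] <- predict_unit(x, labels, train_rows, test_rows, cols,
                             k, regularization, knn_space)
  }
  classification_report(
    unit_label, preds,
    config = list(k = k, regularization = regularization,
                  knn_space = knn_space, select = select,
                  grouped = !is.null(groups)))
}

# fit on train rows/cols, classify test rows, majority vote -> one label
predict_unit <- function(x, labels, train_rows, test_rows, cols,
                         k, regularization, knn_space) {
  xtr <- x[train_rows, cols, drop = FALSE]
  xte <- x[test_rows, cols, drop = FALSE]
  ltr <- droplevels(labels[train_rows])
  if (knn_space == "lda") {
    model <- fit_lda(xtr, ltr, regularization = regularization)
    xtr <- project_lda(model, xtr)
    xte <- project_lda(model, xte)
  }
  votes <- as.character(knn_classify(xtr, ltr, xte, k = k))
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else {
    intersect(levels(labels), winners)[1] # deterministic tie-break
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
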