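#' Explore the 2-D scatter-threshold space with leave-one-out scoring
#'
#' For every cell of a (within-threshold x between-threshold) grid the
#' pipeline selects wavelet variables, runs a full leave-one-out LDA + KNN
#' reclassification -- with the scatter statistics and the selection refit
#' on the retained samples of every fold, so the held-out sample never
#' informs its own classifier -- and records the accuracy and the
#' full-data selected-variable count. Cells whose selection is empty or
#' exceeds `cap` variables (in any fold or on the full data) are marked
#' undefined with a reason.
#'
#' Default grid: 20 x 20 thresholds at the empirical quantiles
#' 2.5%, 7.5%, ..., 97.5% of each statistic (between quantiles over finite
#' values only), giving scale-free coverage of the threshold space.
#'
#' @param features numeric matrix, samples x variables (wavelet
#'   coefficients for the FAIMS route).
#' @param labels group label per row.
#' @param n_within,n_between grid resolution.
#' @param within_thresholds,between_thresholds explicit grids (override the
#'   quantile defaults).
#' @param k KNN neighbourhood size.
#' @param cap maximum selected variables per cell; default
#'   `min(n_samples - n_classes, 500)` keeps LDA well-posed.
#' @param groups optional replicate grouping passed through to the
#'   leave-one-out loop.
#' @param within_dir,between_dir selection directions, see
#'   [select_variables()].
#' @param regularization LDA ridge factor.
#' @return a `threshold_grid_result`: `within_thresholds`,
#'   `between_thresholds`, matrices `accuracy` (NA where undefined),
#'   `n_selected`, `robust_mask`, `undefined_reason`, plus `null`
#'   (the analytic [chance_null()] of the unit labels), `stats`
#'   (full-data scatter stats) and `config`.
#' @export
explore_threshold_grid <- function(features, labels,
                                   n_within = 20L, n_between = 20L,
                                   within_thresholds = NULL,
                                   between_thresholds = NULL,
                                   k = 3L, cap = NULL, groups = NULL,
                                   within_dir = "<", between_dir = ">",
                                   regularization = 1e-6) {
  x <- as.matrix(features)
  labels <- droplevels(factor(labels))
  n <- nrow(x)
  C <- nlevels(labels)
  if (is.null(cap)) cap <- min(n - C, 500L)
  if (is.null(groups)) groups <- seq_len(n)
  groups <- as.character(groups)

  stats_full <- compute_scatter_stats(x, labels)
  if (is.null(within_thresholds)) {
    within_thresholds <- grid_quantiles(stats_full$within, n_within)
  }
  if (is.null(between_thresholds)) {
    between_thresholds <- grid_quantiles_tail(stats_full$between, n_between)
  }
  nw <- length(within_thresholds); nb <- length(between_thresholds)

  units <- unique(groups)
  unit_rows <- split(seq_len(n), factor(groups, levels = units))
  unit_label <- vapply(unit_rows, function(r)
    as.character(labels[r[1]]), character(1))
  null <- chance_null(unit_label)

  n_selected <- matrix(NA_integer_, nw, nb)
  undefined <- matrix(NA_character_, nw, nb)
  for (i in seq_len(nw)) {
    for (j in seq_len(nb)) {
      sel <- select_variables(stats_full, within_thresholds[i],
                              between_thresholds[j], within_dir, between_dir)
      n_selected[i, j] <- length(sel)
      if (length(sel) == 0L) undefined[i, j] <- "no variables selected"
      else if (length(sel) > cap) {
        undefined[i, j] <- sprintf("%d variables exceeds cap %d",
                                   length(sel), cap)
      }
    }
  }

  correct <- matrix(0L, nw, nb)
  suff <- class_sufficient_stats(x, labels)
  for (u in seq_along(units)) {
    test_rows <- unit_rows[[u]]
    train_rows <- setdiff(seq_len(n), test_rows)
    # fold scatter stats by downdating the class sufficient statistics
    held <- x[test_rows, , drop = FALSE]
    ci <- match(unit_label[u], rownames(suff$S))
    n_f <- suff$n; S_f <- suff$S; Q_f <- suff$Q
    n_f[ci] <- n_f[ci] - length(test_rows)
    S_f[ci, ] <- S_f[ci, ] - colSums(held)
    Q_f[ci, ] <- Q_f[ci, ] - colSums(held^2)
    if (n_f[ci] < 2L) {
      stop_format("class %s retains < 2 samples in a fold", unit_label[u])
    }
    st_f <- scatter_from_suff(n_f, S_f, Q_f)
    sel_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nw)) {
      for (j in seq_len(nb)) {
        if (!is.na(undefined[i, j])) next
        sel <- select_variables(st_f, within_thresholds[i],
                                between_thresholds[j], within_dir, between_dir)
        if (length(sel) == 0L) {
          undefined[i, j] <- sprintf("fold %s selected 0 variables", units[u])
          next
        }
        if (length(sel) > cap) {
          undefined[i, j] <- sprintf("fold %s selected %d variables (cap %d)",
                                     units[u], length(sel), cap)
          next
        }
        key <- paste(sel, collapse = ",")
        pred <- sel_cache[[key]]
        if (is.null(pred)) {
          pred <- predict_unit(x, labels, train_rows, test_rows, sel,
                               k, regularization, "lda")
          sel_cache[[key]] <- pred
        }
        if (pred == unit_label[u]) correct[i, j] <- correct[i, j] + 1L
      }
    }
  }
  accuracy <- correct / length(units)
  accuracy[!is.na(undefined)] <- NA_real_
  robust_mask <- !is.na(accuracy) & accuracy > null$mean + 3 * null$sd
  structure(
    list(within_thresholds = within_thresholds,
         between_thresholds = between_thresholds,
         accuracy = accuracy, n_selected = n_selected,
         robust_mask = robust_mask, undefined_reason = undefined,
         null = null, stats = stats_full,
         config = list(k = k, cap = cap, within_dir = within_dir,
                       between_dir = between_dir,
                       regularization = regularization)),
    class = "threshold_grid_result"
  )
}

# linear quantile grid over the finite values of a statistic
grid_quantiles <- function(values, n) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stop_format("no finite values to build a threshold grid")
  q <- unname(stats::quantile(v, probs = seq(0.025, 0.975, length.out = n),
                              type = 7))
  unique(q)
}

# upper-tail quantile grid: with tens of thousands of variables, only
# thresholds deep in the upper tail of the between statistic yield
# selections small enough for LDA, so the exceedance fractions are
# log-spaced from 50% down to ~2 variables
grid_quantiles_tail <- function(values, n) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stop_format("no finite values to build a threshold grid")
  lo <- min(0.5, 2 / length(v))
  probs <- 1 - 10^seq(log10(0.5), log10(lo), length.out = n)
  unique(unname(stats::quantile(v, probs = probs, type = 7)))
}

#' @export
print.threshold_grid_result <- function(x, ...) {
  defined <- sum(!is.na(x$accuracy))
  cat(sprintf("<threshold_grid_result> %d x %d grid, %d defined cell(s), %d robust\n",
              length(x$within_thresholds), length(x$between_thresholds),
              defined, sum(x$robust_mask)))
  if (defined > 0L) {
    cat(sprintf("  best accuracy %.3f (chance %.3f + 3 sd = %.3f)\n",
                max(x$accuracy, na.rm = TRUE), x$null$mean,
                x$null$mean + 3 * x$null$sd))
  }
  invisible(x)
}

#' Locate the robust region of a threshold grid
#'
#' Robust cells are those whose leave-one-out accuracy exceeds the chance
#' null's mean by more than three standard deviations. The chosen cell is
#' the robust cell of maximal accuracy; ties prefer more selected variables,
#' then a smaller within-threshold. If no cell is robust the result says so
#' explicitly rather than raising an error.
#'
#' @param result a [explore_threshold_grid()] result.
#' @param null optional [chance_null()] override (must match the label
#'   composition used for the grid).
#' @return a `robust_region`: `robust` (logical), `mask`, and -- when
#'   robust -- `cell` (grid indices), `within_threshold`,
#'   `between_threshold`, `accuracy`, `variables` (full-data selection of
#'   the chosen cell).
#' @export
find_robust_region <- function(result, null = NULL) {
  stopifnot(inherits(result, "threshold_grid_result"))
  if (is.null(null)) null <- result$null
  mask <- !is.na(result$accuracy) &
    result$accuracy > null$mean + 3 * null$sd
  if (!any(mask)) {
    return(structure(list(robust = FALSE, mask = mask,
                          message = "no robust region"),
                     class = "robust_region"))
  }
  cand <- which(mask, arr.ind = TRUE)
  acc <- result$accuracy[cand]
  nsel <- result$n_selected[cand]
  wt <- result$within_thresholds[cand[, 1]]
  ord <- order(-acc, -nsel, wt)
  best <- cand[ord[1], , drop = TRUE]
  vars <- select_variables(result$stats,
                           result$within_thresholds[best[1]],
                           result$between_thresholds[best[2]],
                           result$config$within_dir, result$config$between_dir)
  structure(
    list(robust = TRUE, mask = mask,
         cell = unname(best),
         within_threshold = result$within_thresholds[best[1]],
         between_threshold = result$between_thresholds[best[2]],
         accuracy = result$accuracy[best[1], best[2]],
         variables = vars),
    class = "robust_region"
  )
}

#' @export
print.robust_region <- function(x, ...) {
  if (!x$robust) cat("<robust_region> no robust region\n")
  else cat(sprintf(
    "<robust_region> accuracy %.3f at (within < %.4g, between > %.4g), %d variable(s)\n",
    x$accuracy, x$within_threshold, x$between_threshold, length(x$variables)))
  invisible(x)
}
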