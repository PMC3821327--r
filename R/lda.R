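#' Regularized Fisher linear discriminant analysis
#'
#' Maximizes the Fisher criterion (between-class over within-class variance
#' in the projected space). The pooled within-class covariance `W` is
#' regularized by adding `regularization x mean(diag(W))` to its diagonal so
#' the fit stays well-posed when the number of selected variables approaches
#' the sample count. The projection has at most `n_classes - 1` dimensions.
#' Eigenvector signs follow a fixed convention (first loading of
#' non-negligible magnitude is positive), making the fit deterministic.
#'
#' @param features numeric matrix, samples x variables.
#' @param labels class labels, >= 2 classes with >= 2 samples each.
#' @param regularization non-negative ridge factor (default `1e-6`).
#' @return an `lda_model`: `class_means`, `grand_mean`, `projection`
#'   (variables x dims), `eigenvalues`, `levels`, `regularization`.
#' @export
fit_lda <- function(features, labels, regularization = 1e-6) {
  x <- as.matrix(features)
  labels <- droplevels(factor(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop_format("LDA needs >= 2 classes")
  if (any(counts < 2L)) stop_format("LDA needs >= 2 samples per class")
  if (regularization < 0) stop_format("regularization must be >= 0")
  n <- nrow(x); d <- ncol(x); C <- length(counts)
  if (all(abs(sweep(x, 2L, x[1L, ], `-`)) < .Machine$double.eps * 100)) {
    stop_format("all samples are identical; LDA is undefined")
  }
  M <- rowsum(x, labels) / as.numeric(counts) # rowsum and table share level order
  grand <- colMeans(x)
  centered <- x - M[as.integer(labels), , drop = FALSE]
  W <- crossprod(centered) / (n - C)
  Mc <- sweep(M, 2L, grand)
  B <- crossprod(Mc * sqrt(as.numeric(counts))) / (C - 1)
  scale <- mean(diag(W))
  if (scale <= 0) scale <- max(mean(diag(B)), .Machine$double.eps)
  Wr <- W + diag(regularization * scale + scale * 1e-12, d)
  ew <- eigen(Wr, symmetric = TRUE)
  lam <- pmax(ew$values, max(ew$values) * 1e-12)
  Wmh <- ew$vectors %*% (t(ew$vectors) / sqrt(lam))
  S <- Wmh %*% B %*% Wmh
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  r <- min(C - 1L, d)
  proj <- Wmh %*% es$vectors[, seq_len(r), drop = FALSE]
  # sign convention: first loading with non-negligible magnitude is positive
  for (j in seq_len(r)) {
    col <- proj[, j]
    i <- which(abs(col) > max(abs(col)) * 1e-8)[1]
    if (col[i] < 0) proj[, j] <- -col
  }
  structure(
    list(class_means = M, grand_mean = grand, projection = proj,
         eigenvalues = es$values[seq_len(r)], levels = levels(labels),
         regularization = regularization),
    class = "lda_model"
  )
}

#' Project samples into the discriminant space of a fitted LDA model
#'
#' @param model an `lda_model` from [fit_lda()].
#' @param x numeric matrix (samples x variables) or a single vector.
#' @return numeric matrix, samples x discriminant dimensions.
#' @export
project_lda <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(as.matrix(x), 2L, model$grand_mean) %*% model$projection
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d variables -> %d discriminant dim(s)\n",
              length(x$levels), nrow(x$projection), ncol(x$projection)))
  invisible(x)
}

#' K-nearest-neighbour classification
#'
#' Euclidean distance in the supplied coordinate space, majority vote over
#' the `k` nearest training points. Vote ties are broken by the nearest
#' neighbour belonging to a tied class; exact distance ties fall back to
#' lexicographic label order, so the result never depends on training-set
#' row order.
#'
#' @param train_coords numeric matrix of training coordinates.
#' @param train_labels labels for the training rows.
#' @param query_coords numeric matrix (or vector) of query coordinates.
#' @param k neighbourhood size, `1 <= k <= nrow(train_coords)`.
#' @return factor of predicted labels, one per query row.
#' @export
knn_classify <- function(train_coords, train_labels, query_coords, k = 3L) {
  train_coords <- as.matrix(train_coords)
  if (is.null(dim(query_coords))) query_coords <- matrix(query_coords, nrow = 1L)
  query_coords <- as.matrix(query_coords)
  n <- nrow(train_coords)
  if (n == 0L) stop_format("empty training set")
  if (k < 1L || k > n) stop_format("k must lie in [1, %d]", n)
  labs <- as.character(train_labels)
  if (length(labs) != n) stop_format("one label per training row required")
  lvls <- if (is.factor(train_labels)) levels(train_labels) else sort(unique(labs))
  preds <- character(nrow(query_coords))
  for (q in seq_len(nrow(query_coords))) {
    delta <- sweep(train_coords, 2L, query_coords[q, ])
    dist <- sqrt(rowSums(delta^2))
    ord <- order(dist, labs) # distance, then label: order-invariant
    top <- labs[ord[seq_len(k)]]
    counts <- table(top)
    tied <- names(counts)[counts == max(counts)]
    preds[q] <- if (length(tied) == 1L) tied else {
      # nearest neighbour among tied classes wins
      labs[ord[match(TRUE, labs[ord] %in% tied)]]
    }
  }
  factor(preds, levels = lvls)
}
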