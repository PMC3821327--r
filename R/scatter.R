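#' Within-class and between-class scatter statistics
#'
#' For each variable (column), with `sigma_i` the sample standard deviation
#' (n-1 denominator) of the variable within class `i` and `sigma_mu` the
#' sample standard deviation of the per-class means:
#' * `within  = (sum_i sigma_i)^2` -- the class scatter;
#' * `between = sigma_mu^2 / within` -- the between-class scatter ratio.
#'
#' Degenerate conventions: a variable constant everywhere has
#' `within = 0, between = 0` (non-discriminative, never selected); a
#' variable constant within each class but with distinct class means has
#' `within = 0, between = Inf` (perfectly discriminative, passes any finite
#' threshold).
#'
#' @param features numeric matrix, samples x variables.
#' @param labels group labels, one per row; >= 2 classes with >= 2 samples
#'   each.
#' @return object of class `scatter_stats`: numeric vectors `within` and
#'   `between` of length `ncol(features)`.
#' @export
compute_scatter_stats <- function(features, labels) {
  features <- as.matrix(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  counts <- table(labels)
  if (length(counts) < 2L) stop_format("need >= 2 classes, got %d", length(counts))
  if (any(counts < 2L)) {
    stop_format("every class needs >= 2 samples (class %s has %d)",
                names(counts)[which.min(counts)], min(counts))
  }
  suff <- class_sufficient_stats(features, labels)
  scatter_from_suff(suff$n, suff$S, suff$Q)
}

# per-class sufficient statistics: counts, column sums, column sums of squares
class_sufficient_stats <- function(features, labels) {
  S <- rowsum(features, labels)
  Q <- rowsum(features^2, labels)
  list(n = as.numeric(table(labels)[rownames(S)]), S = S, Q = Q)
}

# scatter stats from sufficient statistics; n, S, Q have one row per class
scatter_from_suff <- function(n, S, Q) {
  M <- S / n # class means, classes x variables
  v <- (Q - S^2 / n) / (n - 1) # within-class variances
  v[v < 0] <- 0 # guard against cancellation
  within <- colSums(sqrt(v))^2
  C <- length(n)
  mu_bar <- colMeans(M)
  var_mu <- colSums((M - rep(mu_bar, each = C))^2) / (C - 1)
  between <- ifelse(within > 0, var_mu / within,
                    ifelse(var_mu > 0, Inf, 0))
  structure(list(within = within, between = between), class = "scatter_stats")
}

#' @export
print.scatter_stats <- function(x, ...) {
  cat(sprintf("<scatter_stats> %d variables\n", length(x$within)))
  invisible(x)
}

#' Select variables by scatter thresholds
#'
#' Default rule: `within < within_threshold` AND
#' `between > between_threshold`. Low class scatter plus high between-class
#' scatter ratio picks tight, well-separated variables; both comparison
#' directions are configurable because the selection direction for the
#' between statistic is a genuine ambiguity of the original description
#' (see the methods vignette).
#'
#' @param stats a [compute_scatter_stats()] result.
#' @param within_threshold,between_threshold finite thresholds (`Inf`/`-Inf`
#'   allowed to disable a criterion).
#' @param within_dir,between_dir comparison direction, `"<"` or `">"`
#'   (strict).
#' @return integer vector of selected variable indices.
#' @export
select_variables <- function(stats, within_threshold, between_threshold,
                             within_dir = "<", between_dir = ">") {
  stopifnot(inherits(stats, "scatter_stats"))
  cmp <- function(x, thr, dir) {
    switch(dir, "<" = x < thr, ">" = x > thr,
           stop_format("direction must be '<' or '>'"))
  }
  which(cmp(stats$within, within_threshold, within_dir) &
          cmp(stats$between, between_threshold, between_dir))
}
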