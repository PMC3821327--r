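# shared fixtures: everything is generated in code at test time

tiny_config <- function(n = 5L, effect_size = 1, noise_sd = 0.5, seed = 1L,
                        ...) {
  cohort_config(n_per_group = c(BAD = n, UC = n, CONTROL = n),
                effect_size = effect_size, noise_sd = noise_sd,
                seed = seed, ...)
}

# two well-separated Gaussian classes in `d` dimensions
separable_classes <- function(n_per_class = 6L, d = 2L, gap = 30, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  list(x = x, labels = factor(rep(c("A", "B"), each = n_per_class)))
}

# naive KNN with the documented tie rules, kept independent of the package
# implementation: majority vote over the k nearest (distance, then label
# order), vote ties resolved by the nearest neighbour in a tied class
oracle_knn <- function(train, labels, query, k) {
  labels <- as.character(labels)
  apply(query, 1L, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    ord <- order(d, labels)
    top <- labels[ord[1:k]]
    tab <- table(top)
    tied <- names(tab)[tab == max(tab)]
    if (length(tied) == 1L) tied else labels[ord][labels[ord] %in% tied][1]
  })
}

# single-level D4 analysis operator as an explicit (orthogonal) matrix
d4_level_matrix <- function(n) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  T <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (j in 0:3) {
      col <- (2 * (k - 1) + j) %% n + 1
      T[k, col] <- T[k, col] + h[j + 1]
      T[n / 2 + k, col] <- T[n / 2 + k, col] + g[j + 1]
    }
  }
  T
}
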