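test_that("LDA separates separable classes and validates input", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  labels <- c("A", "A", "B", "B")
  model <- fit_lda(x, labels)
  z <- project_lda(model, x)
  gap <- abs(mean(z[3:4, 1]) - mean(z[1:2, 1]))
  spread <- max(sd(z[1:2, 1]), sd(z[3:4, 1]))
  expect_gt(gap / spread, 100)
  expect_error(fit_lda(x, rep("A", 4)), "classes")
  expect_error(fit_lda(matrix(1, 4, 2), labels), "identical")
})

test_that("the fitted discriminant beats 1,000 random projections", {
  set.seed(7)
  means <- list(c(0, 0), c(3, 1), c(1, 4))
  x <- do.call(rbind, lapply(means, function(m)
    sweep(matrix(rnorm(24), ncol = 2), 2, -m)))
  labels <- rep(c("A", "B", "C"), each = 12)
  model <- fit_lda(x, labels, regularization = 0)
  # Fisher quotient w'Bw / w'Ww for a direction w
  M <- rowsum(x, labels) / 12
  W <- crossprod(x - M[rep(1:3, each = 12), ]) / (36 - 3)
  B <- crossprod(sweep(M, 2, colMeans(x)) * sqrt(12)) / 2
  J <- function(w) as.numeric(t(w) %*% B %*% w / (t(w) %*% W %*% w))
  J_fit <- J(model$projection[, 1])
  J_rand <- vapply(1:1000, function(i) J(rnorm(2)), numeric(1))
  expect_gte(J_fit, max(J_rand) - 1e-8)
})

test_that("LDA projections are deterministic and duplication-invariant", {
  set.seed(8)
  x <- matrix(rnorm(60), ncol = 3)
  labels <- rep(c("A", "B", "C"),
                times = c(7, 7, 6))
  a <- fit_lda(x, labels)
  b <- fit_lda(x, labels)
  expect_identical(a$projection, b$projection) # fixed sign convention
  dup <- fit_lda(cbind(x, x[, 1]), labels)
  expect_equal(project_lda(dup, cbind(x, x[, 1])), project_lda(a, x),
               tolerance = 1e-6)
})

test_that("KNN matches a brute-force oracle and honors its tie rules", {
  set.seed(9)
  train <- matrix(rnorm(40), ncol = 2)
  labels <- factor(sample(c("A", "B", "C"), 20, replace = TRUE))
  query <- matrix(rnorm(24), ncol = 2)
  got <- knn_classify(train, labels, query, k = 3L)
  expect_equal(as.character(got), unname(oracle_knn(train, labels, query, 3L)))
  # training-order permutation invariance
  perm <- sample(20)
  expect_equal(as.character(knn_classify(train[perm, ], labels[perm], query, 3L)),
               as.character(got))
  # query equal to a training point, k = 1 -> that label
  expect_equal(as.character(knn_classify(train, labels, train[5, , drop = FALSE], 1L)),
               as.character(labels[5]))
  # k = n -> majority class
  expect_equal(as.character(knn_classify(train, labels, query[1, , drop = FALSE], 20L)),
               names(which.max(table(as.character(labels)))))
  expect_error(knn_classify(train[0, , drop = FALSE], labels[0], query, 1L),
               "empty")
  expect_error(knn_classify(train, labels, query, 21L), "k must")
})

test_that("LOOCV matches an explicit hand-rolled leave-one-out loop", {
  set.seed(10)
  x <- rbind(matrix(rnorm(8, 0), ncol = 2), matrix(rnorm(8, 2), ncol = 2),
             matrix(rnorm(8, 4), ncol = 2))
  labels <- factor(rep(c("A", "B", "C"), each = 4))
  got <- loocv(x, labels, k = 3L)
  preds <- character(12)
  for (i in 1:12) {
    m <- fit_lda(x[-i, ], labels[-i])
    preds[i] <- as.character(knn_classify(project_lda(m, x[-i, ]), labels[-i],
                                          project_lda(m, x[i, ]), 3L))
  }
  expect_equal(got$predicted, preds)
  expect_equal(got$overall_accuracy, mean(preds == as.character(labels)))
  expect_equal(sum(got$confusion), 12)
  expect_equal(unname(rowSums(got$confusion)), rep(4L, 3), ignore_attr = TRUE)
})

test_that("LOOCV on far-separated classes is perfect; leakage guards hold", {
  sep <- separable_classes(n_per_class = 6L)
  expect_equal(loocv(sep$x, sep$labels)$overall_accuracy, 1)
  # grouped hold-out with a class of only 2 rows in one unit is impossible
  x <- matrix(rnorm(12), ncol = 2)
  labels <- rep(c("A", "B"), each = 3)
  groups <- c("u1", "u1", "u2", "v1", "v2", "v3")
  expect_error(loocv(x, labels, groups = groups), "retain")
})

test_that("replicate grouping degenerates to ungrouped LOOCV for 1 replicate", {
  set.seed(11)
  x <- rbind(matrix(rnorm(12, 0), ncol = 2), matrix(rnorm(12, 3), ncol = 2))
  labels <- rep(c("A", "B"), each = 6)
  a <- loocv(x, labels)
  b <- loocv(x, labels, groups = paste0("s", 1:12))
  expect_equal(a$predicted, b$predicted)
  expect_equal(a$overall_accuracy, b$overall_accuracy)
})

test_that("the analytic chance null is exact and matches permutations", {
  expect_equal(chance_null(rep(c("A", "B", "C"), each = 10))$mean, 1 / 3)
  n110 <- rep(c("BAD", "UC", "CONTROL"), c(23, 42, 45))
  null <- chance_null(n110)
  expect_equal(null$mean, (23^2 + 42^2 + 45^2) / 110^2) # ~0.3569
  expect_equal(null$sd, sqrt(null$mean * (1 - null$mean) / 110))
  single <- chance_null(rep("A", 5))
  expect_equal(single$mean, 1)
  expect_equal(single$sd, 0)
  expect_error(chance_null(character(0)), "empty")
  set.seed(12)
  perm <- chance_null(n110, method = "permutation", n_perm = 400L)
  expect_lt(abs(perm$mean - perm$analytic_mean), 2 * perm$se)
})

test_that("binary collapse scores BAM vs non-BAM correctly", {
  expect_equal(collapse_binary(c("BAD", "UC"), c("BAD", "UC")), 1)
  # UC predicted CONTROL counts as correct after the collapse
  expect_equal(collapse_binary("CONTROL", "UC"), 1)
  expect_equal(collapse_binary("BAD", "UC"), 0)
  # recount oracle on random confusion patterns; collapse never hurts
  set.seed(13)
  for (i in 1:10) {
    truth <- sample(c("BAD", "UC", "CONTROL"), 30, replace = TRUE)
    pred <- sample(c("BAD", "UC", "CONTROL"), 30, replace = TRUE)
    manual <- mean(ifelse(truth == "BAD", "BAM", "nonBAM") ==
                     ifelse(pred == "BAD", "BAM", "nonBAM"))
    expect_equal(collapse_binary(truth, pred), manual)
    expect_gte(collapse_binary(truth, pred), mean(truth == pred))
  }
})

test_that("label permutation keeps LOOCV near chance", {
  set.seed(14)
  ok <- 0L
  for (s in 1:20) {
    x <- matrix(rnorm(30 * 4), ncol = 4)
    labels <- sample(rep(c("A", "B", "C"), each = 10))
    acc <- loocv(x, labels)$overall_accuracy
    null <- chance_null(labels)
    if (abs(acc - null$mean) <= 3 * null$sd) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})
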