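test_that("concatenation follows the documented index map", {
  cfg <- tiny_config(noise_sd = 0)
  scan <- generate_faims_scan("BAD", cfg, 3L)
  v <- concatenate_polarities(scan)
  expect_length(v, 52224L)

  # sentinel placement: positive[df = 3, cv = 8] -> 1-based index 2*512 + 8
  scan$positive[3, 8] <- 1234.5
  expect_equal(concatenate_polarities(scan)[2L * 512L + 8L], 1234.5)

  # brute-force index-map oracle over every (polarity, df, cv) triple
  expected <- integer(0)
  idx <- 1L
  ok <- TRUE
  map <- faims_index_map(seq_len(52224L))
  for (pol in c("positive", "negative")) {
    for (df in 1:51) {
      for (cv in 1:512) {
        ok <- ok && map$polarity[idx] == pol && map$df_line[idx] == df &&
          map$cv_step[idx] == cv
        idx <- idx + 1L
      }
    }
  }
  expect_true(ok) # bijection between triples and 1..52224

  zero <- faims_scan(matrix(0, 51, 512), matrix(0, 51, 512), "z")
  expect_true(all(concatenate_polarities(zero) == 0))
})

test_that("the D4 transform matches an explicit orthogonal matrix at one level", {
  n <- 64L
  T <- d4_level_matrix(n)
  expect_lt(max(abs(T %*% t(T) - diag(n))), 1e-12) # orthonormal operator
  set.seed(1)
  x <- rnorm(n)
  w1 <- wavelet_transform(x, levels = 1L)$coefficients
  expect_equal(w1, as.vector(T %*% x), tolerance = 1e-12)
})

test_that("the multilevel D4 transform conserves energy and inverts", {
  set.seed(2)
  for (n in c(64L, 96L, 256L)) {
    x <- rnorm(n)
    w <- wavelet_transform(x, levels = 3L)
    expect_lt(abs(sum(w$coefficients^2) - sum(x^2)), 1e-9) # Parseval
    expect_lt(max(abs(inverse_wavelet(w) - x)), 1e-9)
  }
  # D4 has two vanishing moments: constants produce zero details
  w <- wavelet_transform(rep(3.7, 64), levels = 3L)
  expect_lt(max(abs(w$coefficients[-seq_len(8)])), 1e-10)
  # full-size round trip on a generated scan
  v <- concatenate_polarities(generate_faims_scan("UC", tiny_config(), 5L))
  w <- wavelet_transform(v) # default depth 9
  expect_length(w$coefficients, 52224L)
  expect_lt(max(abs(inverse_wavelet(w) - v)), 1e-8)
  # odd length at some level is refused with advice
  expect_error(wavelet_transform(rnorm(96), levels = 6L), "depth")
})

test_that("scatter statistics match the hand-computed example exactly", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  st <- compute_scatter_stats(x, c("A", "A", "B", "B", "C", "C"))
  expect_equal(st$within, 4.5)      # (3 * sqrt(0.5))^2
  expect_equal(st$between, 8 / 9)   # sd of means = 2 -> 4 / 4.5
})

test_that("degenerate scatter conventions hold", {
  x <- cbind(const = rep(1, 6), sep = rep(c(0, 1, 2), each = 2))
  st <- compute_scatter_stats(x, rep(c("A", "B", "C"), each = 2))
  expect_equal(st$within[["const"]], 0)
  expect_equal(st$between[["const"]], 0)   # constant everywhere: never selected
  expect_equal(st$within[["sep"]], 0)
  expect_equal(st$between[["sep"]], Inf)   # perfectly separating: always passes
  expect_error(compute_scatter_stats(x, c("A", rep("B", 5))), ">= 2 samples")
})

test_that("scatter statistics transform as expected under shift and scale", {
  set.seed(3)
  labels <- rep(c("A", "B", "C"), each = 5)
  for (i in 1:5) {
    x <- matrix(rnorm(15 * 3), ncol = 3)
    st <- compute_scatter_stats(x, labels)
    shifted <- compute_scatter_stats(x + 100, labels)
    expect_equal(shifted$within, st$within)
    expect_equal(shifted$between, st$between)
    scaled <- compute_scatter_stats(x * 2.5, labels)
    expect_equal(scaled$within, st$within * 2.5^2)
    expect_equal(scaled$between, st$between) # scale-invariant ratio
  }
})

test_that("select_variables applies strict thresholds in both directions", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  st <- compute_scatter_stats(x, c("A", "A", "B", "B", "C", "C"))
  expect_equal(select_variables(st, Inf, -Inf), 1L)   # everything passes
  expect_length(select_variables(st, 0, -Inf), 0L)    # strict inequality
  expect_equal(select_variables(st, 5, 0.5), 1L)      # 4.5 < 5 and 8/9 > 0.5
  expect_length(select_variables(st, 5, 0.9), 0L)
  # inverted between direction selects the complement behaviour
  expect_equal(select_variables(st, 5, 0.9, between_dir = "<"), 1L)
})

test_that("a 1x1 grid reproduces a direct single-threshold LOOCV run", {
  cfg <- tiny_config(n = 5L, effect_size = 2, noise_sd = 0.4, seed = 9L)
  co <- generate_cohort(cfg)
  feats <- faims_feature_matrix(co$faims_scans)
  st <- compute_scatter_stats(feats, co$manifest$group)
  wt <- unname(quantile(st$within, 0.9))
  bt <- unname(quantile(st$between[is.finite(st$between)], 1 - 30 / length(st$between)))
  res <- explore_threshold_grid(feats, co$manifest$group, cap = 500L,
                                within_thresholds = wt, between_thresholds = bt)
  direct <- loocv(feats, co$manifest$group,
                  select = list(within_threshold = wt, between_threshold = bt))
  expect_equal(dim(res$accuracy), c(1L, 1L))
  expect_equal(res$accuracy[1, 1], direct$overall_accuracy)
})

test_that("separable synthetic classes reach a perfect robust cell", {
  cfg <- tiny_config(n = 5L, effect_size = 4, noise_sd = 0.05, seed = 21L)
  co <- generate_cohort(cfg)
  feats <- faims_feature_matrix(co$faims_scans)
  res <- explore_threshold_grid(feats, co$manifest$group,
                                n_within = 5L, n_between = 5L)
  expect_equal(max(res$accuracy, na.rm = TRUE), 1)
  region <- find_robust_region(res)
  expect_true(region$robust)
  expect_equal(region$accuracy, 1)

  # the chosen variables draw energy from the planted group-differential
  # plumes: compare against the wavelet transforms of the noiseless
  # pairwise group differences (generator truth)
  cfg0 <- tiny_config(effect_size = 4, noise_sd = 0, bio_sd = 0)
  pair_diff <- function(g1, g2) {
    abs(wavelet_transform(
      concatenate_polarities(generate_faims_scan(g1, cfg0, 1L)) -
        concatenate_polarities(generate_faims_scan(g2, cfg0, 1L)))$coefficients)
  }
  wdiff <- pmax(pair_diff("BAD", "CONTROL"), pair_diff("BAD", "UC"),
                pair_diff("UC", "CONTROL"))
  signal_support <- which(wdiff > 0.01 * max(wdiff)) # ~2% of coefficients
  expect_gt(length(intersect(region$variables, signal_support)), 0L)
})

test_that("undefined cells are marked with a reason, not scored", {
  co <- generate_cohort(tiny_config(n = 5L, seed = 4L))
  feats <- faims_feature_matrix(co$faims_scans)
  # absurd thresholds: nothing selected / everything selected
  res <- explore_threshold_grid(feats, co$manifest$group,
                                within_thresholds = c(0, Inf),
                                between_thresholds = c(-1),
                                cap = 10L)
  expect_true(all(is.na(res$accuracy)))
  expect_match(res$undefined_reason[1, 1], "no variables")
  expect_match(res$undefined_reason[2, 1], "cap")
})

test_that("find_robust_region reports absence explicitly", {
  fake <- structure(list(
    within_thresholds = c(1, 2), between_thresholds = c(1, 2),
    accuracy = matrix(0.33, 2, 2), n_selected = matrix(5L, 2, 2),
    robust_mask = matrix(FALSE, 2, 2),
    undefined_reason = matrix(NA_character_, 2, 2),
    null = chance_null(rep(c("A", "B", "C"), each = 10)),
    stats = NULL, config = list(within_dir = "<", between_dir = ">")),
    class = "threshold_grid_result")
  region <- find_robust_region(fake)
  expect_false(region$robust)
  expect_match(region$message, "no robust region")
})
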