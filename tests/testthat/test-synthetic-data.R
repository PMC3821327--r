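test_that("default cohort has 110 samples split 23/42/45", {
  cfg <- cohort_config(seed = 1L)
  ids <- with(generate_cohort(cfg), manifest)
  expect_equal(nrow(ids), 110L)
  expect_equal(as.vector(table(ids$group)), c(23L, 42L, 45L))
  expect_false(anyDuplicated(ids$sample_id) > 0L)
})

test_that("cohort structure honors the config", {
  cfg <- tiny_config(n = 3L, seed = 2L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$manifest), 9L)
  for (id in co$manifest$sample_id) {
    expect_s3_class(co$faims_scans[[id]], "faims_scan")
    expect_length(co$enose_records[[id]], cfg$n_enose_replicates)
    expect_s3_class(co$gcms_tables[[id]], "gcms_peak_table")
  }
  expect_equal(length(co$faims_scans[[1]]$positive),
               26112L) # 51 DF lines x 512 CV steps per polarity
  expect_equal(dim(co$enose_records[[1]][[1]]$resistances), c(18L, 180L))
})

test_that("the generator is deterministic in (config, sample_id, replicate)", {
  cfg <- tiny_config(n = 2L, seed = 33L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$faims_scans, b$faims_scans)
  expect_identical(a$enose_records, b$enose_records)
  expect_identical(a$gcms_tables, b$gcms_tables)
  # record-level reproducibility, independent of generation order
  s <- generate_faims_scan("UC", cfg, derive_seed(cfg$seed, "UC_001", 0L),
                           sample_id = "UC_001")
  expect_identical(s$positive, a$faims_scans[["UC_001"]]$positive)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = c(BAD = -1, UC = 2, CONTROL = 2)),
               "count")
  expect_error(cohort_config(noise_sd = -0.1), "noise_sd")
  expect_error(cohort_config(effect_size = -2), "effect_size")
  expect_error(cohort_config(n_enose_replicates = 0), "replicates")
})

test_that("effect_size 0 with zero noise removes all group differences", {
  cfg <- tiny_config(effect_size = 0, noise_sd = 0, bio_sd = 0)
  scans <- lapply(c("BAD", "UC", "CONTROL"), generate_faims_scan,
                  config = cfg, sample_seed = 7L)
  expect_equal(scans[[1]]$positive, scans[[2]]$positive)
  expect_equal(scans[[2]]$negative, scans[[3]]$negative)
})

test_that("effect_size separates the group-mean FAIMS matrices", {
  mean_gap <- function(effect) {
    cfg <- tiny_config(effect_size = effect, noise_sd = 0.2, seed = 5L)
    gm <- function(group) {
      acc <- 0
      for (i in 1:10) {
        s <- generate_faims_scan(group, cfg,
                                 100L * i + match(group, c("BAD", "UC", "CONTROL")))
        acc <- acc + cbind(s$positive, s$negative)
      }
      acc / 10
    }
    mean(abs(gm("BAD") - gm("CONTROL")))
  }
  expect_gt(mean_gap(1), mean_gap(0))
})

test_that("e-nose replicates are identical at zero noise and recover truth", {
  cfg0 <- tiny_config(noise_sd = 0)
  r1 <- generate_enose_record("BAD", cfg0, 9L, 1L)
  r2 <- generate_enose_record("BAD", cfg0, 9L, 2L)
  expect_equal(r1$resistances, r2$resistances)

  # averaging max-dR over 50 replicates at noise 0.1 recovers the stored
  # per-sample amplitudes; the max statistic is biased upward by at most
  # about sd * sqrt(2 log T) for T trace samples of additive noise
  cfg <- cohort_config(noise_sd = 0.1, n_enose_replicates = 50L, seed = 3L)
  recs <- lapply(1:50, function(r) generate_enose_record("UC", cfg, 11L, r))
  feats <- rowMeans(vapply(recs, max_delta_r, numeric(18)))
  truth <- attr(recs[[1]], "true_amplitude")
  expect_lt(max(abs(feats - truth)), 0.1 * sqrt(2 * log(180)))
  expect_gt(cor(feats, truth), 0.99)
})

test_that("GC-MS tables carry the BAD markers and only those", {
  cfg <- tiny_config()
  bad <- generate_gcms_table("BAD", cfg, 21L)
  ctl <- generate_gcms_table("CONTROL", cfg, 22L)
  rts_bad <- vapply(bad$entries, `[[`, 0, "retention_time")
  expect_true(any(abs(rts_bad - 2.051) <= 0.05))
  # the 2.05-min entry carries the acetamide reference spectrum verbatim
  amide <- bad$entries[[which(abs(rts_bad - 2.051) <= 0.05)]]
  ref <- Filter(function(r) r$name == "Acetamide", reference_spectra())[[1]]
  expect_equal(amide$spectrum, ref$spectrum)
  rts_ctl <- vapply(ctl$entries, `[[`, 0, "retention_time")
  expect_false(any(abs(rts_ctl - 2.051) <= 0.05))

  # zero jitter puts the markers exactly at the configured centers
  cfg0 <- tiny_config(gcms_rt_jitter = 0)
  bad0 <- generate_gcms_table("BAD", cfg0, 21L)
  rts0 <- vapply(bad0$entries, `[[`, 0, "retention_time")
  expect_true(all(c(1.714, 2.051) %in% rts0))
})
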