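#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study design the package targets: 23 bile acid
#' diarrhoea (BAD), 42 ulcerative colitis (UC) and 45 control samples, each
#' with one FAIMS scan, three e-nose injections and one GC-MS peak table.
#'
#' @param n_per_group named integer vector of group sizes
#'   (`BAD`, `UC`, `CONTROL`).
#' @param effect_size non-negative scaling of all class-specific signal
#'   components; 0 removes every group difference.
#' @param noise_sd non-negative standard deviation of the i.i.d. Gaussian
#'   technical noise added to FAIMS intensities and e-nose traces (and of
#'   the per-replicate e-nose amplitude jitter).
#' @param bio_sd non-negative standard deviation of the per-sample
#'   (biological) multiplicative amplitude jitter; the study gives no
#'   biological/technical variance split, so both are free parameters.
#' @param n_enose_replicates technical e-nose replicates per sample.
#' @param gcms_rt_jitter half-width (minutes) of the uniform retention-time
#'   jitter applied to generated GC-MS peaks.
#' @param gcms_marker_rts retention-time centers (minutes) for the two
#'   BAD-only markers (2-propanol-like and acetamide-like peaks).
#' @param seed integer; together with each sample id it fully determines
#'   the generated data (see [derive_seed()]).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(BAD = 23L, UC = 42L, CONTROL = 45L),
                          effect_size = 1,
                          noise_sd = 0.5,
                          bio_sd = 0.1,
                          n_enose_replicates = 3L,
                          gcms_rt_jitter = 0.01,
                          gcms_marker_rts = c(isopropanol = 1.714,
                                              acetamide = 2.051),
                          seed = 1L) {
  n_per_group <- n_per_group[GROUP_LEVELS]
  names(n_per_group) <- GROUP_LEVELS
  if (anyNA(n_per_group) || any(n_per_group < 0)) {
    stop_format("n_per_group must give a count >= 0 for each of %s",
                paste(GROUP_LEVELS, collapse = ", "))
  }
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0) {
    stop_format("noise_sd must be a single value >= 0")
  }
  if (length(effect_size) != 1L || is.na(effect_size) || effect_size < 0) {
    stop_format("effect_size must be a single value >= 0")
  }
  if (bio_sd < 0) stop_format("bio_sd must be >= 0")
  if (n_enose_replicates < 1L) stop_format("n_enose_replicates must be >= 1")
  if (gcms_rt_jitter < 0) stop_format("gcms_rt_jitter must be >= 0")
  structure(
    list(n_per_group = stats::setNames(as.integer(round(n_per_group)),
                                       GROUP_LEVELS),
         effect_size = effect_size, noise_sd = noise_sd, bio_sd = bio_sd,
         n_enose_replicates = as.integer(n_enose_replicates),
         gcms_rt_jitter = gcms_rt_jitter,
         gcms_marker_rts = gcms_marker_rts,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a full synthetic cohort
#'
#' Draws, for every sample in the configured group sizes, one FAIMS scan,
#' `n_enose_replicates` e-nose records and one GC-MS peak table. Every
#' record's seed derives from `(config$seed, sample_id, replicate)`, so the
#' same configuration reproduces the cohort bit for bit, record by record.
#'
#' @param config a [cohort_config()].
#' @return a `voc_cohort` list: `manifest` (data frame of `sample_id`,
#'   `group`), `faims_scans`, `enose_records` (list of replicate lists),
#'   `gcms_tables`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- unlist(lapply(GROUP_LEVELS, function(g) {
    n <- config$n_per_group[[g]]
    if (n == 0L) character(0) else sprintf("%s_%03d", g, seq_len(n))
  }))
  groups <- as_group_label(rep(GROUP_LEVELS, config$n_per_group))
  manifest <- data.frame(sample_id = ids, group = groups,
                         stringsAsFactors = FALSE)
  faims <- lapply(seq_along(ids), function(i) {
    generate_faims_scan(groups[i], config,
                        derive_seed(config$seed, ids[i], 0L),
                        sample_id = ids[i])
  })
  enose <- lapply(seq_along(ids), function(i) {
    lapply(seq_len(config$n_enose_replicates), function(r) {
      generate_enose_record(groups[i], config,
                            derive_seed(config$seed, ids[i], 0L),
                            replicate = r, sample_id = ids[i])
    })
  })
  gcms <- lapply(seq_along(ids), function(i) {
    generate_gcms_table(groups[i], config,
                        derive_seed(config$seed, ids[i], 1000L))
  })
  structure(
    list(manifest = manifest,
         faims_scans = stats::setNames(faims, ids),
         enose_records = stats::setNames(enose, ids),
         gcms_tables = stats::setNames(gcms, ids),
         config = config),
    class = "voc_cohort"
  )
}

#' @export
print.voc_cohort <- function(x, ...) {
  cat(sprintf("<voc_cohort> %d samples (%s)\n", nrow(x$manifest),
              paste(sprintf("%s=%d", GROUP_LEVELS, x$config$n_per_group),
                    collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# FAIMS generator: 2-D Gaussian "plumes" on the (CV, DF) grid.

# shared chemical background, identical for every group
faims_baseline_plumes <- function() {
  list(
    positive = list(
      list(cv = 0.5, df = 20, w_cv = 1.2, w_df = 25, amp = 10),
      list(cv = -1.5, df = 45, w_cv = 0.8, w_df = 12, amp = 5),
      list(cv = 2.0, df = 60, w_cv = 0.9, w_df = 15, amp = 4)),
    negative = list(
      list(cv = 0.2, df = 25, w_cv = 1.0, w_df = 20, amp = 7),
      list(cv = -2.2, df = 50, w_cv = 0.8, w_df = 12, amp = 3))
  )
}

# designated group-differential plumes: sparse signal so that variable
# selection has something meaningful to find. `amp` and `shift_cv` are per
# group (BAD, UC, CONTROL); contributions scale with effect_size.
faims_group_plumes <- function() {
  list(
    list(polarity = "positive", cv = -2.5, df = 55, w_cv = 0.5, w_df = 8,
         amp = c(BAD = 2.0, UC = 0.8, CONTROL = 0),
         shift_cv = c(BAD = 0, UC = 0, CONTROL = 0)),
    list(polarity = "positive", cv = 1.5, df = 70, w_cv = 0.6, w_df = 10,
         amp = c(BAD = 0, UC = 1.5, CONTROL = 0.5),
         shift_cv = c(BAD = 0.15, UC = 0, CONTROL = -0.1)),
    list(polarity = "negative", cv = -1.0, df = 60, w_cv = 0.5, w_df = 8,
         amp = c(BAD = 1.5, UC = 0, CONTROL = 0.8),
         shift_cv = c(BAD = 0, UC = 0, CONTROL = 0)),
    list(polarity = "negative", cv = 2.2, df = 35, w_cv = 0.7, w_df = 10,
         amp = c(BAD = 0.5, UC = 1.0, CONTROL = 1.5),
         shift_cv = c(BAD = 0, UC = 0, CONTROL = 0))
  )
}

plume_matrix <- function(cv0, df0, w_cv, w_df, df_axis, cv_axis) {
  # rows = DF lines, cols = CV steps
  exp(-(outer((df_axis - df0)^2 / (2 * w_df^2),
              (cv_axis - cv0)^2 / (2 * w_cv^2), `+`)))
}

#' Generate one synthetic FAIMS scan
#'
#' Intensities are a shared plume background plus group-specific plumes
#' scaled by `effect_size`, with per-sample multiplicative amplitude jitter
#' (`bio_sd`) and i.i.d. Gaussian pixel noise (`noise_sd`). RNG consumption
#' is identical for every group, so with `effect_size = 0` and equal
#' `sample_seed` all groups yield the same scan.
#'
#' @param group a group label (`"BAD"`, `"UC"` or `"CONTROL"`).
#' @param config a [cohort_config()].
#' @param sample_seed integer seed for this sample (see [derive_seed()]).
#' @param sample_id identifier stored in the scan.
#' @return a [faims_scan()].
#' @export
generate_faims_scan <- function(group, config, sample_seed,
                                sample_id = paste0(group, "_", sample_seed)) {
  group <- as.character(as_group_label(group))
  df_axis <- faims_df_axis(); cv_axis <- faims_cv_axis()
  base <- faims_baseline_plumes()
  gp <- faims_group_plumes()
  with_seed(sample_seed, {
    # one multiplier per plume, drawn group-independently
    jit_base <- 1 + config$bio_sd * stats::rnorm(length(base$positive) +
                                                   length(base$negative))
    jit_grp <- 1 + config$bio_sd * stats::rnorm(length(gp))
    mats <- list(positive = matrix(0, FAIMS_N_DF, FAIMS_N_CV),
                 negative = matrix(0, FAIMS_N_DF, FAIMS_N_CV))
    j <- 0L
    for (pol in c("positive", "negative")) {
      for (p in base[[pol]]) {
        j <- j + 1L
        mats[[pol]] <- mats[[pol]] + p$amp * jit_base[j] *
          plume_matrix(p$cv, p$df, p$w_cv, p$w_df, df_axis, cv_axis)
      }
    }
    for (k in seq_along(gp)) {
      p <- gp[[k]]
      a <- config$effect_size * p$amp[[group]] * jit_grp[k]
      if (a != 0) {
        mats[[p$polarity]] <- mats[[p$polarity]] + a *
          plume_matrix(p$cv + p$shift_cv[[group]], p$df, p$w_cv, p$w_df,
                       df_axis, cv_axis)
      }
    }
    noise <- stats::rnorm(2L * FAIMS_POINTS_PER_POLARITY, 0, config$noise_sd)
    mats$positive <- mats$positive +
      matrix(noise[seq_len(FAIMS_POINTS_PER_POLARITY)], FAIMS_N_DF, FAIMS_N_CV)
    mats$negative <- mats$negative +
      matrix(noise[FAIMS_POINTS_PER_POLARITY + seq_len(FAIMS_POINTS_PER_POLARITY)],
             FAIMS_N_DF, FAIMS_N_CV)
    faims_scan(mats$positive, mats$negative, sample_id)
  })
}

# ---------------------------------------------------------------------------
# e-nose generator: smooth rise-and-recovery response per sensor.

# fixed instrument properties: baseline resistance, response amplitude and
# time constants per sensor (arbitrary resistance units)
enose_sensor_params <- function() {
  s <- seq_len(ENOSE_N_SENSORS)
  list(baseline = 80 + 6 * s,
       amp = 5 + 15 * (1 + sin(s)) / 2,
       tau_rise = 5 + 15 * (s %% 5) / 4,
       tau_decay = 40 + 50 * (s %% 7) / 6)
}

# group-specific amplitude offsets on four designated sensors
enose_group_deltas <- function() {
  d <- matrix(0, 3, ENOSE_N_SENSORS,
              dimnames = list(GROUP_LEVELS, NULL))
  d["BAD", c(3, 7, 12, 16)] <- c(2.0, -1.5, 1.0, 0)
  d["UC", c(3, 7, 12, 16)] <- c(0, 1.5, -1.0, 1.0)
  d["CONTROL", c(3, 7, 12, 16)] <- c(-1.0, 0, 0, -1.5)
  d
}

#' Expected noiseless e-nose response amplitudes for a group
#'
#' The generator's ground truth: per-sensor peak resistance change before
#' biological jitter and replicate noise. Useful for parameter-recovery
#' tests.
#'
#' @inheritParams generate_faims_scan
#' @return numeric vector of length 18.
#' @export
enose_true_amplitude <- function(group, config) {
  group <- as.character(as_group_label(group))
  par <- enose_sensor_params()
  pmax(par$amp + config$effect_size * enose_group_deltas()[group, ], 0)
}

#' Generate one synthetic e-nose record
#'
#' Each sensor trace is its baseline resistance plus a smooth
#' rise-and-recovery response `(1 - exp(-t/tau_r)) * exp(-t/tau_d)`
#' (normalized to peak 1) with amplitude = instrument amplitude +
#' `effect_size` x group delta, per-sample biological jitter drawn from
#' `sample_seed`, per-replicate amplitude jitter and additive trace noise
#' drawn from the replicate seed with standard deviation `noise_sd`.
#'
#' @inheritParams generate_faims_scan
#' @param replicate replicate index, `1..config$n_enose_replicates`.
#' @return an [enose_record()]; attribute `"true_amplitude"` stores the
#'   noiseless per-sensor amplitude (after biological jitter).
#' @export
generate_enose_record <- function(group, config, sample_seed, replicate = 1L,
                                  sample_id = paste0(group, "_", sample_seed)) {
  group <- as.character(as_group_label(group))
  if (replicate > config$n_enose_replicates) {
    stop_format("replicate %d exceeds n_enose_replicates = %d",
                replicate, config$n_enose_replicates)
  }
  par <- enose_sensor_params()
  amp <- enose_true_amplitude(group, config)
  bio <- with_seed(sample_seed,
                   1 + config$bio_sd * stats::rnorm(ENOSE_N_SENSORS))
  amp_sample <- amp * bio
  t <- seq(0, ENOSE_N_SAMPLES - 1L)
  rep_seed <- derive_seed(sample_seed, "enose", replicate)
  with_seed(rep_seed, {
    amp_rep <- amp_sample + config$noise_sd * stats::rnorm(ENOSE_N_SENSORS)
    traces <- vapply(seq_len(ENOSE_N_SENSORS), function(s) {
      shape <- (1 - exp(-t / par$tau_rise[s])) * exp(-t / par$tau_decay[s])
      shape <- shape / max(shape)
      par$baseline[s] + amp_rep[s] * shape +
        config$noise_sd * stats::rnorm(ENOSE_N_SAMPLES)
    }, numeric(ENOSE_N_SAMPLES))
    rec <- enose_record(t(traces), par$baseline, sample_id, replicate)
    attr(rec, "true_amplitude") <- amp_sample
    rec
  })
}

# ---------------------------------------------------------------------------
# GC-MS generator: plants packaged reference spectra at (jittered)
# retention times; the 2-propanol-like and acetamide-like markers appear in
# BAD tables only.

#' Generate one synthetic GC-MS peak table
#'
#' All groups receive shared urinary-headspace peaks (acetone-like near
#' 1.69 min, a C5 hydrocarbon-like peak near 1.86 min; non-BAD tables also a
#' dimethyl-disulphide-like peak at 1.721 min). BAD tables additionally
#' contain the two marker peaks at `config$gcms_marker_rts` (defaults
#' 1.714 and 2.051 min) with the packaged isopropyl-alcohol and acetamide
#' reference spectra. Retention times are jittered uniformly by
#' `config$gcms_rt_jitter`.
#'
#' @inheritParams generate_faims_scan
#' @return a [gcms_peak_table()].
#' @export
generate_gcms_table <- function(group, config, sample_seed) {
  group <- as.character(as_group_label(group))
  refs <- reference_spectra()
  ref_by <- function(name, rt) {
    hit <- which(vapply(refs, function(r)
      r$name == name && abs(r$retention_time - rt) < 1e-6, logical(1)))
    refs[[hit[1]]]
  }
  entries <- list()
  add <- function(ref, rt = ref$retention_time) {
    entries[[length(entries) + 1L]] <<- list(
      retention_time = rt, spectrum = ref$spectrum,
      identification = ref$name)
    invisible(NULL)
  }
  if (group == "BAD") {
    add(ref_by("Acetone", 1.688))
    add(ref_by("Cyclopentane", 1.863))
    add(ref_by("Isopropyl alcohol", 1.714),
        rt = config$gcms_marker_rts[[1]])
    add(ref_by("Acetamide", 2.051), rt = config$gcms_marker_rts[[2]])
  } else {
    add(ref_by("Acetone", 1.694))
    add(ref_by("Dihydro-3-methyl-2,5-furandione", 1.868))
    add(ref_by("Dimethyl disulphide", 1.721))
  }
  with_seed(sample_seed, {
    jit <- stats::runif(length(entries), -config$gcms_rt_jitter,
                        config$gcms_rt_jitter)
    for (i in seq_along(entries)) {
      entries[[i]]$retention_time <- entries[[i]]$retention_time + jit[i]
    }
    gcms_peak_table(entries)
  })
}
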