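#' Derive a per-record random seed from a cohort seed and identifiers
#'
#' Deterministic integer hash used by the synthetic generators so that every
#' generated record is reproducible in isolation: the seed of a FAIMS scan,
#' e-nose replicate or GC-MS table depends only on the cohort seed, the
#' sample id and the replicate index, never on generation order.
#'
#' @param seed integer cohort seed.
#' @param sample_id character scalar.
#' @param replicate integer replicate index (0 for non-replicated records).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, sample_id, replicate = 0L) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(sample_id)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 31 + as.numeric(replicate) + 17) %% m
  as.integer(h)
}

#' Validate group labels
#'
#' @param labels character vector or factor of group labels.
#' @return a factor with levels `BAD`, `UC`, `CONTROL`.
#' @export
as_group_label <- function(labels) {
  x <- as.character(labels)
  bad <- setdiff(unique(x), GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected BAD, UC, CONTROL)", call. = FALSE)
  }
  factor(x, levels = GROUP_LEVELS)
}

# run code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# format doubles so that write -> read round-trips bit-exactly
fmt_num <- function(x) sprintf("%.17g", x)

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
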