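#' Packaged GC-MS reference spectra
#'
#' Seven urinary-headspace reference peaks (retention time, base-peak-999
#' mass spectrum, library identification) covering the shared acetone-like
#' and hydrocarbon-like peaks of all groups and the two candidate bile acid
#' diarrhoea markers: isopropyl alcohol (2-propanol) at 1.714 min and
#' acetamide at 2.051 min. `name` keeps the first-listed library
#' identification; `annotation` the full identification string.
#'
#' @param path optional path to a reference TSV; defaults to the packaged
#'   set.
#' @return a list of reference spectra, each with `name`, `source_group`,
#'   `retention_time`, `spectrum` (base peak 999) and `annotation`.
#' @export
reference_spectra <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gcms_reference_spectra.tsv",
                        package = "vocfinger", mustWork = TRUE)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    list(name = df$name[i],
         source_group = if ("source_group" %in% names(df))
           df$source_group[i] else NA_character_,
         retention_time = as.numeric(df$retention_time[i]),
         spectrum = normalize_spectrum(parse_spectrum(df$spectrum[i], path, i)),
         annotation = if ("annotation" %in% names(df)) df$annotation[i]
                      else df$name[i])
  })
}

#' Cosine similarity between two mass spectra
#'
#' Computed over the union of m/z values (an ion absent from one spectrum
#' counts as intensity 0). The score is symmetric, lies in `[0, 1]` for
#' non-negative intensities, and is invariant to uniform rescaling of either
#' spectrum -- so base-peak normalization does not affect it.
#'
#' @param a,b named numeric vectors (names = integer m/z, values =
#'   intensities >= 0).
#' @return similarity in `[0, 1]`.
#' @export
spectrum_similarity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop_format("empty spectrum")
  mz <- union(names(a), names(b))
  va <- stats::setNames(numeric(length(mz)), mz)
  vb <- va
  va[names(a)] <- a
  vb[names(b)] <- b
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop_format("spectrum with zero total intensity")
  min(1, max(0, sum(va * vb) / (na * nb)))
}

#' Flag candidate markers in a GC-MS peak table
#'
#' A table entry is a hit for a reference iff its retention time lies within
#' `rt_window` of the reference retention time and the spectral cosine
#' similarity is at least `min_similarity`. Defaults (0.05 min, 0.8) are
#' tight enough that the acetamide-like 2.05-min marker is flagged in bile
#' acid diarrhoea tables and never in control tables.
#'
#' @param table a [gcms_peak_table()].
#' @param references list of reference spectra, see [reference_spectra()].
#' @param rt_window retention-time window, minutes (> 0).
#' @param min_similarity minimum cosine similarity in `[0, 1]`.
#' @return a `marker_report`: data frame `hits` with columns
#'   `retention_time`, `reference`, `similarity`, `rt_delta`, sorted by
#'   retention time, plus the thresholds used.
#' @export
detect_markers <- function(table, references = reference_spectra(),
                           rt_window = 0.05, min_similarity = 0.8) {
  stopifnot(inherits(table, "gcms_peak_table"))
  if (rt_window <= 0) stop_format("rt_window must be > 0")
  if (min_similarity < 0 || min_similarity > 1) {
    stop_format("min_similarity must lie in [0, 1]")
  }
  hits <- list()
  for (e in table$entries) {
    for (r in references) {
      delta <- abs(e$retention_time - r$retention_time)
      if (delta <= rt_window) {
        sim <- spectrum_similarity(e$spectrum, r$spectrum)
        if (sim >= min_similarity) {
          hits[[length(hits) + 1L]] <- data.frame(
            retention_time = e$retention_time, reference = r$name,
            similarity = sim, rt_delta = e$retention_time - r$retention_time,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits) == 0L) {
    data.frame(retention_time = numeric(0), reference = character(0),
               similarity = numeric(0), rt_delta = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    h <- do.call(rbind, hits)
    h[order(h$retention_time, h$reference), , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, rt_window = rt_window,
                 min_similarity = min_similarity),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report> %d hit(s) (rt window %.3f min, min similarity %.2f)\n",
              nrow(x$hits), x$rt_window, x$min_similarity))
  if (nrow(x$hits) > 0L) print(x$hits)
  invisible(x)
}
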