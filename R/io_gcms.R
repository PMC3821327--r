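#' GC-MS peak table container
#'
#' A list of chromatographic peaks, each with a retention time (minutes) and
#' a fragmentation mass spectrum given as relative intensities over integer
#' m/z values. Spectra follow the base-peak convention: intensities are
#' scaled so the most intense ion reads 999.
#'
#' @param entries a list; each element has `retention_time` (minutes >= 0),
#'   `spectrum` (named numeric vector, names = integer m/z, values =
#'   relative intensities) and optional `identification` (string).
#' @return an object of class `gcms_peak_table`, entries sorted by
#'   retention time, spectra base-peak normalized to 999.
#' @export
gcms_peak_table <- function(entries = list()) {
  entries <- lapply(entries, function(e) {
    rt <- as.numeric(e$retention_time)
    if (!is.finite(rt) || rt < 0) stop_format("retention time must be >= 0")
    spec <- normalize_spectrum(e$spectrum)
    list(retention_time = rt, spectrum = spec,
         identification = if (is.null(e$identification)) NA_character_
                          else as.character(e$identification))
  })
  if (length(entries) > 1L) {
    entries <- entries[order(vapply(entries, `[[`, 0, "retention_time"))]
  }
  structure(list(entries = entries), class = "gcms_peak_table")
}

# base-peak normalization: scale so the maximum intensity reads 999
normalize_spectrum <- function(spectrum) {
  mz <- as.integer(names(spectrum))
  val <- as.numeric(spectrum)
  if (length(val) == 0L) stop_format("empty mass spectrum")
  if (anyNA(mz) || any(mz <= 0L)) stop_format("m/z values must be positive integers")
  if (any(!is.finite(val)) || any(val < 0)) {
    stop_format("spectrum intensities must be finite and >= 0")
  }
  if (max(val) <= 0) stop_format("spectrum has no positive intensity")
  val <- val * (999 / max(val))
  names(val) <- mz
  val[order(mz)]
}

#' @export
print.gcms_peak_table <- function(x, ...) {
  cat(sprintf("<gcms_peak_table> %d peaks\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %.3f min  base m/z %s  %s\n", e$retention_time,
                names(e$spectrum)[which.max(e$spectrum)],
                if (is.na(e$identification)) "" else e$identification))
  }
  invisible(x)
}

#' Read and write GC-MS peak tables
#'
#' TSV layout with columns `retention_time`, `spectrum`
#' (semicolon-separated `mz:intensity` pairs) and `identification`. On read,
#' spectra are re-normalized so the base peak reads 999 and entries are
#' sorted by retention time.
#'
#' @param path file path.
#' @param table a [gcms_peak_table()].
#' @return `read_gcms_table` returns a `gcms_peak_table`; the writer returns
#'   `path` invisibly.
#' @export
read_gcms_table <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) return(gcms_peak_table())
  need <- c("retention_time", "spectrum")
  if (!all(need %in% names(df))) {
    stop_format("%s: missing required columns %s", path, paste(need, collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    rt <- suppressWarnings(as.numeric(df$retention_time[i]))
    if (is.na(rt)) stop_format("%s: bad retention_time in row %d", path, i)
    list(retention_time = rt,
         spectrum = parse_spectrum(df$spectrum[i], path, i),
         identification = if ("identification" %in% names(df) &&
                              nzchar(df$identification[i]))
           df$identification[i] else NULL)
  })
  gcms_peak_table(entries)
}

parse_spectrum <- function(text, path, row) {
  pairs <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(trimws(pairs))]
  if (length(pairs) == 0L) stop_format("%s: empty spectrum in row %d", path, row)
  mz <- numeric(length(pairs)); val <- numeric(length(pairs))
  for (j in seq_along(pairs)) {
    kv <- strsplit(trimws(pairs[j]), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop_format("%s: bad 'mz:intensity' pair '%s' in row %d",
                                      path, pairs[j], row)
    mz[j] <- suppressWarnings(as.numeric(kv[1]))
    val[j] <- suppressWarnings(as.numeric(kv[2]))
  }
  if (anyNA(mz) || anyNA(val)) stop_format("%s: non-numeric spectrum in row %d", path, row)
  if (any(mz <= 0) || any(mz != round(mz))) {
    stop_format("%s: m/z must be positive integers in row %d", path, row)
  }
  if (any(val < 0)) stop_format("%s: negative intensity in row %d", path, row)
  stats::setNames(val, as.integer(mz))
}

#' @rdname read_gcms_table
#' @export
write_gcms_table <- function(table, path) {
  stopifnot(inherits(table, "gcms_peak_table"))
  rows <- vapply(table$entries, function(e) {
    spec <- paste(sprintf("%s:%s", names(e$spectrum), fmt_num(e$spectrum)),
                  collapse = ";")
    paste(fmt_num(e$retention_time), spec,
          if (is.na(e$identification)) "" else e$identification, sep = "\t")
  }, character(1))
  writeLines(c("retention_time\tspectrum\tidentification", rows), path)
  invisible(path)
}
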