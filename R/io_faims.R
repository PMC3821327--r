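#' FAIMS scan container
#'
#' One urine-sample measurement from the FAIMS instrument: two dispersion
#' matrices (positive- and negative-polarity scans), each 51 dispersion-field
#' (DF) lines by 512 compensation-voltage (CV) steps of ion current in
#' arbitrary units, plus the two axis vectors. The DF axis runs 0 to 90%
#' ascending; the CV axis runs +6 V to -6 V descending, matching the sweep
#' direction of the instrument.
#'
#' @param positive,negative numeric matrices, 51 x 512, rows = DF lines.
#' @param sample_id character scalar identifying the sample.
#' @param df_axis,cv_axis optional axis vectors; defaults are the instrument
#'   sweeps (51 equal DF settings 0-90%, 512 CV steps +6 to -6 V).
#' @return an object of class `faims_scan`.
#' @export
faims_scan <- function(positive, negative, sample_id,
                       df_axis = faims_df_axis(), cv_axis = faims_cv_axis()) {
  check_faims_matrix(positive, "positive")
  check_faims_matrix(negative, "negative")
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (length(df_axis) != FAIMS_N_DF || any(diff(df_axis) <= 0)) {
    stop_format("df_axis must have %d strictly increasing values", FAIMS_N_DF)
  }
  if (length(cv_axis) != FAIMS_N_CV || any(diff(cv_axis) >= 0)) {
    stop_format("cv_axis must have %d strictly decreasing values", FAIMS_N_CV)
  }
  structure(
    list(positive = positive, negative = negative,
         df_axis = as.numeric(df_axis), cv_axis = as.numeric(cv_axis),
         sample_id = sample_id),
    class = "faims_scan"
  )
}

#' @rdname faims_scan
#' @export
faims_df_axis <- function() seq(0, 90, length.out = FAIMS_N_DF)

#' @rdname faims_scan
#' @export
faims_cv_axis <- function() seq(6, -6, length.out = FAIMS_N_CV)

check_faims_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) ||
      nrow(m) != FAIMS_N_DF || ncol(m) != FAIMS_N_CV) {
    stop_format("%s matrix must be numeric %d x %d (DF lines x CV steps), got %s",
                what, FAIMS_N_DF, FAIMS_N_CV,
                if (is.matrix(m)) paste(dim(m), collapse = " x ") else class(m)[1])
  }
  if (any(!is.finite(m))) stop_format("%s matrix contains non-finite values", what)
  invisible(m)
}

#' @export
print.faims_scan <- function(x, ...) {
  cat(sprintf("<faims_scan> sample %s: 2 x %d x %d ion-current matrices\n",
              x$sample_id, FAIMS_N_DF, FAIMS_N_CV))
  invisible(x)
}

#' Read and write FAIMS scans
#'
#' Plain-text dialect: comment headers give the sample id and the two axis
#' vectors, then a `# POSITIVE` block of 51 CSV rows (512 columns each) and a
#' `# NEGATIVE` block of the same shape. Values are written with 17
#' significant digits so write-then-read round-trips bit-exactly.
#'
#' @param path file path.
#' @param scan a [faims_scan()].
#' @return `read_faims_scan` returns a `faims_scan`; `write_faims_scan`
#'   returns `path` invisibly.
#' @export
read_faims_scan <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(path)
  hdr <- function(key) {
    i <- grep(paste0("^# ", key, ":"), lines)
    if (length(i) != 1L) stop_format("%s: missing '# %s:' header", path, key)
    sub(paste0("^# ", key, ":\\s*"), "", lines[i])
  }
  sample_id <- hdr("sample_id")
  df_axis <- parse_csv_row(hdr("df_axis"), path, "df_axis header")
  cv_axis <- parse_csv_row(hdr("cv_axis"), path, "cv_axis header")
  blocks <- lapply(c("POSITIVE", "NEGATIVE"), function(tag) {
    start <- grep(paste0("^# ", tag, "$"), lines)
    if (length(start) != 1L) stop_format("%s: missing '# %s' block", path, tag)
    body <- if (start >= length(lines)) character(0) else
      lines[seq(start + 1L, length(lines))]
    body <- body[seq_len(min(which(c(grepl("^#", body), TRUE))) - 1L)]
    if (length(body) != FAIMS_N_DF) {
      stop_format("%s: %s block has %d rows, expected %d x %d",
                  path, tag, length(body), FAIMS_N_DF, FAIMS_N_CV)
    }
    rows <- lapply(seq_along(body), function(r) {
      v <- parse_csv_row(body[r], path, sprintf("%s row %d", tag, r))
      if (length(v) != FAIMS_N_CV) {
        stop_format("%s: %s row %d has %d columns, expected %d x %d",
                    path, tag, r, length(v), FAIMS_N_DF, FAIMS_N_CV)
      }
      v
    })
    do.call(rbind, rows)
  })
  faims_scan(blocks[[1]], blocks[[2]], sample_id,
             df_axis = df_axis, cv_axis = cv_axis)
}

#' @rdname read_faims_scan
#' @export
write_faims_scan <- function(scan, path) {
  stopifnot(inherits(scan, "faims_scan"))
  block <- function(m) apply(m, 1L, function(r) paste(fmt_num(r), collapse = ","))
  lines <- c(
    paste0("# sample_id: ", scan$sample_id),
    paste0("# df_axis: ", paste(fmt_num(scan$df_axis), collapse = ",")),
    paste0("# cv_axis: ", paste(fmt_num(scan$cv_axis), collapse = ",")),
    "# POSITIVE", block(scan$positive),
    "# NEGATIVE", block(scan$negative)
  )
  writeLines(lines, path)
  invisible(path)
}

parse_csv_row <- function(line, path, where) {
  parts <- strsplit(line, ",", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v)) {
    col <- which(is.na(v))[1]
    stop_format("%s: non-numeric value '%s' at %s, column %d",
                path, parts[col], where, col)
  }
  v
}
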