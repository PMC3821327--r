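#' Electronic-nose record container
#'
#' One headspace injection measured by the 18-sensor metal-oxide array:
#' resistance traces sampled at 1 Hz for 180 s from injection, plus the
#' pre-injection baseline resistance of each sensor. Each biological sample
#' is typically injected three times (technical replicates).
#'
#' @param resistances numeric matrix, 18 sensors x 180 time samples (ohms).
#' @param baseline numeric vector of 18 positive pre-injection resistances.
#' @param sample_id character scalar.
#' @param replicate integer replicate index (1-based).
#' @return an object of class `enose_record`.
#' @export
enose_record <- function(resistances, baseline, sample_id, replicate = 1L) {
  if (!is.matrix(resistances) || !is.numeric(resistances) ||
      nrow(resistances) != ENOSE_N_SENSORS ||
      ncol(resistances) != ENOSE_N_SAMPLES) {
    stop_format("resistances must be numeric %d x %d (sensors x samples), got %s",
                ENOSE_N_SENSORS, ENOSE_N_SAMPLES,
                if (is.matrix(resistances))
                  paste(dim(resistances), collapse = " x ")
                else class(resistances)[1])
  }
  if (any(!is.finite(resistances))) stop_format("non-finite resistance values")
  if (length(baseline) != ENOSE_N_SENSORS || any(!is.finite(baseline)) ||
      any(baseline <= 0)) {
    stop_format("baseline must be %d finite positive values", ENOSE_N_SENSORS)
  }
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  structure(
    list(resistances = resistances, baseline = as.numeric(baseline),
         sample_id = sample_id, replicate = as.integer(replicate)),
    class = "enose_record"
  )
}

#' @export
print.enose_record <- function(x, ...) {
  cat(sprintf("<enose_record> sample %s replicate %d: %d sensors x %d s\n",
              x$sample_id, x$replicate, ENOSE_N_SENSORS, ENOSE_N_SAMPLES))
  invisible(x)
}

#' Read and write e-nose records
#'
#' CSV dialect: comment headers for sample id and replicate, a `baseline`
#' row of 18 values, then one row of 180 values per sensor.
#'
#' @param path file path.
#' @param record an [enose_record()].
#' @return `read_enose_record` returns an `enose_record`; the writer returns
#'   `path` invisibly.
#' @export
read_enose_record <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(path)
  hdr <- function(key, default = NULL) {
    i <- grep(paste0("^# ", key, ":"), lines)
    if (length(i) != 1L) {
      if (!is.null(default)) return(default)
      stop_format("%s: missing '# %s:' header", path, key)
    }
    sub(paste0("^# ", key, ":\\s*"), "", lines[i])
  }
  sample_id <- hdr("sample_id")
  replicate <- as.integer(hdr("replicate", "1"))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != ENOSE_N_SENSORS + 1L) {
    stop_format("%s: found %d data rows, expected a baseline row plus %d sensor rows",
                path, length(body), ENOSE_N_SENSORS)
  }
  if (!grepl("^baseline,", body[1])) {
    stop_format("%s: first data row must be the 'baseline' row", path)
  }
  baseline <- parse_csv_row(sub("^baseline,", "", body[1]), path, "baseline row")
  rows <- lapply(seq_len(ENOSE_N_SENSORS), function(s) {
    v <- parse_csv_row(body[s + 1L], path, sprintf("sensor row %d", s))
    if (length(v) != ENOSE_N_SAMPLES) {
      stop_format("%s: sensor row %d has %d columns, expected %d",
                  path, s, length(v), ENOSE_N_SAMPLES)
    }
    v
  })
  enose_record(do.call(rbind, rows), baseline, sample_id, replicate)
}

#' @rdname read_enose_record
#' @export
write_enose_record <- function(record, path) {
  stopifnot(inherits(record, "enose_record"))
  lines <- c(
    paste0("# sample_id: ", record$sample_id),
    paste0("# replicate: ", record$replicate),
    paste0("baseline,", paste(fmt_num(record$baseline), collapse = ",")),
    apply(record$resistances, 1L,
          function(r) paste(fmt_num(r), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
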