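#' Write a synthetic cohort to disk and read its manifest back
#'
#' `write_cohort` lays a [generate_cohort()] result out as one directory:
#' `manifest.json` (a list of `{sample_id, group, faims_path, enose_paths,
#' gcms_path}` records), one FAIMS CSV per sample, one e-nose CSV per
#' replicate and one GC-MS TSV per sample. `read_manifest` parses the JSON
#' and resolves the relative paths; `read_cohort` additionally loads every
#' referenced file.
#'
#' @param cohort a `voc_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param path path to a `manifest.json`.
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_manifest` a data frame; `read_cohort` a list with `manifest`,
#'   `faims_scans`, `enose_records`, `gcms_tables`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "voc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    id <- cohort$manifest$sample_id[i]
    faims_rel <- sprintf("%s_faims.csv", id)
    write_faims_scan(cohort$faims_scans[[id]], file.path(dir, faims_rel))
    reps <- cohort$enose_records[[id]]
    enose_rel <- vapply(seq_along(reps), function(r) {
      rel <- sprintf("%s_enose_r%d.csv", id, r)
      write_enose_record(reps[[r]], file.path(dir, rel))
      rel
    }, character(1))
    gcms_rel <- sprintf("%s_gcms.tsv", id)
    write_gcms_table(cohort$gcms_tables[[id]], file.path(dir, gcms_rel))
    list(sample_id = id, group = as.character(cohort$manifest$group[i]),
         faims_path = faims_rel, enose_paths = as.list(enose_rel),
         gcms_path = gcms_rel)
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(records, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  records <- jsonlite::read_json(path)
  base <- dirname(path)
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop_format("%s: duplicate sample ids", path)
  data.frame(
    sample_id = ids,
    group = as_group_label(vapply(records, function(r) r$group, character(1))),
    faims_path = file.path(base, vapply(records, function(r) r$faims_path, character(1))),
    gcms_path = file.path(base, vapply(records, function(r) r$gcms_path, character(1))),
    enose_paths = I(lapply(records, function(r)
      file.path(base, unlist(r$enose_paths)))),
    stringsAsFactors = FALSE
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  manifest <- read_manifest(path)
  list(
    manifest = manifest,
    faims_scans = stats::setNames(
      lapply(manifest$faims_path, read_faims_scan), manifest$sample_id),
    enose_records = stats::setNames(
      lapply(manifest$enose_paths, function(p) lapply(p, read_enose_record)),
      manifest$sample_id),
    gcms_tables = stats::setNames(
      lapply(manifest$gcms_path, read_gcms_table), manifest$sample_id)
  )
}
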