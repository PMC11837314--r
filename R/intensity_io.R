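#' Probe-level intensity table IO
#'
#' Reads tab-delimited per-probe intensity exports of the kind produced
#' by Illumina GenomeStudio final reports (one row per sample x probe,
#' with Log R Ratio, B Allele Freq and genotype call columns) into a
#' canonical probe table, and writes per-sample call results back out as
#' TSV. Header names vary between export pipelines, so the mapping from
#' canonical field to column header is a configurable "dialect".
#'
#' @name mloy-io
#' @keywords internal
NULL

CANONICAL_FIELDS <- c("sample_id", "probe_id", "chrom", "position",
                      "lrr", "baf", "genotype")

#' GenomeStudio final-report column dialect
#'
#' The default mapping from canonical probe fields to the column headers
#' of a GenomeStudio final report. Override individual entries (or load a
#' YAML mapping with [read_dialect()]) for other export formats.
#'
#' @return Named character vector: canonical field -> expected header.
#' @export
default_dialect <- function() {
  c(sample_id = "Sample ID", probe_id = "SNP Name", chrom = "Chr",
    position = "Position", lrr = "Log R Ratio", baf = "B Allele Freq",
    genotype = "GType")
}

#' Load a header dialect from YAML
#'
#' The file holds `canonical_field: "Header Name"` pairs; unspecified
#' fields fall back to the GenomeStudio defaults.
#'
#' @param path YAML file path.
#' @return Named character vector as [default_dialect()].
#' @export
read_dialect <- function(path) {
  spec <- yaml::read_yaml(path)
  d <- default_dialect()
  unknown <- setdiff(names(spec), CANONICAL_FIELDS)
  if (length(unknown))
    stop("unknown dialect fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d[names(spec)] <- vapply(spec, as.character, character(1))
  d
}

#' Read a per-probe intensity table
#'
#' Parses a tab-delimited intensity table into a canonical probe table:
#' a `data.table` with columns `sample_id`, `probe_id`, `chrom`
#' (normalized names), `position`, `lrr`, `baf`, `genotype`, sorted by
#' (sample, chromosome, position). Unparseable LRR/BAF values become
#' missing (`NA`), never zero; BAF values outside `[0, 1]` are set
#' missing and counted; rows with an unparseable position are skipped and
#' counted; duplicate (sample, probe) rows are dropped beyond the first.
#' Counters are attached as the `"issues"` attribute and no sample is
#' ever silently removed.
#'
#' @param path Tab-delimited file with a header row.
#' @param dialect Named character vector mapping canonical fields to
#'   header names (default [default_dialect()]).
#' @return A `data.table` of class `probe_table`.
#' @export
read_intensity_table <- function(path, dialect = default_dialect()) {
  missing_fields <- setdiff(CANONICAL_FIELDS, names(dialect))
  if (length(missing_fields))
    stop("dialect lacks fields: ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c("", "NA", "NaN", "nan"))
  absent <- setdiff(unname(dialect[CANONICAL_FIELDS]), names(raw))
  if (length(absent))
    stop(sprintf("missing mandatory column(s) %s; file headers: %s",
                 paste(sQuote(absent), collapse = ", "),
                 paste(sQuote(names(raw)), collapse = ", ")), call. = FALSE)
  tbl <- raw[, unname(dialect[CANONICAL_FIELDS]), with = FALSE]
  data.table::setnames(tbl, CANONICAL_FIELDS)

  issues <- c(rows_skipped_bad_position = 0L, baf_out_of_range = 0L,
              duplicate_rows_dropped = 0L)
  pos <- suppressWarnings(as.numeric(tbl$position))
  bad <- is.na(pos) | pos < 1
  if (any(bad)) {
    issues["rows_skipped_bad_position"] <- sum(bad)
    warning(sum(bad), " row(s) with unparseable position skipped", call. = FALSE)
    tbl <- tbl[!bad]
    pos <- pos[!bad]
  }
  tbl[, `:=`(
    chrom = normalize_chrom(chrom),
    position = as.integer(pos),
    lrr = suppressWarnings(as.numeric(lrr)),
    baf = suppressWarnings(as.numeric(baf)),
    genotype = toupper(genotype)
  )]
  tbl[!genotype %in% c("AA", "AB", "BB") | is.na(genotype), genotype := "NC"]
  oob <- !is.na(tbl$baf) & (tbl$baf < 0 | tbl$baf > 1)
  if (any(oob)) {
    issues["baf_out_of_range"] <- sum(oob)
    warning(sum(oob), " BAF value(s) outside [0,1] set to missing", call. = FALSE)
    tbl[oob, baf := NA_real_]
  }
  dup <- duplicated(tbl, by = c("sample_id", "probe_id"))
  if (any(dup)) {
    issues["duplicate_rows_dropped"] <- sum(dup)
    tbl <- tbl[!dup]
  }
  chrom_f <- factor(tbl$chrom, levels = .chrom_levels(tbl$chrom))
  data.table::setorderv(tbl[, .chrom_order := as.integer(chrom_f)],
                        c("sample_id", ".chrom_order", "position"))
  tbl[, .chrom_order := NULL]
  data.table::setattr(tbl, "issues", issues)
  data.table::setattr(tbl, "class", c("probe_table", class(tbl)))
  tbl[]
}

#' Split a probe table into per-sample tables
#'
#' @param probes A probe table from [read_intensity_table()] or
#'   [simulate_cohort()].
#' @return Named list of `data.table`s, one per sample, order preserved.
#' @export
split_samples <- function(probes) {
  stopifnot(is.data.frame(probes), "sample_id" %in% names(probes))
  probes <- data.table::as.data.table(probes)
  split(probes, by = "sample_id", sorted = FALSE)
}

.CALL_NUMERIC <- c("mlrr_y", "cf_mlrry", "bdev", "cf_baf", "call_rate",
                   "baf_auto", "rel_cov_par1", "threshold_used")
.CALL_COLUMNS <- c("sample_id", "n_msy_probes", "mlrr_y", "cf_mlrry",
                   "n_par1_het", "bdev", "cf_baf", "call_rate", "baf_auto",
                   "rel_cov_par1", "qc_pass", "mloy_lrr", "threshold_used",
                   "flags")

#' Write and read per-sample call tables
#'
#' One TSV row per sample: probe counts, mLRR_Y and its cell fraction,
#' PAR1 heterozygote count, Bdev and its cell fraction, QC metrics and
#' flags, the mLOY decision and the threshold used. Numeric fields are
#' written with six decimals, so write -> read -> write is byte-stable.
#'
#' @param calls A call table from [call_cohort()] (or read back with
#'   [read_calls()]).
#' @param path Output TSV path.
#' @return `path` invisibly; `read_calls()` returns a `data.table`.
#' @export
write_calls <- function(calls, path) {
  calls <- data.table::as.data.table(calls)
  missing_cols <- setdiff(.CALL_COLUMNS, names(calls))
  if (length(missing_cols))
    stop("call table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data.table::copy(calls)[, .CALL_COLUMNS, with = FALSE]
  for (col in .CALL_NUMERIC) {
    v <- out[[col]]
    out[, (col) := ifelse(is.na(v), "NA", sprintf("%.6f", v))]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(.CALL_COLUMNS, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(.CALL_COLUMNS, function(cn)
      as.character(out[[cn]])), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tbl <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "NA")
  for (col in .CALL_NUMERIC) tbl[, (col) := as.numeric(get(col))]
  for (col in c("n_msy_probes", "n_par1_het")) tbl[, (col) := as.integer(get(col))]
  for (col in c("qc_pass", "mloy_lrr")) tbl[, (col) := as.logical(get(col))]
  tbl[]
}
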