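#' Per-sample mLOY calling and cell-fraction estimation
#'
#' For each sample the caller computes mLRR_Y (median LRR over
#' male-specific Y probes), makes the dichotomous mLOY decision
#' (mLRR_Y <= -0.15 by default), converts mLRR_Y to a cell fraction, and
#' independently estimates the cell fraction from the median absolute
#' BAF deviation at PAR1 heterozygotes. Sample-level QC (call rate, BAF
#' autocorrelation, relative PAR1 copy number) is computed alongside and
#' applied as flags rather than hard drops, so failures stay auditable.
#'
#' @name mloy-calling
#' @keywords internal
NULL

#' Calling configuration
#'
#' Collects the thresholds and minimum-coverage requirements of the
#' caller. Defaults: mLOY is called when mLRR_Y <= -0.15 (the LRR-route
#' detection floor, a cell fraction of about 20.6%); at least 30
#' male-specific Y probes and 30 PAR1 heterozygotes are required for the
#' respective estimates; QC flags fire at call rate < 0.97, autosomal BAF
#' autocorrelation > 0.03, or relative PAR1 copy number >= 2.5.
#'
#' @param mloy_threshold Negative mLRR_Y cutoff for the mLOY call.
#' @param min_msy_probes Minimum non-missing MSY LRR count.
#' @param min_par1_het Minimum PAR1 heterozygote count for Bdev.
#' @param scale LRR scale factor (see [cn_from_lrr()]).
#' @param call_rate_min,baf_auto_max,rel_cov_max QC flag cutoffs.
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(mloy_threshold = -0.15, min_msy_probes = 30L,
                           min_par1_het = 30L, scale = DEFAULT_SCALE_FACTOR,
                           call_rate_min = 0.97, baf_auto_max = 0.03,
                           rel_cov_max = 2.5) {
  if (!is.finite(mloy_threshold) || mloy_threshold >= 0)
    stop("`mloy_threshold` must be negative", call. = FALSE)
  if (min_msy_probes < 1L || min_par1_het < 1L)
    stop("minimum probe counts must be >= 1", call. = FALSE)
  .check_scale(scale)
  structure(list(mloy_threshold = mloy_threshold,
                 min_msy_probes = as.integer(min_msy_probes),
                 min_par1_het = as.integer(min_par1_het), scale = scale,
                 call_rate_min = call_rate_min, baf_auto_max = baf_auto_max,
                 rel_cov_max = rel_cov_max),
            class = "calling_config")
}

#' Load a calling configuration from YAML
#'
#' Keys mirror the arguments of [calling_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `calling_config`.
#' @export
read_calling_config <- function(path) {
  spec <- yaml::read_yaml(path)
  allowed <- names(formals(calling_config))
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(calling_config, spec)
}

.region_of <- function(sample, map) {
  classify_probe(sample$chrom, sample$position, map)
}

#' Median LRR over the male-specific Y region
#'
#' Returns the median of non-missing LRR values over probes classified
#' MSY, together with the number of probes contributing. With fewer than
#' `min_probes` usable probes the estimate is withheld and a reason is
#' reported (`"no_msy_coverage"` when there are none at all,
#' `"insufficient_msy_probes"` otherwise).
#'
#' @param sample One sample's probe table (columns chrom, position, lrr).
#' @param map A `region_map`.
#' @param min_probes Minimum usable MSY probe count (default 30).
#' @return List with `mlrr_y` (NA when withheld), `n_msy_probes`,
#'   `reason` (NA when the estimate is reported).
#' @export
compute_mlrry <- function(sample, map = default_region_map(), min_probes = 30L) {
  stopifnot(min_probes >= 1L)
  lrr <- sample$lrr[.region_of(sample, map) == "MSY"]
  lrr <- lrr[!is.na(lrr)]
  n <- length(lrr)
  if (n == 0L)
    return(list(mlrr_y = NA_real_, n_msy_probes = 0L, reason = "no_msy_coverage"))
  if (n < min_probes)
    return(list(mlrr_y = NA_real_, n_msy_probes = n,
                reason = "insufficient_msy_probes"))
  list(mlrr_y = stats::median(lrr), n_msy_probes = n, reason = NA_character_)
}

#' Dichotomous mLOY decision from mLRR_Y
#'
#' TRUE iff `mlrr_y <= threshold`, inclusive at the boundary. A missing
#' mLRR_Y yields NA (no-call), which is distinct from a negative call.
#'
#' @param mlrr_y Numeric vector of median MSY LRR values (may contain NA).
#' @param threshold Negative cutoff (default -0.15).
#' @return Logical vector.
#' @export
call_mloy_lrr <- function(mlrr_y, threshold = -0.15) {
  if (!is.finite(threshold) || threshold >= 0)
    stop("`threshold` must be negative", call. = FALSE)
  mlrr_y <= threshold
}

#' Phase-free BAF deviation over PAR1 heterozygotes
#'
#' The median of |BAF - 0.5| over PAR1 probes called heterozygous (AB)
#' with non-missing BAF. This is a phase-free summary of the allelic
#' imbalance that a phased analysis would model haplotype-by-haplotype;
#' it reads the split between the two heterozygote BAF bands directly.
#' Withheld (with reason `"insufficient_par1_het"`) below `min_het`
#' usable heterozygotes, since sparse PAR1 coverage makes the estimate
#' unreliable.
#'
#' @param sample One sample's probe table (columns chrom, position, baf,
#'   genotype).
#' @inheritParams compute_mlrry
#' @param min_het Minimum usable PAR1 heterozygote count (default 30).
#' @return List with `bdev` (NA when withheld), `n_par1_het`, `reason`.
#' @export
estimate_bdev <- function(sample, map = default_region_map(), min_het = 30L) {
  stopifnot(min_het >= 1L)
  sel <- .region_of(sample, map) == "PAR1" & sample$genotype == "AB" &
    !is.na(sample$baf)
  baf <- sample$baf[sel]
  n <- length(baf)
  if (n < min_het)
    return(list(bdev = NA_real_, n_par1_het = n,
                reason = "insufficient_par1_het"))
  list(bdev = stats::median(abs(baf - 0.5)), n_par1_het = n,
       reason = NA_character_)
}

#' Per-sample QC metrics
#'
#' * `call_rate`: fraction of probes with a non-missing genotype call.
#' * `baf_auto`: lag-1 autocorrelation of (BAF - 0.5) over autosomal
#'   probes in genomic order — white-noise BAF gives a value near 0,
#'   while uncorrected intensity artifacts induce serial correlation.
#'   NA with fewer than 2 usable autosomal probes.
#' * `rel_cov_par1`: relative copy number in PAR1,
#'   `2 * 2^(median PAR1 LRR / scale)`; a sanity check that PAR1 behaves
#'   as diploid territory.
#'
#' @inheritParams compute_mlrry
#' @param scale LRR scale factor.
#' @return List with `call_rate`, `baf_auto`, `rel_cov_par1`.
#' @export
compute_qc <- function(sample, map = default_region_map(),
                       scale = DEFAULT_SCALE_FACTOR) {
  region <- .region_of(sample, map)
  call_rate <- mean(sample$genotype != "NC")
  dev <- sample$baf[region == "AUTOSOME"]
  dev <- dev[!is.na(dev)] - 0.5
  baf_auto <- if (length(dev) >= 2L && stats::sd(dev) > 0) {
    m <- mean(dev)
    sum((dev[-length(dev)] - m) * (dev[-1] - m)) / sum((dev - m)^2)
  } else NA_real_
  par1_lrr <- sample$lrr[region == "PAR1"]
  par1_lrr <- par1_lrr[!is.na(par1_lrr)]
  rel_cov <- if (length(par1_lrr))
    cn_from_lrr(stats::median(par1_lrr), expected_cn = 2L, scale = scale)
  else NA_real_
  list(call_rate = call_rate, baf_auto = baf_auto, rel_cov_par1 = rel_cov)
}

#' Assemble the full per-sample call
#'
#' Runs [compute_mlrry()], [call_mloy_lrr()], [estimate_bdev()] and
#' [compute_qc()] and assembles one call record. The mLRR_Y-route cell
#' fraction is reported (clamped to `[0, 1]`) only when mLRR_Y <= 0; a
#' positive mLRR_Y indicates no loss in the LRR signal and the sample is
#' flagged `positive_mlrry` instead. The BAF-route cell fraction is
#' reported whenever Bdev is available. QC failures set flags
#' (`low_call_rate`, `high_baf_auto`, `high_rel_cov`) and `qc_pass`, but
#' never erase measurements.
#'
#' @param sample One sample's probe table.
#' @param map A `region_map`.
#' @param config A [calling_config()].
#' @param sample_id Sample identifier; defaults to the table's
#'   `sample_id` column.
#' @return One-row `data.table` (see [write_calls()] for the columns).
#' @export
call_sample <- function(sample, map = default_region_map(),
                        config = calling_config(), sample_id = NULL) {
  stopifnot(inherits(config, "calling_config"))
  if (is.null(sample_id)) {
    sample_id <- unique(sample$sample_id)
    if (length(sample_id) != 1L)
      stop("`sample` must hold exactly one sample; got ",
           length(sample_id), call. = FALSE)
  }
  m <- compute_mlrry(sample, map, config$min_msy_probes)
  b <- estimate_bdev(sample, map, config$min_par1_het)
  qc <- compute_qc(sample, map, config$scale)

  flags <- character()
  if (!is.na(m$reason)) flags <- c(flags, m$reason)
  if (!is.na(b$reason)) flags <- c(flags, b$reason)

  cf_mlrry <- NA_real_
  if (!is.na(m$mlrr_y)) {
    if (m$mlrr_y <= 0) {
      cf_mlrry <- cf_from_mlrry_clamped(m$mlrr_y, config$scale)
    } else {
      flags <- c(flags, "positive_mlrry")
    }
  }
  cf_baf <- if (!is.na(b$bdev)) cf_from_bdev(b$bdev) else NA_real_

  if (!is.na(qc$call_rate) && qc$call_rate < config$call_rate_min)
    flags <- c(flags, "low_call_rate")
  if (!is.na(qc$baf_auto) && qc$baf_auto > config$baf_auto_max)
    flags <- c(flags, "high_baf_auto")
  if (!is.na(qc$rel_cov_par1) && qc$rel_cov_par1 >= config$rel_cov_max)
    flags <- c(flags, "high_rel_cov")
  qc_pass <- !any(flags %in% c("low_call_rate", "high_baf_auto", "high_rel_cov"))

  data.table::data.table(
    sample_id = sample_id, n_msy_probes = m$n_msy_probes, mlrr_y = m$mlrr_y,
    cf_mlrry = cf_mlrry, n_par1_het = b$n_par1_het, bdev = b$bdev,
    cf_baf = cf_baf, call_rate = qc$call_rate, baf_auto = qc$baf_auto,
    rel_cov_par1 = qc$rel_cov_par1, qc_pass = qc_pass,
    mloy_lrr = call_mloy_lrr(m$mlrr_y, config$mloy_threshold),
    threshold_used = config$mloy_threshold,
    flags = if (length(flags)) paste(flags, collapse = ",") else NA_character_
  )
}

#' Call every sample in a probe table
#'
#' @param probes A probe table covering one or more samples.
#' @inheritParams call_sample
#' @return A `data.table` with one row per sample.
#' @export
call_cohort <- function(probes, map = default_region_map(),
                        config = calling_config()) {
  samples <- split_samples(probes)
  data.table::rbindlist(lapply(names(samples), function(id)
    call_sample(samples[[id]], map, config, sample_id = id)))
}
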