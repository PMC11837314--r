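#' Synthetic genotyping-array cohort generator
#'
#' Generates probe-level intensity tables with known ground truth,
#' emulating the signal regimes the mLOY method must handle: normal
#' males, males with graded mosaic Y loss, females (zero Y copies up to
#' an intensity floor), and the heterozygote-miscall failure mode at
#' high cell fraction where the split BAF bands drift outside the
#' genotype caller's AB window.
#'
#' Signal model, per sample with true cell fraction CF:
#' * MSY probe LRR ~ Normal(scale * log2(max(1 - CF, cn_floor)),
#'   sigma_lrr) — the generative inverse of the copy-number rescaling
#'   the caller applies.
#' * PAR1 probes are heterozygous with probability `het_fraction`; a true
#'   heterozygote's BAF is 0.5 +/- Bdev(CF) plus Normal(0, sigma_baf)
#'   noise (band sign equiprobable), a homozygote's BAF sits near 0 or 1
#'   plus noise; all BAF clipped to [0, 1]. The reported genotype is AB
#'   iff the observed BAF falls inside `het_call_band`, else AA/BB by
#'   proximity — so large Bdev pushes true heterozygotes into
#'   homozygous calls, exactly the high-CF failure mode.
#' * Autosomal probes: LRR ~ Normal(0, sigma_lrr), BAF bands at 0, 0.5,
#'   1 under Hardy-Weinberg genotype frequencies.
#' * Females carry no Y: their MSY LRR centres on the intensity floor
#'   (`cn_floor` copies), their Y probes are not genotyped, and their
#'   PAR1 (an ordinary diploid X-X region) shows no BAF deviation.
#'
#' @name mloy-simulate
#' @keywords internal
NULL

#' Simulation configuration
#'
#' @param cf Per-sample true cell fraction(s) in `[0, 1]`; recycled to
#'   `n_samples`.
#' @param sex Per-sample sex, "male" or "female"; recycled. Females are
#'   simulated at CF 1 with Y copy number `cn_floor`.
#' @param n_samples Cohort size; defaults to `length(cf)`.
#' @param n_msy_probes Probes in the male-specific Y region (default 397,
#'   the OncoArray's MSY coverage).
#' @param n_par1_probes Probes in PAR1 (default 434, the GSA's PAR1
#'   coverage).
#' @param n_autosomal_probes Autosomal probes (default 10000; only QC
#'   metrics read them — enough that the BAF-autocorrelation statistic's
#'   sampling noise, roughly `1/sqrt(n)`, sits well inside its 0.03
#'   cutoff, as on a real array).
#' @param sigma_lrr Per-probe LRR noise s.d. (default 0.15).
#' @param sigma_baf Per-probe BAF noise s.d. (default 0.03).
#' @param het_fraction Probability a PAR1/autosomal probe is truly
#'   heterozygous (default 0.3).
#' @param het_call_band BAF interval within which a probe is called AB
#'   (default `c(0.15, 0.85)`).
#' @param cn_floor Minimal observable Y copy number — residual background
#'   intensity at zero copies (default 0.005).
#' @param scale LRR scale factor (see [cn_from_lrr()]).
#' @param seed Integer RNG seed (mandatory: runs must be reproducible).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cf = 0, sex = "male", n_samples = length(cf),
                              n_msy_probes = 397L, n_par1_probes = 434L,
                              n_autosomal_probes = 10000L, sigma_lrr = 0.15,
                              sigma_baf = 0.03, het_fraction = 0.3,
                              het_call_band = c(0.15, 0.85), cn_floor = 0.005,
                              scale = DEFAULT_SCALE_FACTOR, seed) {
  if (missing(seed) || !is.finite(seed))
    stop("`seed` is mandatory: simulations must be reproducible", call. = FALSE)
  if (any(!is.finite(cf)) || any(cf < 0 | cf > 1))
    stop("`cf` values must lie in [0, 1]", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  if (sigma_lrr < 0 || sigma_baf < 0) stop("sigmas must be >= 0", call. = FALSE)
  if (het_fraction < 0 || het_fraction > 1)
    stop("`het_fraction` must lie in [0, 1]", call. = FALSE)
  if (length(het_call_band) != 2L || het_call_band[1] >= het_call_band[2] ||
      het_call_band[1] < 0 || het_call_band[2] > 1)
    stop("`het_call_band` must be an increasing interval within [0, 1]",
         call. = FALSE)
  if (cn_floor <= 0 || cn_floor > 1) stop("`cn_floor` must be in (0, 1]",
                                          call. = FALSE)
  .check_scale(scale)
  structure(list(
    cf = rep_len(as.numeric(cf), n_samples),
    sex = rep_len(sex, n_samples), n_samples = as.integer(n_samples),
    n_msy_probes = as.integer(n_msy_probes),
    n_par1_probes = as.integer(n_par1_probes),
    n_autosomal_probes = as.integer(n_autosomal_probes),
    sigma_lrr = sigma_lrr, sigma_baf = sigma_baf, het_fraction = het_fraction,
    het_call_band = as.numeric(het_call_band), cn_floor = cn_floor,
    scale = scale, seed = as.integer(seed)), class = "simulation_config")
}

#' Load a simulation configuration from YAML
#'
#' Keys mirror [simulation_config()] arguments; `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  spec <- yaml::read_yaml(path)
  allowed <- names(formals(simulation_config))
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(simulation_config, spec)
}

.sim_probe_layout <- function(config) {
  # fixed probe positions shared by all samples, like a real array manifest
  auto <- if (config$n_autosomal_probes > 0L) data.table::data.table(
    probe_id = sprintf("auto_%05d", seq_len(config$n_autosomal_probes)),
    chrom = "chr1",
    position = as.integer(round(seq(1e6, 2.4e8,
                                    length.out = config$n_autosomal_probes))),
    region = "AUTOSOME") else NULL
  par1 <- if (config$n_par1_probes > 0L) data.table::data.table(
    probe_id = sprintf("par1_%05d", seq_len(config$n_par1_probes)),
    chrom = "chrX",
    position = as.integer(round(seq(10001, 2781479,
                                    length.out = config$n_par1_probes))),
    region = "PAR1") else NULL
  msy <- if (config$n_msy_probes > 0L) data.table::data.table(
    probe_id = sprintf("msy_%05d", seq_len(config$n_msy_probes)),
    chrom = "chrY",
    position = as.integer(round(seq(3e6, 5.6e7,
                                    length.out = config$n_msy_probes))),
    region = "MSY") else NULL
  data.table::rbindlist(list(auto, par1, msy))
}

#' Simulate a cohort of probe-level intensity tables
#'
#' @param config A [simulation_config()].
#' @return List with elements `probes` (a probe table as produced by
#'   [read_intensity_table()]) and `truth` (a `data.table` with
#'   `sample_id`, `true_cf`, `sex`, `expected_mlrry`, `expected_bdev`;
#'   `expected_bdev` is NA for females, whose PAR1 is balanced diploid
#'   X-X territory).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- config$n_samples
  sample_id <- sprintf("S%05d", seq_len(ns))
  female <- config$sex == "female"
  cf_eff <- ifelse(female, 1, config$cf)
  y_cn <- pmax(1 - cf_eff, config$cn_floor)
  expected_mlrry <- config$scale * log2(y_cn)
  bdev_true <- ifelse(female, 0, bdev_from_cf(config$cf))

  layout <- .sim_probe_layout(config)
  np <- nrow(layout)
  probes <- layout[rep(seq_len(np), times = ns)]
  probes[, sample_id := rep(sample_id, each = np)]
  idx <- rep(seq_len(ns), each = np)  # sample index per row
  n <- nrow(probes)

  lrr <- numeric(n)
  baf <- rep(NA_real_, n)
  genotype <- character(n)
  band <- config$het_call_band
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  noise <- function(m) if (config$sigma_baf > 0)
    stats::rnorm(m, 0, config$sigma_baf) else numeric(m)

  is_msy <- probes$region == "MSY"
  is_par1 <- probes$region == "PAR1"
  is_auto <- probes$region == "AUTOSOME"

  # MSY: LRR around the scaled log copy number; no usable BAF (hemizygous);
  # males are called homozygous, females are not genotyped on chrY
  n_msy <- sum(is_msy)
  lrr[is_msy] <- stats::rnorm(n_msy, expected_mlrry[idx[is_msy]],
                              config$sigma_lrr)
  genotype[is_msy] <- ifelse(female[idx[is_msy]], "NC",
                             sample(c("AA", "BB"), n_msy, replace = TRUE))

  # diploid regions (PAR1 and autosomes): BAF bands split by the
  # sample's Bdev in PAR1 only
  for (region in c("PAR1", "AUTOSOME")) {
    sel <- if (region == "PAR1") is_par1 else is_auto
    m <- sum(sel)
    if (m == 0L) next
    ridx <- idx[sel]
    lrr[sel] <- stats::rnorm(m, 0, config$sigma_lrr)
    het <- stats::runif(m) < config$het_fraction
    dev <- if (region == "PAR1") bdev_true[ridx] else 0
    sgn <- sample(c(-1, 1), m, replace = TRUE)
    b <- numeric(m)
    b[het] <- 0.5 + (sgn * dev)[het]
    b[!het] <- sample(c(0, 1), sum(!het), replace = TRUE)
    b <- clip01(b + noise(m))
    g <- ifelse(b >= band[1] & b <= band[2], "AB",
                ifelse(b < 0.5, "AA", "BB"))
    baf[sel] <- b
    genotype[sel] <- g
  }

  probes[, `:=`(lrr = lrr, baf = baf, genotype = genotype)]
  # PAR1 LRR in a male mLOY sample drops with the lost Y copy (observed
  # CN = 2 - CF); female PAR1 is ordinary diploid X-X, centred at 0
  if (any(is_par1)) {
    cn_par1 <- ifelse(female, 2, 2 - config$cf)
    centre <- config$scale * log2(cn_par1 / 2)
    probes[is_par1, lrr := lrr + centre[idx[is_par1]]]
  }
  probes[, region := NULL]
  chrom_f <- factor(probes$chrom, levels = .chrom_levels(probes$chrom))
  data.table::setorderv(probes[, .chrom_order := as.integer(chrom_f)],
                        c("sample_id", ".chrom_order", "position"))
  probes[, .chrom_order := NULL]
  data.table::setcolorder(probes, CANONICAL_FIELDS)
  data.table::setattr(probes, "class", c("probe_table", class(probes)))

  truth <- data.table::data.table(
    sample_id = sample_id, true_cf = cf_eff, sex = config$sex,
    expected_mlrry = expected_mlrry,
    expected_bdev = ifelse(female, NA_real_, bdev_true))
  list(probes = probes[], truth = truth)
}

#' Analytic heterozygote miscall probability
#'
#' Probability that a truly heterozygous PAR1 probe's observed BAF falls
#' outside the AB calling band, given the sample's expected BAF
#' deviation and the per-probe BAF noise: a half/half mixture of
#' Gaussians centred at 0.5 +/- bdev, with tail mass beyond each band
#' edge. Verifies that the simulator reproduces the high-cell-fraction
#' failure mode, where almost all true heterozygotes are called
#' homozygous.
#'
#' @param bdev Expected BAF deviation(s) in `[0, 0.5]`.
#' @param sigma_baf Per-probe BAF noise s.d. (>= 0; 0 gives the
#'   deterministic step).
#' @param band AB calling band (default `c(0.15, 0.85)`).
#' @return Numeric vector of miscall probabilities in `[0, 1]`.
#' @export
miscall_rate <- function(bdev, sigma_baf, band = c(0.15, 0.85)) {
  if (any(bdev < 0 | bdev > 0.5)) stop("`bdev` must lie in [0, 0.5]",
                                       call. = FALSE)
  if (sigma_baf < 0) stop("`sigma_baf` must be >= 0", call. = FALSE)
  out_of_band <- function(mu) {
    if (sigma_baf == 0) as.numeric(mu < band[1] | mu > band[2])
    else stats::pnorm(band[1], mu, sigma_baf) +
      stats::pnorm(band[2], mu, sigma_baf, lower.tail = FALSE)
  }
  0.5 * out_of_band(0.5 + bdev) + 0.5 * out_of_band(0.5 - bdev)
}

#' Write a probe table as a canonical intensity TSV
#'
#' Writes with the given dialect's headers, so the file reads back with
#' [read_intensity_table()] under the same dialect.
#'
#' @param probes A probe table.
#' @param path Output TSV path.
#' @param dialect Header dialect (default [default_dialect()]).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(probes, path, dialect = default_dialect()) {
  out <- data.table::as.data.table(probes)[, CANONICAL_FIELDS, with = FALSE]
  data.table::setnames(out, unname(dialect[CANONICAL_FIELDS]))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
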