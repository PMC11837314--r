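#' Copy-number, cell-fraction and BAF-deviation conversions
#'
#' Closed-form conversions among the Log2 R ratio (LRR), observed copy
#' number, mosaic-loss cell fraction (CF) and B-allele-frequency deviation
#' (Bdev). The LRR route rescales the log ratio by an empirical scale
#' factor because a one-copy deletion from the diploid state registers a
#' mean LRR of about -0.45 on Illumina arrays, not the theoretical -1:
#'
#'   CN_observed = CN_expected * 2^(LRR / scale)
#'
#' For the male-specific Y region (expected one copy in a normal male
#' cell), the fraction of cells that have lost the Y is
#'
#'   CF = 1 - 2^(mLRR_Y / scale)
#'
#' where `mLRR_Y` is the median LRR over male-specific Y probes. In the
#' diploid PAR1 region, allelic imbalance at heterozygous sites relates
#' the BAF deviation from 0.5 to the same cell fraction via
#'
#'   CF = 4 * Bdev / (1 + 2 * Bdev)
#'
#' @name mloy-formulas
#' @keywords internal
NULL

DEFAULT_SCALE_FACTOR <- 0.45

.check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive finite number", call. = FALSE)
  scale
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L)
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  as.numeric(x)
}

#' Observed copy number from a Log2 R ratio
#'
#' Rescales an LRR value to an observed copy number,
#' `CN_observed = CN_expected * 2^(lrr / scale)`. Use `expected_cn = 1`
#' for the male-specific Y region of a normal male and `expected_cn = 2`
#' for autosomes or the pseudoautosomal PAR1 region.
#'
#' @param lrr Numeric vector of Log2 R ratios (finite).
#' @param expected_cn Expected integer copy number in the unaffected
#'   state; must be 1 or 2.
#' @param scale Positive scale factor; the empirical magnitude of the LRR
#'   shift for a one-copy loss from the diploid state (default 0.45).
#' @return Numeric vector of observed copy numbers.
#' @examples
#' cn_from_lrr(-0.15, expected_cn = 1)  # ~0.794
#' cn_from_lrr(0, expected_cn = 2)      # 2
#' @export
cn_from_lrr <- function(lrr, expected_cn = 1L, scale = DEFAULT_SCALE_FACTOR) {
  lrr <- .check_finite(lrr, "lrr")
  .check_scale(scale)
  if (length(expected_cn) != 1L || !expected_cn %in% c(1L, 2L))
    stop("`expected_cn` must be 1 or 2", call. = FALSE)
  as.numeric(expected_cn) * 2^(lrr / scale)
}

#' Cell fraction from the median LRR over the male-specific Y region
#'
#' `CF = 1 - 2^(mlrr_y / scale)`. The raw value is returned: it is
#' negative whenever `mlrr_y > 0`, which downstream calling uses to
#' exclude samples whose LRR signal indicates no loss. Use
#' [cf_from_mlrry_clamped()] for a value truncated to `[0, 1]`.
#'
#' @param mlrr_y Numeric vector, median LRR over male-specific Y probes.
#' @inheritParams cn_from_lrr
#' @return Numeric vector of cell fractions (possibly negative).
#' @examples
#' cf_from_mlrry(-0.45)  # 0.5
#' cf_from_mlrry(-3.3)   # ~0.994: what a female sample registers
#' @export
cf_from_mlrry <- function(mlrr_y, scale = DEFAULT_SCALE_FACTOR) {
  mlrr_y <- .check_finite(mlrr_y, "mlrr_y")
  .check_scale(scale)
  1 - 2^(mlrr_y / scale)
}

#' @rdname cf_from_mlrry
#' @export
cf_from_mlrry_clamped <- function(mlrr_y, scale = DEFAULT_SCALE_FACTOR) {
  pmin(pmax(cf_from_mlrry(mlrr_y, scale), 0), 1)
}

#' Median LRR implied by a cell fraction (inverse conversion)
#'
#' Algebraic inverse of [cf_from_mlrry()]: `scale * log2(1 - cf)`.
#' Defined for `cf` in `[0, 1)`; a complete loss (`cf = 1`) has no finite
#' LRR and is rejected.
#'
#' @param cf Numeric vector of cell fractions in `[0, 1)`.
#' @inheritParams cn_from_lrr
#' @return Numeric vector of mLRR_Y values (<= 0).
#' @export
mlrry_from_cf <- function(cf, scale = DEFAULT_SCALE_FACTOR) {
  cf <- .check_finite(cf, "cf")
  .check_scale(scale)
  if (any(cf < 0 | cf >= 1))
    stop("`cf` must lie in [0, 1): a complete loss has no finite mLRR_Y",
         call. = FALSE)
  scale * log2(1 - cf)
}

#' Cell fraction from the BAF deviation at PAR1 heterozygotes
#'
#' `CF = 4 * Bdev / (1 + 2 * Bdev)`, where Bdev is the deviation of
#' heterozygote B-allele frequencies from the balanced value 0.5 caused
#' by the mosaic loss. Maps 0 to 0 and the maximal deviation 0.5 to a
#' complete loss (CF 1).
#'
#' @param bdev Numeric vector of BAF deviations in `[0, 0.5]`.
#' @return Numeric vector of cell fractions in `[0, 1]`.
#' @examples
#' cf_from_bdev(0.234)  # ~0.638
#' @export
cf_from_bdev <- function(bdev) {
  bdev <- .check_finite(bdev, "bdev")
  if (any(bdev < 0 | bdev > 0.5))
    stop("`bdev` must lie in [0, 0.5]", call. = FALSE)
  4 * bdev / (1 + 2 * bdev)
}

#' BAF deviation implied by a cell fraction (inverse conversion)
#'
#' Inverse of [cf_from_bdev()]: `Bdev = cf / (4 - 2 * cf)`.
#'
#' @param cf Numeric vector of cell fractions in `[0, 1]`.
#' @return Numeric vector of BAF deviations in `[0, 0.5]`.
#' @examples
#' bdev_from_cf(0.652)  # ~0.242
#' @export
bdev_from_cf <- function(cf) {
  cf <- .check_finite(cf, "cf")
  if (any(cf < 0 | cf > 1))
    stop("`cf` must lie in [0, 1]", call. = FALSE)
  cf / (4 - 2 * cf)
}

#' Reference table mapping mLRR_Y to cell fraction
#'
#' Tabulates `CF = 1 - 2^(mLRR_Y / scale)` on a regular grid, for quick
#' lookup of the cell fraction implied by an observed median LRR. Rows
#' run from `mlrry_max` down to `mlrry_min`, so CF increases down the
#' table.
#'
#' @param mlrry_min Most negative grid value (default -4.5).
#' @param mlrry_max Least negative grid value; must be <= 0 (default 0).
#' @param step Positive grid spacing (default 0.01).
#' @inheritParams cn_from_lrr
#' @return A `data.frame` with columns `mLRR_Y` (decreasing) and `CF`
#'   (increasing).
#' @examples
#' tab <- reference_table()
#' tab[tab$mLRR_Y == -0.15, ]  # CF ~ 0.206, the LRR-route detection floor
#' @export
reference_table <- function(mlrry_min = -4.5, mlrry_max = 0, step = 0.01,
                            scale = DEFAULT_SCALE_FACTOR) {
  .check_finite(c(mlrry_min, mlrry_max, step), "grid specification")
  .check_scale(scale)
  if (!(mlrry_min < mlrry_max) || mlrry_max > 0)
    stop("need mlrry_min < mlrry_max <= 0", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  n <- floor((mlrry_max - mlrry_min) / step + 1e-9)
  if (n < 1L) stop("grid is empty: step exceeds the requested range", call. = FALSE)
  # build the grid by index to keep values exact at printable precision
  grid <- round(mlrry_max - step * (0:n), 12)
  data.frame(mLRR_Y = grid, CF = cf_from_mlrry(grid, scale))
}

#' Write a reference table as tab-separated text
#'
#' @param tab A table from [reference_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(tab, path) {
  stopifnot(is.data.frame(tab), all(c("mLRR_Y", "CF") %in% names(tab)))
  data.table::fwrite(tab[, c("mLRR_Y", "CF")], path, sep = "\t")
  invisible(path)
}
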