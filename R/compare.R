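#' Agreement between the LRR-route and BAF-route cell fractions
#'
#' Given a cohort of per-sample calls, pairs the two cell-fraction
#' estimates, measures their squared Pearson correlation, and summarises
#' agreement in equal-size bins of sorted mLRR_Y. Binning by the noisier
#' coordinate and correlating bin medians suppresses independent
#' per-sample noise, so the binned-median R^2 sits above the pairwise
#' R^2 on cohorts where both estimates scatter independently around the
#' same truth.
#'
#' @name mloy-compare
#' @keywords internal
NULL

#' Pair the two cell-fraction estimates
#'
#' Retains samples with both estimates present and mLRR_Y strictly
#' negative (a non-negative mLRR_Y means the LRR signal shows no loss,
#' so its cell fraction would be non-positive). Exclusions are counted
#' by reason — `no_lrr_call`, `positive_mlrry`, `no_baf_call` — in the
#' `"exclusions"` attribute; the first applicable reason is charged.
#'
#' @param calls A call table from [call_cohort()].
#' @return `data.table` with columns `sample_id`, `cf_mlrry`, `cf_baf`,
#'   `mlrr_y`; attribute `"exclusions"` is a named integer vector.
#' @export
pair_samples <- function(calls) {
  calls <- data.table::as.data.table(calls)
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(calls$mlrr_y)] <- "no_lrr_call"
  reason[is.na(reason) & calls$mlrr_y >= 0] <- "positive_mlrry"
  reason[is.na(reason) & (is.na(calls$cf_baf) | is.na(calls$bdev))] <- "no_baf_call"
  keep <- is.na(reason) & !is.na(calls$cf_mlrry)
  pairs <- calls[keep, .(sample_id, cf_mlrry, cf_baf, mlrr_y)]
  excl <- table(factor(reason[!keep],
                       levels = c("no_lrr_call", "positive_mlrry", "no_baf_call")))
  data.table::setattr(pairs, "exclusions",
                      stats::setNames(as.integer(excl), names(excl)))
  pairs[]
}

#' Squared Pearson correlation of paired cell fractions
#'
#' @param pairs A pair table from [pair_samples()], or a numeric vector
#'   (then `y` must be given).
#' @param y Optional second numeric vector.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(pairs, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.data.frame(pairs))
    x <- pairs$cf_mlrry
    y <- pairs$cf_baf
  } else {
    x <- pairs
  }
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: R^2 undefined", call. = FALSE)
  stats::cor(x, y)^2
}

#' Equal-size bin summaries of paired cell fractions
#'
#' Sorts pairs by mLRR_Y (ties broken by sample ID for determinism) and
#' splits them into `n_bins` bins whose sizes differ by at most one (the
#' remainder is distributed one-per-bin from the first bin). Each bin
#' reports the min, max, median and mean of both cell-fraction estimates.
#' The squared correlation of the per-bin medians is attached as
#' attribute `"r_squared_median"` (also via [binned_median_r_squared()]).
#'
#' @param pairs A pair table from [pair_samples()].
#' @param n_bins Number of bins (>= 2, <= number of pairs).
#' @return `data.table` with one row per bin: `bin_index`, `n`,
#'   `{min,max,median,mean}_cf_mlrry`, `{min,max,median,mean}_cf_baf`.
#' @export
bin_summaries <- function(pairs, n_bins = 100L) {
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  if (n_bins > n)
    stop(sprintf("`n_bins` (%d) exceeds the number of pairs (%d)", n_bins, n),
         call. = FALSE)
  pairs <- data.table::as.data.table(pairs)[order(mlrr_y, sample_id)]
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  pairs[, bin_index := rep(seq_len(n_bins), times = sizes)]
  bins <- pairs[, .(
    n = .N,
    min_cf_mlrry = min(cf_mlrry), max_cf_mlrry = max(cf_mlrry),
    median_cf_mlrry = stats::median(cf_mlrry), mean_cf_mlrry = mean(cf_mlrry),
    min_cf_baf = min(cf_baf), max_cf_baf = max(cf_baf),
    median_cf_baf = stats::median(cf_baf), mean_cf_baf = mean(cf_baf)
  ), by = bin_index]
  data.table::setattr(bins, "r_squared_median",
                      r_squared(bins$median_cf_mlrry, bins$median_cf_baf))
  bins[]
}

#' @rdname bin_summaries
#' @export
binned_median_r_squared <- function(pairs, n_bins = 100L) {
  attr(bin_summaries(pairs, n_bins), "r_squared_median")
}

#' Scatter plot of the two cell-fraction estimates
#'
#' Optional diagnostic plot (requires ggplot2): per-sample pairs in grey
#' and, when bins are supplied, bin medians overlaid in colour.
#'
#' @param pairs A pair table from [pair_samples()].
#' @param bins Optional bin table from [bin_summaries()].
#' @return A ggplot object.
#' @export
plot_cf_agreement <- function(pairs, bins = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_cf_agreement() requires the ggplot2 package", call. = FALSE)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = cf_mlrry, y = cf_baf)) +
    ggplot2::geom_point(alpha = 0.3, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(CF[mLRR_Y]), y = expression(CF[BAF])) +
    ggplot2::theme_minimal()
  if (!is.null(bins))
    p <- p + ggplot2::geom_point(
      data = bins,
      ggplot2::aes(x = median_cf_mlrry, y = median_cf_baf),
      colour = "firebrick", size = 2)
  p
}
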