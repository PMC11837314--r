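msy_sample <- function(lrr, sample_id = "S01") {
  make_probe_table(sample_id, "chrY", 3e6 + seq_along(lrr) * 1000,
                   lrr = lrr, genotype = "AA")
}

par1_het_sample <- function(baf, sample_id = "S01") {
  make_probe_table(sample_id, "chrX", 10001 + seq_along(baf) * 1000,
                   lrr = 0, baf = baf, genotype = "AB")
}

test_that("mLRR_Y is the median LRR over usable MSY probes", {
  expect_equal(compute_mlrry(msy_sample(c(-0.1, -0.2, -0.3)),
                             min_probes = 3)$mlrr_y, -0.2)
  # even count: midpoint of the two central order statistics
  expect_equal(compute_mlrry(msy_sample(c(-0.1, -0.3)),
                             min_probes = 2)$mlrr_y, -0.2)
  # missing LRR probes do not count toward the minimum
  r <- compute_mlrry(msy_sample(c(rep(-0.2, 29), NA)), min_probes = 30)
  expect_true(is.na(r$mlrr_y))
  expect_equal(r$n_msy_probes, 29L)
  expect_identical(r$reason, "insufficient_msy_probes")
  # no MSY coverage at all is a distinct reason
  r0 <- compute_mlrry(make_probe_table("S01", "chr1", 1:5 * 1000, lrr = 0))
  expect_identical(r0$reason, "no_msy_coverage")
  expect_equal(r0$n_msy_probes, 0L)
})

test_that("the mLOY decision threshold is inclusive at the boundary", {
  expect_true(call_mloy_lrr(-0.15))
  expect_false(call_mloy_lrr(-0.15 + 1e-12))
  expect_false(call_mloy_lrr(-0.1499))
  expect_false(call_mloy_lrr(0))
  expect_true(is.na(call_mloy_lrr(NA_real_)))  # no-call, not FALSE
  expect_error(call_mloy_lrr(-0.2, threshold = 0.1), "negative")
})

test_that("Bdev is the median absolute BAF deviation at PAR1 heterozygotes", {
  expect_equal(estimate_bdev(par1_het_sample(c(0.5, 0.5, 0.5)),
                             min_het = 3)$bdev, 0)
  expect_equal(estimate_bdev(par1_het_sample(c(0.266, 0.734, 0.27, 0.73)),
                             min_het = 4)$bdev, 0.232)
  r <- estimate_bdev(par1_het_sample(rep(0.3, 5)), min_het = 30)
  expect_true(is.na(r$bdev))
  expect_equal(r$n_par1_het, 5L)
  expect_identical(r$reason, "insufficient_par1_het")
  # homozygotes and missing BAF are excluded
  s <- par1_het_sample(c(0.3, 0.7, NA))
  s$genotype[2] <- "AA"
  expect_equal(estimate_bdev(s, min_het = 1)$n_par1_het, 1L)
})

test_that("QC metrics: call rate, autosomal BAF autocorrelation, PAR1 copy number", {
  s <- make_probe_table("S01", "chr1", 1:10 * 1000, lrr = 0, baf = 0.5,
                        genotype = c(rep("AA", 9), "NC"))
  qc <- compute_qc(s)
  expect_equal(qc$call_rate, 0.9)
  # diploid PAR1 at LRR 0 has relative copy number 2
  p <- par1_het_sample(rep(0.5, 5))
  expect_equal(compute_qc(p)$rel_cov_par1, 2)
  # white-noise autosomal BAF has near-zero lag-1 autocorrelation
  set.seed(11)
  reps <- replicate(40, {
    w <- make_probe_table("S01", "chr1", 1:2000 * 1000, lrr = 0,
                          baf = pmin(pmax(stats::rnorm(2000, 0.5, 0.03), 0), 1),
                          genotype = "AB")
    compute_qc(w)$baf_auto
  })
  expect_true(mean(abs(reps) < 0.05) > 0.95)
  # fewer than two usable autosomal probes -> no autocorrelation estimate
  expect_true(is.na(compute_qc(par1_het_sample(0.5))$baf_auto))
})

test_that("assembled calls report CF by both routes and flag rather than drop", {
  map <- default_region_map()
  cfg <- calling_config(min_msy_probes = 3, min_par1_het = 3)
  s <- rbind(msy_sample(c(-0.45, -0.45, -0.45)),
             par1_het_sample(c(0.35, 0.65, 0.35, 0.65)))
  call <- call_sample(s, map, cfg)
  expect_equal(call$mlrr_y, -0.45)
  expect_equal(call$cf_mlrry, 0.5)
  expect_equal(call$bdev, 0.15)
  expect_equal(call$cf_baf, cf_from_bdev(0.15))
  expect_true(call$mloy_lrr)
  expect_true(is.na(call$flags))
  # positive mLRR_Y: CF withheld and flagged, measurement kept
  pos <- call_sample(msy_sample(c(0.02, 0.02, 0.02)), map, cfg)
  expect_true(is.na(pos$cf_mlrry))
  expect_match(pos$flags, "positive_mlrry")
  expect_equal(pos$mlrr_y, 0.02)
  expect_false(pos$mloy_lrr)
  # boundary: mlrr_y exactly 0 reports CF 0 (only strictly positive is removed)
  zero <- call_sample(msy_sample(c(0, 0, 0)), map, cfg)
  expect_equal(zero$cf_mlrry, 0)
})

test_that("QC failures flag the sample but keep its measurements", {
  cfg <- calling_config(min_msy_probes = 3, min_par1_het = 3)
  s <- msy_sample(rep(-0.45, 3))
  s$genotype <- c("AA", "NC", "NC")  # call rate 1/3
  call <- call_sample(s, default_region_map(), cfg)
  expect_false(call$qc_pass)
  expect_match(call$flags, "low_call_rate")
  expect_equal(call$cf_mlrry, 0.5)  # measurement not erased
})

test_that("CF estimates are invariant to probe order and duplicated rows", {
  set.seed(21)
  cfg <- calling_config(min_msy_probes = 3, min_par1_het = 3)
  s <- rbind(msy_sample(stats::rnorm(40, -0.3, 0.1)),
             par1_het_sample(stats::runif(40, 0.2, 0.8)))
  s$probe_id <- sprintf("p%03d", seq_len(nrow(s)))
  shuffled <- s[sample(nrow(s)), ]
  duplicated_rows <- rbind(s, s[1:10, ])
  dedup <- duplicated_rows[!duplicated(duplicated_rows,
                                       by = c("sample_id", "probe_id"))]
  c1 <- call_sample(s, config = cfg)
  c2 <- call_sample(shuffled, config = cfg)
  c3 <- call_sample(dedup, config = cfg)
  expect_equal(c2$cf_mlrry, c1$cf_mlrry)
  expect_equal(c2$cf_baf, c1$cf_baf)
  expect_equal(c3$cf_mlrry, c1$cf_mlrry)
  expect_equal(c3$cf_baf, c1$cf_baf)
})

test_that("noiseless simulated samples recover their true CF exactly", {
  cfg <- simulation_config(cf = c(0, 0.3, 0.7), sigma_lrr = 0, sigma_baf = 0,
                           n_autosomal_probes = 50, seed = 5)
  sim <- simulate_cohort(cfg)
  calls <- call_cohort(sim$probes)
  expect_equal(calls$mlrr_y, sim$truth$expected_mlrry, tolerance = 1e-12)
  expect_equal(calls$cf_mlrry, sim$truth$true_cf, tolerance = 1e-9)
  expect_equal(calls$bdev, sim$truth$expected_bdev, tolerance = 1e-9)
  expect_identical(calls$mloy_lrr, c(FALSE, TRUE, TRUE))
})

test_that("a noiseless female registers near-complete Y loss", {
  cfg <- simulation_config(cf = 0, sex = "female", sigma_lrr = 0,
                           sigma_baf = 0, cn_floor = 0.005,
                           n_autosomal_probes = 50, seed = 6)
  call <- call_cohort(simulate_cohort(cfg)$probes)
  expect_gte(call$cf_mlrry, 0.99)
  expect_true(call$mloy_lrr)
})

test_that("calling configuration validates and loads from YAML", {
  expect_error(calling_config(mloy_threshold = 0.1), "negative")
  expect_error(calling_config(min_msy_probes = 0), ">= 1")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mloy_threshold: -0.2", "min_par1_het: 10"), path)
  cfg <- read_calling_config(path)
  expect_equal(cfg$mloy_threshold, -0.2)
  expect_equal(cfg$min_par1_het, 10L)
  expect_equal(cfg$scale, 0.45)  # untouched defaults survive
  writeLines("bogus_key: 1", path)
  expect_error(read_calling_config(path), "unknown config keys")
})
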