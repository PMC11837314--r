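test_that("configuration validates its domain before any sampling", {
  expect_error(simulation_config(cf = 0.5), "seed")
  expect_error(simulation_config(cf = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(simulation_config(cf = 0.5, sex = "unknown", seed = 1), "sex")
  expect_error(simulation_config(cf = 0.5, sigma_lrr = -1, seed = 1), "sigmas")
  expect_error(simulation_config(cf = 0.5, cn_floor = 0, seed = 1), "cn_floor")
  expect_error(simulation_config(cf = 0.5, het_call_band = c(0.9, 0.1),
                                 seed = 1), "band")
})

test_that("identical config and seed give byte-identical output tables", {
  cfg <- simulation_config(cf = c(0.2, 0.6), n_autosomal_probes = 100,
                           seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(s1$probes, p1)
  write_intensity_table(s2$probes, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth, s2$truth)
  # a different seed actually changes the draw
  s3 <- simulate_cohort(simulation_config(cf = c(0.2, 0.6),
                                          n_autosomal_probes = 100, seed = 100))
  expect_false(identical(s1$probes$lrr, s3$probes$lrr))
})

test_that("noiseless signal centres sit exactly on the model curves", {
  cfg0 <- simulation_config(cf = 0, sigma_lrr = 0, sigma_baf = 0,
                            n_autosomal_probes = 0, seed = 2)
  sim0 <- simulate_cohort(cfg0)
  msy <- sim0$probes[sim0$probes$chrom == "chrY"]
  expect_true(all(msy$lrr == 0))
  cfg5 <- simulation_config(cf = 0.5, sigma_lrr = 0, sigma_baf = 0,
                            n_autosomal_probes = 0, seed = 2)
  sim5 <- simulate_cohort(cfg5)
  expect_equal(unique(sim5$probes[chrom == "chrY"]$lrr), -0.45)
  # female with the intensity floor matched to the observed female median
  cfgf <- simulation_config(cf = 0, sex = "female", sigma_lrr = 0,
                            sigma_baf = 0, cn_floor = 0.0062,
                            n_autosomal_probes = 0, seed = 2)
  simf <- simulate_cohort(cfgf)
  expect_equal(round(unique(simf$probes[chrom == "chrY"]$lrr), 2), -3.3)
  expect_identical(unique(simf$probes[chrom == "chrY"]$genotype), "NC")
  expect_true(is.na(simf$truth$expected_bdev))
})

test_that("probe tables carry the canonical layout and region coverage", {
  cfg <- simulation_config(cf = 0.3, n_autosomal_probes = 120, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_s3_class(sim$probes, "probe_table")
  expect_named(sim$probes, c("sample_id", "probe_id", "chrom", "position",
                             "lrr", "baf", "genotype"))
  region <- classify_probe(sim$probes$chrom, sim$probes$position)
  expect_equal(sum(region == "MSY"), 397L)
  expect_equal(sum(region == "PAR1"), 434L)
  expect_equal(sum(region == "AUTOSOME"), 120L)
  # emitted TSV reads back through the canonical dialect
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(sim$probes, path)
  reread <- read_intensity_table(path)
  expect_equal(nrow(reread), nrow(sim$probes))
  expect_equal(reread$lrr, sim$probes$lrr, tolerance = 1e-12)
})

test_that("true-heterozygote miscall frequency matches the Gaussian tails", {
  expect_equal(miscall_rate(0, 0), 0)
  expect_equal(miscall_rate(0, 0.02), miscall_rate(0, 0.02))
  # monotone in the deviation
  b <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(miscall_rate(b, 0.02)) >= 0))
  # Monte-Carlo agreement: simulate one high-CF male and count AB calls
  bdev <- 0.4
  cf_target <- cf_from_bdev(bdev)  # CF whose expected deviation is 0.4
  cfg <- simulation_config(cf = cf_target, sigma_baf = 0.02,
                           n_par1_probes = 5000, n_autosomal_probes = 0,
                           het_fraction = 1, seed = 44)
  sim <- simulate_cohort(cfg)
  par1 <- sim$probes[chrom == "chrX"]
  empirical <- mean(par1$genotype != "AB")
  analytic <- miscall_rate(bdev, 0.02)
  se <- sqrt(analytic * (1 - analytic) / nrow(par1))
  expect_lt(abs(empirical - analytic), 3 * se + 1e-6)
  expect_gt(analytic, 0.98)  # nearly every true het is miscalled
})

test_that("high-CF cohorts lose the BAF route while the LRR route holds", {
  cfg <- simulation_config(cf = rep(0.92, 30), seed = 45)
  sim <- simulate_cohort(cfg)
  calls <- call_cohort(sim$probes)
  # heterozygote miscalling starves the BAF estimator below its minimum
  expect_true(all(is.na(calls$bdev)))
  expect_true(all(calls$n_par1_het < 30))
  # while the LRR route still recovers the true fraction
  expect_true(all(calls$mloy_lrr))
  expect_lt(abs(mean(calls$cf_mlrry) - 0.92), 0.02)
})

test_that("sub-floor cell fractions escape the LRR call but not the Bdev signal", {
  cfg <- simulation_config(cf = rep(0.15, 40), seed = 46)
  sim <- simulate_cohort(cfg)
  calls <- call_cohort(sim$probes)
  # expected mLRR_Y at CF 0.15 is above the -0.15 cutoff
  expect_gt(mlrry_from_cf(0.15), -0.15)
  expect_lt(mean(calls$mloy_lrr, na.rm = TRUE), 0.1)
  # the BAF deviation still registers the event
  expected_bdev <- bdev_from_cf(0.15)
  expect_lt(abs(mean(calls$bdev, na.rm = TRUE) - expected_bdev), 0.01)
})

test_that("simulation configuration loads from YAML with a mandatory seed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cf: [0.1, 0.4]", "n_samples: 2", "sigma_lrr: 0.1",
               "seed: 7"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$cf, c(0.1, 0.4))
  expect_equal(cfg$sigma_lrr, 0.1)
  writeLines("cf: [0.1]", path)
  expect_error(read_simulation_config(path), "seed")
})
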