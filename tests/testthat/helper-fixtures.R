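# Builders for tiny in-code fixtures used across the test files.

# A hand-specified probe table (already in canonical column layout).
make_probe_table <- function(sample_id, chrom, position, lrr = NA_real_,
                             baf = NA_real_, genotype = "NC",
                             probe_id = NULL) {
  n <- max(lengths(list(sample_id, chrom, position, lrr, baf, genotype)))
  data.table::data.table(
    sample_id = rep_len(sample_id, n),
    probe_id = if (is.null(probe_id)) sprintf("p%03d", seq_len(n))
               else rep_len(probe_id, n),
    chrom = rep_len(chrom, n),
    position = as.integer(rep_len(position, n)),
    lrr = rep_len(as.numeric(lrr), n),
    baf = rep_len(as.numeric(baf), n),
    genotype = rep_len(genotype, n))
}

# Write a GenomeStudio-style intensity TSV from explicit vectors.
write_gs_fixture <- function(path, sample, probe, chrom, position, lrr, baf,
                             gtype) {
  dt <- data.table::data.table(
    `Sample ID` = sample, `SNP Name` = probe, Chr = chrom,
    Position = position, `Log R Ratio` = lrr, `B Allele Freq` = baf,
    GType = gtype)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

# Paired-CF table lying exactly on the identity line.
identity_pairs <- function(n) {
  cf <- seq(0.2, 0.95, length.out = n)
  data.table::data.table(
    sample_id = sprintf("S%04d", seq_len(n)),
    cf_mlrry = cf, cf_baf = cf,
    mlrr_y = mloycf::mlrry_from_cf(cf))
}
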