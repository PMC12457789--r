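test_that("end trimming keeps exactly the interior positions", {
  cols <- tibble::tibble(pos = 1:100)
  kept <- trim_ends(cols, 100)
  expect_equal(kept$pos, 7:94)
  expect_equal(nrow(kept), 88)
  expect_warning(empty <- trim_ends(tibble::tibble(pos = 1:12), 12),
                 "trimmed")
  expect_equal(nrow(empty), 0)
  expect_equal(trim_ends(tibble::tibble(pos = 1:13), 13)$pos, 7L)
})

test_that("TPM normalizes rates to one million per sample", {
  one <- compute_tpm(tibble::tibble(sample_id = "s", locus_id = "L1",
                                    est_count = 7, effective_length = 50))
  expect_equal(one$tpm, 1e6)
  two <- compute_tpm(tibble::tibble(
    sample_id = "s", locus_id = c("a", "b"),
    est_count = c(10, 10), effective_length = c(100, 200)))
  expect_equal(two$tpm, c(2e6 / 3, 1e6 / 3))
  expect_equal(round(two$tpm, 2), c(666666.67, 333333.33))
  zero <- compute_tpm(tibble::tibble(
    sample_id = "s", locus_id = c("a", "b"),
    est_count = c(0, 0), effective_length = c(100, 200)))
  expect_equal(zero$tpm, c(0, 0))
  # multi-sample: each sample sums to 1e6 independently
  multi <- compute_tpm(tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    locus_id = rep(c("a", "b", "c"), 2),
    est_count = c(5, 1, 9, 2, 2, 2),
    effective_length = rep(c(100, 300, 120), 2)))
  sums <- tapply(multi$tpm, multi$sample_id, sum)
  expect_equal(as.numeric(sums), c(1e6, 1e6))
})

test_that("the expression filter is strictly greater-than", {
  expect_false(expression_filter(1.0))
  expect_true(expression_filter(1.01))
  expect_equal(sum(expression_filter(c(0, 0.5, 1, 1.000001, 5))), 2)
})

test_that("variant detection reproduces the worked browser example", {
  # self-cross all C at a G reference position; outcross C + G
  self <- pileup_col("s", "self_cross", "L1", 50, "G", C = 30)
  out <- pileup_col("o", "outcross", "L1", 50, "G", C = 20, G = 10)
  v <- detect_variants(self, out, locus_length = 100)
  expect_equal(nrow(v), 1)
  expect_equal(v$alleles_self, "C")
  expect_equal(v$alleles_out, "C,G")
  expect_equal(v$pattern, "II")
  expect_equal(v$pollen_ratio, 100 * 10 / 30)
})

test_that("reference-only and sub-threshold columns are not variants", {
  self <- pileup_col("s", "self_cross", "L1", 50, "G", G = 30)
  out <- pileup_col("o", "outcross", "L1", 50, "G", G = 25)
  expect_equal(nrow(detect_variants(self, out, 100)), 0)
  # one alt read in depth 100 fails min_allele_fraction = 0.1
  out2 <- pileup_col("o", "outcross", "L1", 50, "G", G = 99, C = 1)
  expect_equal(nrow(detect_variants(self, out2, 100)), 0)
  # zero depth in both samples: skipped silently
  self0 <- pileup_col("s", "self_cross", "L1", 50, "G")
  out0 <- pileup_col("o", "outcross", "L1", 50, "G")
  expect_equal(nrow(detect_variants(self0, out0, 100)), 0)
})

test_that("pattern classification follows the two-pattern decision rule", {
  expect_equal(classify_pattern("C", c("C", "G"), "G"), "II")
  expect_equal(classify_pattern(c("C", "G"), c("C", "G"), "G"), "I")
  expect_equal(classify_pattern("C", "C", "G"), "uninformative")
  expect_equal(classify_pattern(c("A", "T"), c("A", "T", "G"), "G"), "II")
  expect_equal(classify_pattern(character(0), "G", "G"), "II")
})

test_that("pollen-allele ratios are reference fractions over present alleles", {
  expect_equal(
    pollen_allele_ratio(c(A = 0, C = 20, G = 10, T = 0), c("C", "G"), "G"),
    100 / 3)
  expect_equal(
    pollen_allele_ratio(c(A = 0, C = 30, G = 0, T = 0), c("C", "G"), "G"),
    0)
  expect_equal(
    pollen_allele_ratio(c(A = 0, C = 0, G = 12, T = 0), "G", "G"), 100)
  # error-level reads of non-present bases are excluded from the denominator
  expect_equal(
    pollen_allele_ratio(c(A = 1, C = 20, G = 10, T = 0), c("C", "G"), "G"),
    100 / 3)
  expect_error(
    pollen_allele_ratio(c(A = 0, C = 0, G = 0, T = 0), "G", "G"), "depth")
})

test_that("locus summaries apply the mean and SE presence rules", {
  s1 <- summarize_locus(calls_with_ratios(38.5, n_pattern_I = 13),
                        "L1", 500)
  expect_equal(s1$n_pattern_I, 13)
  expect_equal(s1$n_pattern_II, 1)
  expect_equal(s1$mean_ratio, 38.5)
  expect_true(is.na(s1$se_ratio))  # single pattern II SNP: dash

  s2 <- summarize_locus(calls_with_ratios(c(50, 50)), "L1", 500)
  expect_equal(s2$mean_ratio, 50)
  expect_equal(s2$se_ratio, 0)

  s3 <- summarize_locus(calls_with_ratios(c(28, 30, 32)), "L1", 500)
  expect_equal(s3$mean_ratio, 30)
  expect_equal(s3$se_ratio, 2 / sqrt(3))

  s0 <- summarize_locus(calls_with_ratios(numeric(0), n_pattern_I = 11),
                        "L1", 500)
  expect_true(is.na(s0$mean_ratio) && is.na(s0$se_ratio))
  expect_true(s0$pollen_detected)  # pattern-I-only still counts
  expect_true(detect_pollen_allele(s0))

  none <- summarize_locus(calls_with_ratios(numeric(0)), "L1", 500)
  expect_false(detect_pollen_allele(none))
})

test_that("a maternal line identical to the reference yields no detection", {
  loci <- acgt_locus(n_units = 40)
  sim <- suppressMessages(simulate_ase(
    loci, pollen_fraction = 0.4, mean_depth = 100,
    maternal_het_rate = 0, maternal_hom_alt_rate = 0, seed = 41))
  expect_equal(nrow(sim$truth), 0)
  res <- suppressMessages(run_ase(sim$pileup, loci))
  expect_equal(nrow(res$variants), 0)
  expect_false(any(detect_pollen_allele(res$summary)))
})

test_that("amino-acid annotation translates the affected codon", {
  expect_equal(annotate_amino_acid_change("ATGGCT", 1, 2, "T", "C"),
               "nonsynonymous")                     # ATG -> ACG, M -> T
  expect_equal(annotate_amino_acid_change("ATGGCT", 1, 6, "T", "C"),
               "synonymous")                        # GCT -> GCC, A -> A
  expect_equal(annotate_amino_acid_change("AAATGGCT", 3, 2, "A", "G"),
               "noncoding")                         # upstream of the CDS
  expect_equal(annotate_amino_acid_change("ACGTACGT", NA, 4, "T", "A"),
               "noncoding")                         # unknown frame
  expect_warning(
    res <- annotate_amino_acid_change("ATGGC", 1, 5, "C", "T"),
    "incomplete")
  expect_equal(res, "noncoding")
  # frame awareness: same position, different cds_start, different codon
  expect_equal(annotate_amino_acid_change("TTTAGA", 1, 4, "A", "G"),
               "nonsynonymous")                     # AGA(R) -> GGA(G)
})

test_that("the pipeline recovers the true pollen fraction and truth patterns", {
  loci <- acgt_locus(n_units = 131)
  pi_true <- 0.3
  sim <- suppressMessages(simulate_ase(
    loci, pollen_fraction = pi_true, mean_depth = 200,
    maternal_het_rate = 0.02, maternal_hom_alt_rate = 0.10, seed = 42))
  res <- suppressMessages(run_ase(sim$pileup, loci))
  v <- res$variants

  # no call inside the trimmed ends
  expect_true(all(v$pos > 6 & v$pos <= loci$length_bp - 6))

  # pattern agreement with generator truth at >= 99% of retained sites
  truth <- sim$truth[sim$truth$pos > 6 &
                       sim$truth$pos <= loci$length_bp - 6, ]
  m <- merge(v, truth, by = c("locus_id", "pos"))
  expect_gte(nrow(m) / nrow(truth), 0.99)
  expect_gte(mean(m$pattern == m$expected_pattern), 0.99)

  # depth-weighted mean ratio within 3 binomial SEs of 100 * pi
  w <- v[v$pattern == "II", ]
  est <- sum(w$pollen_ratio * w$depth_out) / sum(w$depth_out)
  se <- 100 * sqrt(pi_true * (1 - pi_true) / sum(w$depth_out))
  expect_lt(abs(est - 100 * pi_true), 3 * se)
})

test_that("per-SNP ratios equal an independent tally of the read-level log", {
  loci <- acgt_locus(n_units = 40)
  sim <- suppressMessages(simulate_ase(
    loci, pollen_fraction = 0.35, mean_depth = 80,
    maternal_het_rate = 0, maternal_hom_alt_rate = 0.15,
    return_reads = TRUE, seed = 43))
  res <- suppressMessages(run_ase(sim$pileup, loci))
  v <- res$variants[res$variants$pattern == "II", ]
  expect_gt(nrow(v), 5)
  out_id <- unique(sim$pileup$sample_id[sim$pileup$cross_type ==
                                          "outcross"])
  for (i in seq_len(nrow(v))) {
    reads <- sim$reads$base[sim$reads$sample_id == out_id &
                              sim$reads$locus_id == v$locus_id[i] &
                              sim$reads$pos == v$pos[i]]
    present <- strsplit(v$alleles_out[i], ",")[[1]]
    reads <- reads[reads %in% present]
    expect_equal(v$pollen_ratio[i],
                 100 * mean(reads == v$ref_base[i]))
  }
})

test_that("raising the true pollen fraction raises the estimated mean ratio", {
  loci <- acgt_locus(n_units = 131)
  means <- vapply(c(0.1, 0.3, 0.5), function(pi_true) {
    sim <- suppressMessages(simulate_ase(
      loci, pollen_fraction = pi_true, mean_depth = 200,
      maternal_het_rate = 0, maternal_hom_alt_rate = 0.10,
      seed = 44))
    res <- suppressMessages(run_ase(sim$pileup, loci))
    res$summary$mean_ratio[1]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("run_ase honors the expression filter and joins enzyme families", {
  loci <- dplyr::bind_rows(acgt_locus("L1", 40), acgt_locus("L2", 40))
  loci$enzyme_family <- c("PAL", "CHS")
  sim <- suppressMessages(simulate_ase(
    loci, pollen_fraction = 0.3, mean_depth = 60,
    maternal_hom_alt_rate = 0.1, seed = 45))
  expr <- tibble::tibble(sample_id = "out_1",
                         locus_id = c("L1", "L2"),
                         est_count = c(1e6, 1),
                         effective_length = c(160, 160))
  res <- suppressMessages(run_ase(sim$pileup, loci, expression = expr))
  expect_true(res$summary$expressed[res$summary$locus_id == "L1"])
  expect_false(res$summary$expressed[res$summary$locus_id == "L2"])
  # no SNP search in unexpressed loci
  expect_false("L2" %in% res$variants$locus_id)
  expect_equal(res$summary$enzyme_family, c("PAL", "CHS"))
  expect_equal(res$summary$total_positions, c(148L, 148L))
})
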