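#!/usr/bin/env Rscript
# Generate paired self-cross / outcross pileup experiments.
#
# Mirrors the sequencing design: two heterozygous maternal plants (A, B),
# each crossed to a same-line pollen plant (self_cross) and to the
# homozygous reference line (outcross). Fourteen synthetic cDNA loci with
# the length and enzyme-family layout of the loci in which SNPs were
# examined; the true pollen-transcript fraction is set to 0.30 for
# replicate A and 0.25 for replicate B (inside the 20-40% band where most
# observed per-locus ratios fall).

suppressMessages(library(xeniaseq))
dir.create("results/ase", recursive = TRUE, showWarnings = FALSE)

ratios <- ref_pollen_ratios()
meta <- unique(ratios[c("locus_id", "enzyme_family", "total_nt")])

set.seed(75179)
loci <- tibble::tibble(
  locus_id = meta$locus_id,
  enzyme_family = meta$enzyme_family,
  length_bp = meta$total_nt,
  sequence = vapply(meta$total_nt, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1)))
write_fasta(setNames(loci$sequence, loci$locus_id),
            "results/ase/reference_cdna_synthetic.fa")

for (rep_cfg in list(list(rep = "A", pi = 0.30, seed = 118730),
                     list(rep = "B", pi = 0.25, seed = 118757))) {
  sim <- simulate_ase(
    loci, pollen_fraction = rep_cfg$pi, mean_depth = 200,
    base_error = 0.002, maternal_het_rate = 0.015,
    maternal_hom_alt_rate = 0.005, multiallelic_rate = 0.0005,
    self_sample = paste0("self_", rep_cfg$rep),
    out_sample = paste0("out_", rep_cfg$rep),
    seed = rep_cfg$seed)
  write_pileup_table(sim$pileup,
                     sprintf("results/ase/pileup_%s.tsv", rep_cfg$rep))
  write.table(as.data.frame(sim$truth),
              sprintf("results/ase/truth_%s.tsv", rep_cfg$rep),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("Replicate %s: %d truth variant sites (%d pattern II), true pi = %.2f\n",
              rep_cfg$rep, nrow(sim$truth),
              sum(sim$truth$expected_pattern == "II"), rep_cfg$pi))
}
cat("Wrote pileups, truth tables and the synthetic reference FASTA to results/ase/\n")
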