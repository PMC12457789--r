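#!/usr/bin/env Rscript
# Run the allele-specific expression pipeline on the simulated pileups.
#
# Reads the replicate A/B pileups written by 03 back through the file
# layer, applies end-trimming and the presence thresholds, classifies
# each SNP as pattern I (maternal heterozygous for the reference) or
# pattern II (reference reads attributable to the pollen parent), and
# summarizes per locus. Estimates are compared with the generator truth.

suppressMessages(library(xeniaseq))
dir.create("results", showWarnings = FALSE)

ratios <- ref_pollen_ratios()
loci <- unique(ratios[c("locus_id", "enzyme_family", "total_nt")])
names(loci)[names(loci) == "total_nt"] <- "length_bp"

cfg <- pipeline_config()  # defaults: trim 6, count >= 3, fraction >= 0.10
summaries <- list()
for (rep in c("A", "B")) {
  pile <- read_pileup_table(sprintf("results/ase/pileup_%s.tsv", rep))
  res <- run_ase(pile, loci, config = cfg)
  truth <- read.delim(sprintf("results/ase/truth_%s.tsv", rep))
  pi_true <- unique(truth$true_pi)

  w <- res$variants[res$variants$pattern == "II", ]
  est <- sum(w$pollen_ratio * w$depth_out) / sum(w$depth_out)
  cat(sprintf("Replicate %s: %d SNPs (%d pattern II); depth-weighted pollen ratio %.1f%% (truth %.0f%%)\n",
              rep, nrow(res$variants), nrow(w), est, 100 * pi_true))

  s <- res$summary
  s$replicate <- rep
  summaries[[rep]] <- s
  out <- sprintf("results/ase_summary_%s.tsv", rep)
  sdf <- as.data.frame(s)
  sdf$mean_ratio <- ifelse(is.na(sdf$mean_ratio), "-",
                           formatC(round_report(sdf$mean_ratio, 1),
                                   format = "f", digits = 1))
  sdf$se_ratio <- ifelse(is.na(sdf$se_ratio), "-",
                         formatC(round_report(sdf$se_ratio, 2),
                                 format = "f", digits = 2))
  write.table(sdf[c("locus_id", "enzyme_family", "total_positions",
                    "n_pattern_I", "n_pattern_II", "mean_ratio",
                    "se_ratio")],
              out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  wrote %s\n", out))
}
saveRDS(dplyr::bind_rows(summaries), "results/ase_summaries.rds")
cat("Note: loci drawn with few or no homozygous-alternative maternal sites\n")
cat("report a dash for the ratio, exactly like the pattern-I-only loci in\n")
cat("the published per-locus table.\n")
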