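#!/usr/bin/env Rscript
# Effect partitioning on simulated per-seed data, with LSD significance.
#
# The desk-scale run (01) has no per-seed data, so no significance tests.
# Here we regenerate the full field design — 5 plants x 15 seeds per line,
# per-line Normal distributions with the published means/SDs, F1 lots with
# the maternal-effect values recomputed in 01 as ground truth — and run
# the complete engine: group means, LSD within each plot, star codes.

suppressMessages(library(xeniaseq))
dir.create("results", showWarnings = FALSE)

lines <- ref_parent_lines()
crosses <- ref_crosses()
m_truth <- setNames(effects_from_means(lines, crosses)$m, crosses$cross_id)

rec <- simulate_rutin(lines, crosses, m_truth = m_truth,
                      sd_f1 = setNames(crosses$f1_sd, crosses$cross_id),
                      seed = 20240618)
write_rutin_table(rec, "results/seed_rutin_simulated.tsv")

eff <- compute_effects(rec, crosses)
render_report(effects = eff, out_dir = "results/simulated_report")
cat("\nSimulated per-seed effect partitioning (75 seeds/group):\n")
print(as.data.frame(parse_effects_report(
  "results/simulated_report/effects.tsv")))

cat(sprintf("\nMean |m_hat - m_truth| over %d crosses: %.3f\n",
            nrow(eff), mean(abs(eff$m - m_truth[eff$cross_id]))))
cat("Heads-up: with 75 seeds/group and the wide high-rutin line SD (0.41),\n")
cat("single-cross m estimates scatter by ~0.1, and resampling negative\n")
cat("draws shifts that line's realized mean upward; the published-scale\n")
cat("design quantifies direction and rough size of xenia, not precise m.\n")
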