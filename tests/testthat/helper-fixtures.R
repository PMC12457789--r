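# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# A single pileup column with named counts.
pileup_col <- function(sample_id, cross_type, locus_id, pos, ref,
                       A = 0, C = 0, G = 0, T = 0) {
  tibble::tibble(sample_id = sample_id, cross_type = cross_type,
                 locus_id = locus_id, pos = as.integer(pos),
                 ref_base = ref,
                 count_A = as.integer(A), count_C = as.integer(C),
                 count_G = as.integer(G), count_T = as.integer(T))
}

# Repeating-ACGT reference locus of length 4 * n_units.
acgt_locus <- function(locus_id = "L1", n_units = 131) {
  tibble::tibble(locus_id = locus_id,
                 sequence = strrep("ACGT", n_units),
                 length_bp = 4L * as.integer(n_units))
}

# Variant-call rows with given pollen ratios (pattern II) and pattern I
# filler, for summarize_locus() tests.
calls_with_ratios <- function(ratios, n_pattern_I = 0) {
  n2 <- length(ratios)
  tibble::tibble(
    locus_id = "L1",
    pos = seq_len(n2 + n_pattern_I) + 6L,
    pattern = c(rep("II", n2), rep("I", n_pattern_I)),
    pollen_ratio = c(ratios, rep(NA_real_, n_pattern_I)))
}

expect_silent_messages <- function(expr) {
  suppressMessages(expr)
}
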