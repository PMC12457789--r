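#' @name allele_expression
#' @title Pollen-allele expression from paired self-cross/outcross pileups
#'
#' @description
#' Quantifies expression of the pollen parent's alleles in F1 seed
#' transcriptomes. Reads are assumed mapped to the cDNA of a homozygous
#' reference line that is also the outcross pollen parent, so at sites
#' where the maternal line carries no reference allele, reference-base
#' reads in the outcross must come from the pollen parent. Comparing the
#' outcross with a self-type cross from the same maternal plant separates
#' such sites from ordinary maternal heterozygosity.
#'
#' The stage order mirrors the upstream protocol: end-trimming (the first
#' and last bases of each locus have unreliable base calls), a strict
#' TPM > threshold expression filter, threshold-based SNP detection,
#' pattern classification, per-SNP pollen-allele ratios, and per-locus
#' summaries.
NULL

#' Trim unreliable locus ends
#'
#' Retains pileup columns at positions `p` with
#' `trim_bases < p <= length - trim_bases`. A locus no longer than
#' `2 * trim_bases` is emptied with a warning.
#'
#' @param columns Pileup tibble for a single locus (must have `pos`).
#' @param locus_length Full locus length in bp.
#' @param trim_bases Bases removed from each end (default 6).
#' @return The retained rows of `columns`.
#' @export
#' @examples
#' cols <- tibble::tibble(pos = 1:100)
#' nrow(trim_ends(cols, 100))  # 88: positions 7..94
trim_ends <- function(columns, locus_length, trim_bases = 6) {
  stopifnot(trim_bases >= 0, locus_length >= 1)
  if (locus_length <= 2 * trim_bases) {
    warning(sprintf("locus length %d <= 2 * %d: all positions trimmed",
                    locus_length, trim_bases), call. = FALSE)
    return(columns[0, , drop = FALSE])
  }
  columns[columns$pos > trim_bases &
          columns$pos <= locus_length - trim_bases, , drop = FALSE]
}

retained_length <- function(locus_length, trim_bases) {
  max(locus_length - 2 * trim_bases, 0L)
}

#' Transcripts per million from counts and effective lengths
#'
#' Within each sample, `tpm_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`.
#' A sample whose counts are all zero gets TPM 0 everywhere.
#'
#' @param expression Tibble with `sample_id`, `locus_id`, `est_count`,
#'   `effective_length` ([read_expression_table()] layout).
#' @return The input with a `tpm` column added.
#' @export
#' @examples
#' compute_tpm(tibble::tibble(sample_id = "s", locus_id = c("a", "b"),
#'                            est_count = c(10, 10),
#'                            effective_length = c(100, 200)))
compute_tpm <- function(expression) {
  stopifnot(all(expression$est_count >= 0),
            all(expression$effective_length > 0))
  expression |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(.rate = .data$est_count / .data$effective_length,
                  tpm = if (sum(.data$.rate) > 0)
                          1e6 * .data$.rate / sum(.data$.rate)
                        else 0) |>
    dplyr::ungroup() |>
    dplyr::select(-".rate")
}

#' Expression filter
#'
#' A locus is expressed iff its TPM is strictly greater than the
#' threshold (TPM exactly at the threshold does not pass).
#'
#' @param tpm Numeric vector of TPM values.
#' @param tpm_threshold Cutoff (default 1.0).
#' @return Logical vector.
#' @export
expression_filter <- function(tpm, tpm_threshold = 1.0) {
  tpm > tpm_threshold
}

# Alleles present in one pileup column: count >= min_count AND
# count/depth >= min_fraction. Empty when depth is 0.
present_alleles <- function(counts, min_count, min_fraction) {
  depth <- sum(counts)
  if (depth == 0) return(character(0))
  keep <- counts >= min_count & counts / depth >= min_fraction
  BASES[keep]
}

#' Classify a variant position into SNP pattern I or II
#'
#' Pattern II (ratio-informative): the maternal line carries no reference
#' allele — the reference base is absent from the self-cross allele set
#' but present in the outcross, so outcross reference reads are
#' attributable to the pollen parent. Pattern I (detected but not
#' ratio-informative): the reference base is among the self-cross alleles
#' (maternal reference/alternative heterozygote; pollen reference reads
#' are confounded with maternal ones). Anything else is uninformative
#' (the pollen allele is not observed).
#'
#' This decision rule is deliberately a standalone pure function so an
#' alternative taxonomy can be swapped in.
#'
#' @param alleles_self,alleles_out Character vectors of present alleles.
#' @param ref Reference base at the position.
#' @return `"I"`, `"II"` or `"uninformative"`.
#' @export
#' @examples
#' classify_pattern(c("C"), c("C", "G"), "G")       # "II"
#' classify_pattern(c("C", "G"), c("C", "G"), "G")  # "I"
classify_pattern <- function(alleles_self, alleles_out, ref) {
  stopifnot(ref %in% BASES)
  if (ref %in% alleles_self) "I"
  else if (ref %in% alleles_out) "II"
  else "uninformative"
}

#' Pollen-allele ratio at a pattern II position
#'
#' Percentage of outcross reads carrying the pollen (reference) base,
#' over reads of the alleles deemed present at that position (reads of
#' error-level bases below the presence thresholds are excluded from the
#' denominator).
#'
#' @param counts Named count vector (A, C, G, T) for the outcross column.
#' @param present Character vector of present alleles (must include
#'   `ref`).
#' @param ref Reference base.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' pollen_allele_ratio(c(A = 0, C = 20, G = 10, T = 0), c("C", "G"), "G")
pollen_allele_ratio <- function(counts, present, ref) {
  denom <- sum(counts[present])
  if (denom == 0) stop("zero depth over present alleles", call. = FALSE)
  100 * unname(counts[ref]) / denom
}

#' Detect and classify SNPs for one locus
#'
#' Applies end-trimming, then at every retained position determines the
#' present alleles in the self-cross and outcross columns, flags the
#' position as a variant if any present allele differs from the reference
#' in either sample, classifies the variant's pattern, and computes the
#' pollen-allele ratio for pattern II positions. Positions with zero
#' depth in both samples are skipped.
#'
#' @param self_columns,out_columns Pileup tibbles for the same locus from
#'   the self-cross and outcross samples.
#' @param locus_length Locus length in bp (for trimming).
#' @param config A [pipeline_config()].
#' @return Tibble of variant calls: `locus_id`, `pos`, `ref_base`,
#'   `alleles_self`, `alleles_out` (comma-joined), `pattern`,
#'   `pollen_ratio` (`NA` unless pattern II), `depth_out`.
#' @export
detect_variants <- function(self_columns, out_columns, locus_length,
                            config = pipeline_config()) {
  s <- trim_ends(self_columns, locus_length, config$trim_bases)
  o <- trim_ends(out_columns, locus_length, config$trim_bases)
  pos_all <- sort(union(s$pos, o$pos))
  calls <- list()
  for (p in pos_all) {
    si <- match(p, s$pos); oi <- match(p, o$pos)
    cs <- if (is.na(si)) c(A = 0, C = 0, G = 0, T = 0) else
      c(A = s$count_A[si], C = s$count_C[si], G = s$count_G[si],
        T = s$count_T[si])
    co <- if (is.na(oi)) c(A = 0, C = 0, G = 0, T = 0) else
      c(A = o$count_A[oi], C = o$count_C[oi], G = o$count_G[oi],
        T = o$count_T[oi])
    if (sum(cs) == 0 && sum(co) == 0) next
    ref <- if (!is.na(si)) s$ref_base[si] else o$ref_base[oi]
    as_ <- present_alleles(cs, config$min_allele_count,
                           config$min_allele_fraction)
    ao <- present_alleles(co, config$min_allele_count,
                          config$min_allele_fraction)
    if (length(setdiff(c(as_, ao), ref)) == 0) next  # no non-ref allele
    pattern <- classify_pattern(as_, ao, ref)
    ratio <- if (pattern == "II")
      pollen_allele_ratio(co, ao, ref) else NA_real_
    calls[[length(calls) + 1]] <- tibble(
      locus_id = if (!is.na(si)) s$locus_id[si] else o$locus_id[oi],
      pos = p, ref_base = ref,
      alleles_self = paste(as_, collapse = ","),
      alleles_out = paste(ao, collapse = ","),
      pattern = pattern, pollen_ratio = ratio,
      depth_out = sum(co))
  }
  dplyr::bind_rows(c(list(empty_calls()), calls))
}

# Zero-row variant-call tibble with the full schema.
empty_calls <- function() {
  tibble(locus_id = character(0), pos = integer(0),
         ref_base = character(0), alleles_self = character(0),
         alleles_out = character(0), pattern = character(0),
         pollen_ratio = numeric(0), depth_out = numeric(0))
}

#' Summarize variant calls for one locus
#'
#' Counts pattern I and II SNPs and computes the mean and standard error
#' of the per-SNP pollen-allele ratios: the mean is present iff at least
#' one pattern II SNP exists; the SE (sample SD divided by the square
#' root of the pattern II count) is present iff at least two exist —
#' single-SNP loci are reported with an absent SE (rendered as a dash).
#'
#' @param calls Variant-call tibble from [detect_variants()] (one locus).
#' @param locus_id Locus identifier (used when `calls` is empty).
#' @param total_positions Number of retained (post-trim) positions.
#' @param tpm TPM of the locus (`NA` if not supplied).
#' @param expressed Logical expression flag.
#' @return One-row tibble: `locus_id`, `total_positions`, `n_pattern_I`,
#'   `n_pattern_II`, `mean_ratio`, `se_ratio`, `pollen_detected`,
#'   `expressed`, `tpm`.
#' @export
summarize_locus <- function(calls, locus_id, total_positions,
                            tpm = NA_real_, expressed = NA) {
  r <- calls$pollen_ratio[!is.na(calls$pollen_ratio) &
                            calls$pattern == "II"]
  n2 <- sum(calls$pattern == "II")
  tibble(locus_id = locus_id,
         total_positions = as.integer(total_positions),
         n_pattern_I = sum(calls$pattern == "I"),
         n_pattern_II = n2,
         mean_ratio = if (n2 >= 1) mean(r) else NA_real_,
         se_ratio = if (n2 >= 2) sample_sd(r) / sqrt(n2) else NA_real_,
         pollen_detected = (sum(calls$pattern == "I") + n2) >= 1,
         expressed = expressed, tpm = tpm)
}

#' Pollen-allele detection flag per locus
#'
#' A pollen-parent allele counts as detected at a locus iff at least one
#' SNP of either pattern was found — pattern-I-only loci demonstrate the
#' pollen allele's presence even though no ratio can be computed.
#'
#' @param summaries Per-locus summary tibble ([summarize_locus()] rows).
#' @return Logical vector, one per row.
#' @export
detect_pollen_allele <- function(summaries) {
  (summaries$n_pattern_I + summaries$n_pattern_II) >= 1
}

#' Annotate a substitution as synonymous, nonsynonymous or noncoding
#'
#' Translates the codon containing the position with the standard genetic
#' code, before and after substituting the alternative base. Positions
#' upstream of the coding start, loci with unknown coding start, and
#' positions falling in an incomplete terminal codon are noncoding (the
#' latter with a warning).
#'
#' @param sequence Reference cDNA sequence of the locus.
#' @param cds_start 1-based position where the coding frame starts
#'   (`NA` for unknown).
#' @param pos Position of the substitution.
#' @param ref_base,alt_base Reference and alternative bases.
#' @return `"synonymous"`, `"nonsynonymous"` or `"noncoding"`.
#' @export
#' @examples
#' annotate_amino_acid_change("ATGGCT", 1, 2, "T", "C")  # nonsynonymous
annotate_amino_acid_change <- function(sequence, cds_start, pos,
                                       ref_base, alt_base) {
  stopifnot(pos >= 1, pos <= nchar(sequence),
            ref_base %in% BASES, alt_base %in% BASES)
  if (is.na(cds_start) || pos < cds_start) return("noncoding")
  offset <- pos - cds_start
  codon_start <- cds_start + 3 * (offset %/% 3)
  if (codon_start + 2 > nchar(sequence)) {
    warning("position falls in an incomplete terminal codon",
            call. = FALSE)
    return("noncoding")
  }
  codon <- substr(sequence, codon_start, codon_start + 2)
  within <- offset %% 3 + 1
  ref_codon <- codon
  substr(ref_codon, within, within) <- ref_base
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  code <- Biostrings::GENETIC_CODE
  if (code[[ref_codon]] == code[[alt_codon]]) "synonymous"
  else "nonsynonymous"
}

#' Run the allele-specific expression pipeline on one sample pair
#'
#' Orchestrates TPM computation, the expression filter, per-locus SNP
#' detection, pattern classification and summarization for one
#' self-cross / outcross pair of pileups. SNPs are searched only in
#' expressed loci; when `expression` is `NULL` all loci are treated as
#' expressed (TPM reported as `NA`).
#'
#' @param pileup Pileup tibble containing exactly one `self_cross` and
#'   one `outcross` sample.
#' @param loci Locus tibble with `locus_id`, `length_bp` and optionally
#'   `enzyme_family`.
#' @param expression Optional expression tibble for the outcross sample
#'   ([read_expression_table()] layout).
#' @param config A [pipeline_config()].
#' @return A list with `variants` (all calls) and `summary` (one row per
#'   locus, enzyme family joined in when available).
#' @export
run_ase <- function(pileup, loci, expression = NULL,
                    config = pipeline_config()) {
  types <- split(unique(pileup$sample_id),
                 pileup$cross_type[match(unique(pileup$sample_id),
                                         pileup$sample_id)])
  if (length(types$self_cross) != 1 || length(types$outcross) != 1)
    stop("pileup must contain exactly one self_cross and one outcross sample",
         call. = FALSE)

  if (!is.null(expression)) {
    expression <- compute_tpm(expression)
    tpm <- setNames(expression$tpm, expression$locus_id)
  } else tpm <- NULL

  variants <- list(); summaries <- list()
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    L <- loci$length_bp[i]
    tp <- if (is.null(tpm)) NA_real_ else unname(tpm[lid])
    expressed <- if (is.null(tpm)) TRUE
                 else !is.na(tp) && expression_filter(tp, config$tpm_threshold)
    calls <- if (expressed) {
      detect_variants(
        pileup[pileup$cross_type == "self_cross" &
               pileup$locus_id == lid, ],
        pileup[pileup$cross_type == "outcross" &
               pileup$locus_id == lid, ],
        L, config)
    } else empty_calls()
    variants[[i]] <- if (expressed) calls else NULL
    summaries[[i]] <- summarize_locus(
      calls, lid, retained_length(L, config$trim_bases),
      tpm = if (is.null(tpm)) NA_real_ else tp,
      expressed = expressed)
  }
  summary <- dplyr::bind_rows(summaries)
  if ("enzyme_family" %in% names(loci))
    summary <- dplyr::left_join(
      summary, loci[, c("locus_id", "enzyme_family")], by = "locus_id")
  log_stage("run_ase",
            "%d loci (%d expressed), %d variants, %d pattern II",
            nrow(loci), sum(summary$expressed, na.rm = TRUE),
            sum(summary$n_pattern_I + summary$n_pattern_II),
            sum(summary$n_pattern_II))
  list(variants = dplyr::bind_rows(variants), summary = summary)
}
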