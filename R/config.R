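#' Pipeline configuration
#'
#' Collects the fixed analysis constants in one validated object: the
#' number of low-quality bases trimmed from each end of a locus, the TPM
#' expression cutoff (strict `>`), the allele-presence thresholds used in
#' place of by-eye browser calls, report rounding, the pollen-ratio band
#' of interest, and the rutin-content group boundaries (mg/g).
#'
#' @param trim_bases Bases removed from each end of every locus before SNP
#'   detection (default 6; base-call quality is unreliable there).
#' @param tpm_threshold A locus counts as expressed iff TPM is strictly
#'   greater than this (default 1.0).
#' @param min_allele_count Minimum reads supporting a base for it to count
#'   as a present allele at a position (default 3).
#' @param min_allele_fraction Minimum fraction of the column depth for a
#'   present allele (default 0.10). Suppresses sequencing-error noise.
#' @param rounding_decimals Decimal places for rendered reports (default 2).
#' @param band_lo,band_hi Inclusive pollen-ratio band reported by
#'   [ratio_stats()], in percent (defaults 20 and 40).
#' @param rutin_low,rutin_high Group boundaries in mg/g for
#'   [classify_rutin_group()]: `< rutin_low` is low, `> rutin_high` is high,
#'   the closed interval between is medium (defaults 0.1 and 0.5).
#' @return A list of class `xeniaseq_config`.
#' @export
pipeline_config <- function(trim_bases = 6L,
                            tpm_threshold = 1.0,
                            min_allele_count = 3L,
                            min_allele_fraction = 0.10,
                            rounding_decimals = 2L,
                            band_lo = 20,
                            band_hi = 40,
                            rutin_low = 0.1,
                            rutin_high = 0.5) {
  stopifnot(trim_bases >= 0,
            min_allele_count >= 0,
            min_allele_fraction >= 0, min_allele_fraction <= 1,
            rounding_decimals >= 0,
            band_lo <= band_hi,
            rutin_low <= rutin_high)
  structure(
    list(trim_bases = as.integer(trim_bases),
         tpm_threshold = tpm_threshold,
         min_allele_count = as.integer(min_allele_count),
         min_allele_fraction = min_allele_fraction,
         rounding_decimals = as.integer(rounding_decimals),
         band_lo = band_lo, band_hi = band_hi,
         rutin_low = rutin_low, rutin_high = rutin_high),
    class = "xeniaseq_config")
}

#' @export
print.xeniaseq_config <- function(x, ...) {
  cat("xeniaseq pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
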