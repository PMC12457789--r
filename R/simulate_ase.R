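#' Simulate paired self-cross / outcross pileup experiments
#'
#' Emulates the read-count data of the allele-specific expression design:
#' a heterozygous self-incompatible maternal plant is crossed (i) to a
#' pollen plant drawn from the same heterogeneous population
#' (`self_cross`) and (ii) to the homozygous line whose cDNA is the
#' mapping reference (`outcross`, pollen allele = reference base at every
#' site). Reads in the F1 seed transcriptome come from the pollen allele
#' with probability `pollen_fraction` and otherwise from one of the two
#' maternal alleles (each with probability 1/2).
#'
#' Per locus and position the maternal genotype is drawn once:
#' heterozygous reference/alternative with probability
#' `maternal_het_rate`, homozygous for a single alternative base with
#' probability `maternal_hom_alt_rate`, heterozygous for two distinct
#' alternative bases with probability `multiallelic_rate`, otherwise
#' homozygous reference. The self-cross pollen plant's contributed allele
#' is drawn from the same population site frequencies (reference or
#' alternative with probability 1/2 at heterozygous sites). Read depth per
#' position and sample is `Poisson(mean_depth)`; each read's base is
#' mis-called with probability `base_error`, uniformly to one of the three
#' other bases.
#'
#' The returned truth table covers exactly the sites where the maternal
#' genotype carries a non-reference allele, with the SNP pattern the
#' classifier is expected to assign: pattern `"I"` for maternal
#' reference/alternative heterozygotes (pollen reference reads are
#' confounded with maternal ones) and `"II"` for maternal genotypes
#' without a reference allele (reference reads in the outcross are
#' attributable to the pollen parent).
#'
#' An optional three-compartment seed model (`tissue_weights`, named
#' `embryo` / `endosperm` / `testa`, summing to 1) replaces the single
#' mixing fraction by tissue-dosage expectations: pollen-allele fraction
#' 1/2 in the diploid embryo, 1/3 in the 2:1 maternal:paternal triploid
#' endosperm, 0 in the maternal testa. Off by default — the pipeline
#' measures only the aggregate ratio.
#'
#' @param loci Tibble with `locus_id` and `sequence` (uppercase A/C/G/T;
#'   the reference cDNA). Optional columns are carried through.
#' @param pollen_fraction True fraction of transcripts from the pollen
#'   allele, in \[0, 1\].
#' @param mean_depth Mean read depth per position (Poisson).
#' @param base_error Per-read base mis-call probability (default 0).
#' @param maternal_het_rate,maternal_hom_alt_rate,multiallelic_rate Site
#'   class rates; must sum to at most 1. Defaults (0.015 / 0.005 / 0)
#'   give SNP densities of the order seen in heterozygous buckwheat cDNA.
#' @param tissue_weights Optional named weights for the three-compartment
#'   mode (overrides `pollen_fraction`).
#' @param self_sample,out_sample Sample identifiers for the two pileups.
#' @param return_reads If `TRUE`, also return the post-error read-level
#'   log (one row per read) for independent re-tallying.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A list with `pileup` (both samples, [read_pileup_table()]
#'   layout plus `depth`), `truth` (one row per non-reference maternal
#'   site: `locus_id`, `pos`, `ref_base`, `maternal_a1`, `maternal_a2`,
#'   `genotype_class`, `expected_pattern`, `true_pi`), and `reads` (`NULL`
#'   unless `return_reads`).
#' @export
#' @examples
#' loci <- tibble::tibble(locus_id = "L1",
#'                        sequence = strrep("ACGT", 30))
#' sim <- simulate_ase(loci, pollen_fraction = 0.3, mean_depth = 50,
#'                     seed = 1)
#' head(sim$truth)
simulate_ase <- function(loci, pollen_fraction, mean_depth = 200,
                         base_error = 0,
                         maternal_het_rate = 0.015,
                         maternal_hom_alt_rate = 0.005,
                         multiallelic_rate = 0,
                         tissue_weights = NULL,
                         self_sample = "self_1", out_sample = "out_1",
                         return_reads = FALSE, seed = NULL) {
  if (nrow(loci) == 0) stop("empty locus list", call. = FALSE)
  stopifnot(pollen_fraction >= 0, pollen_fraction <= 1, mean_depth > 0,
            base_error >= 0, base_error <= 1,
            maternal_het_rate >= 0, maternal_hom_alt_rate >= 0,
            multiallelic_rate >= 0,
            maternal_het_rate + maternal_hom_alt_rate +
              multiallelic_rate <= 1)
  if (!is.null(tissue_weights)) {
    stopifnot(setequal(names(tissue_weights),
                       c("embryo", "endosperm", "testa")),
              abs(sum(tissue_weights) - 1) < 1e-8)
    pollen_fraction <- 0.5 * tissue_weights[["embryo"]] +
      (1 / 3) * tissue_weights[["endosperm"]]
  }
  if (!is.null(seed)) withr::local_seed(seed)

  pileup_rows <- list(); truth_rows <- list(); read_rows <- list()
  for (li in seq_len(nrow(loci))) {
    lid <- loci$locus_id[li]
    refs <- strsplit(toupper(loci$sequence[li]), "")[[1]]
    if (!all(refs %in% BASES))
      stop(sprintf("locus %s: sequence must be A/C/G/T only", lid),
           call. = FALSE)
    L <- length(refs)
    u <- runif(L)
    cls <- rep("hom_ref", L)
    cls[u < maternal_het_rate] <- "het"
    cls[u >= maternal_het_rate &
        u < maternal_het_rate + maternal_hom_alt_rate] <- "hom_alt"
    cls[u >= maternal_het_rate + maternal_hom_alt_rate &
        u < maternal_het_rate + maternal_hom_alt_rate +
            multiallelic_rate] <- "multi"

    a1 <- refs; a2 <- refs          # maternal genotype per site
    pollen_self <- refs             # self-cross pollen plant's allele
    for (p in which(cls != "hom_ref")) {
      alts <- setdiff(BASES, refs[p])
      if (cls[p] == "het") {
        alt <- sample(alts, 1)
        a1[p] <- refs[p]; a2[p] <- alt
        pollen_self[p] <- sample(c(refs[p], alt), 1)
      } else if (cls[p] == "hom_alt") {
        alt <- sample(alts, 1)
        a1[p] <- alt; a2[p] <- alt
        pollen_self[p] <- alt
      } else {
        two <- sample(alts, 2)
        a1[p] <- two[1]; a2[p] <- two[2]
        pollen_self[p] <- sample(two, 1)
      }
    }

    for (sm in list(list(id = self_sample, type = "self_cross",
                         pollen = pollen_self),
                    list(id = out_sample, type = "outcross",
                         pollen = refs))) {
      depth <- rpois(L, mean_depth)
      counts <- matrix(0L, nrow = L, ncol = 4,
                       dimnames = list(NULL, BASES))
      for (p in seq_len(L)) {
        d <- depth[p]
        if (d == 0) next
        n_pollen <- rbinom(1, d, pollen_fraction)
        n_m1 <- rbinom(1, d - n_pollen, 0.5)
        bases <- c(rep(sm$pollen[p], n_pollen),
                   rep(a1[p], n_m1), rep(a2[p], d - n_pollen - n_m1))
        if (base_error > 0) {
          err <- runif(d) < base_error
          if (any(err))
            bases[err] <- vapply(bases[err], function(b)
              sample(setdiff(BASES, b), 1), character(1))
        }
        counts[p, ] <- tabulate(match(bases, BASES), 4L)
        if (return_reads)
          read_rows[[length(read_rows) + 1]] <-
            tibble(sample_id = sm$id, locus_id = lid, pos = p,
                   base = bases)
      }
      pileup_rows[[length(pileup_rows) + 1]] <-
        tibble(sample_id = sm$id, cross_type = sm$type, locus_id = lid,
               pos = seq_len(L), ref_base = refs,
               count_A = counts[, "A"], count_C = counts[, "C"],
               count_G = counts[, "G"], count_T = counts[, "T"],
               depth = depth)
    }

    var_sites <- which(cls != "hom_ref")
    truth_rows[[length(truth_rows) + 1]] <- tibble(
      locus_id = lid, pos = var_sites, ref_base = refs[var_sites],
      maternal_a1 = a1[var_sites], maternal_a2 = a2[var_sites],
      genotype_class = c(het = "ref_alt", hom_alt = "alt_alt",
                         multi = "alt1_alt2")[cls[var_sites]],
      expected_pattern = ifelse(cls[var_sites] == "het", "I", "II"),
      true_pi = pollen_fraction)
  }

  truth <- dplyr::bind_rows(truth_rows)
  log_stage("simulate_ase",
            "%d loci, %d variant truth sites, pi = %.3f, depth %g",
            nrow(loci), nrow(truth), pollen_fraction, mean_depth)
  list(pileup = dplyr::bind_rows(pileup_rows),
       truth = truth,
       reads = if (return_reads) dplyr::bind_rows(read_rows) else NULL)
}
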