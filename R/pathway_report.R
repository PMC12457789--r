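#' Classify a line's rutin level
#'
#' Groups a mean seed rutin content (mg/g) into `low` (< 0.1), `medium`
#' (0.1 to 0.5, both boundaries included) or `high` (> 0.5).
#'
#' @param mean_rutin Numeric vector of non-negative means (mg/g).
#' @return Character vector of group labels.
#' @export
#' @examples
#' classify_rutin_group(c(0.06, 0.18, 0.60))
classify_rutin_group <- function(mean_rutin) {
  if (any(mean_rutin < 0)) stop("negative rutin mean", call. = FALSE)
  ifelse(mean_rutin < 0.1, "low",
         ifelse(mean_rutin > 0.5, "high", "medium"))
}

#' Aggregate per-locus results to pathway level
#'
#' Per enzyme family: loci detected in the reference annotation, loci
#' expressed, loci with a pollen-parent allele detected. The totals row
#' counts all families in the detected column but excludes the
#' glycosyltransferase (GTR) family from the expressed and
#' pollen-detected totals (a GTR gene was expressed in only a single
#' plant, so the pathway summary flags rather than counts it);
#' `percent_expressed` is `100 * total expressed / total detected`.
#'
#' @param locus_status Tibble with `locus_id`, `enzyme_family`,
#'   `expressed`, `pollen_detected` — e.g. [ref_pathway_loci()] or a
#'   [run_ase()] summary joined to a locus table.
#' @return A list with `by_family` (one row per family present) and
#'   `totals` (single row: `n_detected`, `n_expressed`,
#'   `n_pollen_detected`, `percent_expressed`).
#' @export
#' @examples
#' tabulate_pathway(ref_pathway_loci())$totals
tabulate_pathway <- function(locus_status) {
  stopifnot(all(c("locus_id", "enzyme_family", "expressed",
                  "pollen_detected") %in% names(locus_status)))
  bad <- setdiff(unique(locus_status$enzyme_family), ENZYME_FAMILIES)
  if (length(bad) > 0)
    stop(sprintf("unknown enzyme family %s", dQuote(bad[1])),
         call. = FALSE)
  by_family <- locus_status |>
    dplyr::group_by(.data$enzyme_family) |>
    dplyr::summarise(n_detected = dplyr::n(),
                     n_expressed = sum(.data$expressed),
                     n_pollen_detected = sum(.data$pollen_detected),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$enzyme_family, ENZYME_FAMILIES))
  non_gtr <- by_family[by_family$enzyme_family != "GTR", ]
  totals <- tibble(
    n_detected = sum(by_family$n_detected),
    n_expressed = sum(non_gtr$n_expressed),
    n_pollen_detected = sum(non_gtr$n_pollen_detected))
  totals$percent_expressed <-
    if (totals$n_detected > 0)
      100 * totals$n_expressed / totals$n_detected else NA_real_
  list(by_family = by_family, totals = totals)
}

#' Pollen-allele ratio statistics across loci and replicates
#'
#' Pools the per-locus mean pollen-allele ratios over all locus x
#' replicate combinations where a ratio exists, and reports how many fall
#' inside an inclusive percentage band (both band edges count as inside),
#' along with the minimum and maximum.
#'
#' @param mean_ratios Numeric vector of per-locus mean ratios in percent;
#'   `NA`s (loci without pattern II SNPs) are dropped.
#' @param band_lo,band_hi Band edges in percent (defaults 20 and 40).
#' @return One-row tibble: `n_values`, `min_ratio`, `max_ratio`,
#'   `band_count`, `band_percent`.
#' @export
#' @examples
#' ratio_stats(ref_pollen_ratios()$mean_ratio)
ratio_stats <- function(mean_ratios, band_lo = 20, band_hi = 40) {
  stopifnot(band_lo <= band_hi)
  r <- mean_ratios[!is.na(mean_ratios)]
  if (length(r) == 0) stop("no ratios available", call. = FALSE)
  inside <- r >= band_lo & r <= band_hi
  tibble(n_values = length(r),
         min_ratio = min(r), max_ratio = max(r),
         band_count = sum(inside),
         band_percent = 100 * sum(inside) / length(r))
}

#' Render the pipeline report
#'
#' Writes machine-readable TSVs (effect partitioning, pathway summary,
#' ratio statistics) plus a short markdown report. Numeric cells are
#' rounded half away from zero to `config$rounding_decimals`; absent
#' values are rendered as `"-"`. Empty inputs produce explicit "no data"
#' sections rather than empty files.
#'
#' @param effects Effect tibble ([compute_effects()] or
#'   [effects_from_means()] output), or `NULL`.
#' @param pathway [tabulate_pathway()] output, or `NULL`.
#' @param stats [ratio_stats()] output, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written.
#' @export
render_report <- function(effects = NULL, pathway = NULL, stats = NULL,
                          out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- config$rounding_decimals
  paths <- character(0)
  md <- c("# Pollen-parent effect report", "")

  if (!is.null(effects) && nrow(effects) > 0) {
    tab <- data.frame(cross_id = effects$cross_id,
                      mp = fmt_cell(effects$mp, d),
                      f1_mean = fmt_cell(effects$f1_mean, d),
                      f1_sd = if ("f1_sd" %in% names(effects))
                        fmt_cell(effects$f1_sd, d) else "-",
                      sig_pm_vs_f1 = if ("stars_pm" %in% names(effects))
                        effects$stars_pm else "-",
                      sig_pp_vs_f1 = if ("stars_pp" %in% names(effects))
                        effects$stars_pp else "-",
                      maternal_effect = fmt_cell(effects$m, d),
                      pollen_effect = fmt_cell(effects$pollen_effect, d))
    p <- file.path(out_dir, "effects.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## Effect partitioning",
            sprintf("%d crosses; mean maternal effect %s, mean pollen effect %s.",
                    nrow(effects),
                    fmt_cell(group_mean_effects(effects$m), d),
                    fmt_cell(group_mean_effects(effects$pollen_effect), d)),
            "")
  } else md <- c(md, "## Effect partitioning", "No data.", "")

  if (!is.null(pathway)) {
    p <- file.path(out_dir, "pathway.tsv")
    write.table(as.data.frame(pathway$by_family), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## Pathway summary",
            sprintf("%d loci detected, %d expressed (%s%%), %d with a pollen-parent allele (totals exclude GTR).",
                    pathway$totals$n_detected, pathway$totals$n_expressed,
                    fmt_cell(pathway$totals$percent_expressed, 0),
                    pathway$totals$n_pollen_detected),
            "")
  } else md <- c(md, "## Pathway summary", "No data.", "")

  if (!is.null(stats)) {
    p <- file.path(out_dir, "ratio_stats.tsv")
    write.table(as.data.frame(stats), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, "## Pollen-allele ratio statistics",
            sprintf("%d ratios: min %s%%, max %s%%; %s%% inside [%g, %g].",
                    stats$n_values, fmt_cell(stats$min_ratio, 1),
                    fmt_cell(stats$max_ratio, 1),
                    fmt_cell(stats$band_percent, 0),
                    config$band_lo, config$band_hi),
            "")
  } else md <- c(md, "## Pollen-allele ratio statistics", "No data.", "")

  rp <- file.path(out_dir, "report.md")
  writeLines(md, rp)
  paths <- c(paths, rp)
  log_stage("render_report", "wrote %d files to %s", length(paths), out_dir)
  invisible(paths)
}

#' Parse a rendered effects table back
#'
#' Reads the `effects.tsv` written by [render_report()], converting `"-"`
#' cells back to `NA`. Round-trips effect values at report precision.
#'
#' @param path Path to an effects TSV.
#' @return A tibble with numeric `mp`, `f1_mean`, `f1_sd`,
#'   `maternal_effect`, `pollen_effect` and character star columns.
#' @export
parse_effects_report <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  tibble(cross_id = df$cross_id,
         mp = parse_cell(df$mp),
         f1_mean = parse_cell(df$f1_mean),
         f1_sd = parse_cell(df$f1_sd),
         sig_pm_vs_f1 = df$sig_pm_vs_f1,
         sig_pp_vs_f1 = df$sig_pp_vs_f1,
         maternal_effect = parse_cell(df$maternal_effect),
         pollen_effect = parse_cell(df$pollen_effect))
}
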