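#' @name io
#' @title Tab-separated readers and writers
#'
#' @description
#' All pipeline tables are plain UTF-8 TSV with fixed headers and "."
#' decimal separators; absent values are written as `"-"` and parsed back
#' to `NA`, never to 0. Every reader validates row-level invariants and
#' raises an error naming the first offending data row (1-based, header
#' excluded). Reader/writer pairs round-trip valid data exactly.
NULL

stop_row <- function(row, fmt, ...) {
  stop(sprintf("data row %d: %s", row, sprintf(fmt, ...)), call. = FALSE)
}

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read a per-seed rutin measurement table
#'
#' Expects columns `line`, `plant`, `seed`, `rutin_mg_per_g`. One row per
#' seed; `(line, plant, seed)` must be unique and rutin non-negative.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `line`, `plant_index`, `seed_index`,
#'   `rutin` (mg/g).
#' @seealso [write_rutin_table()]
#' @export
read_rutin_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("line", "plant", "seed", "rutin_mg_per_g"),
                "rutin table")
  n <- nrow(df)
  rutin <- suppressWarnings(as.numeric(df$rutin_mg_per_g))
  for (i in seq_len(n)) {
    if (is.na(df$line[i]) || !nzchar(df$line[i]))
      stop_row(i, "empty line identifier")
    if (is.na(rutin[i]))
      stop_row(i, "non-numeric rutin value %s", dQuote(df$rutin_mg_per_g[i]))
    if (rutin[i] < 0)
      stop_row(i, "negative rutin content %g", rutin[i])
    if (df$plant[i] < 1 || df$seed[i] < 1)
      stop_row(i, "plant and seed indices must be >= 1")
  }
  key <- paste(df$line, df$plant, df$seed, sep = "\r")
  if (anyDuplicated(key))
    stop_row(which(duplicated(key))[1], "duplicate (line, plant, seed) key")
  out <- tibble(line = as.character(df$line),
                plant_index = as.integer(df$plant),
                seed_index = as.integer(df$seed),
                rutin = rutin)
  log_stage("read_rutin_table", "%d records from %s", n, path)
  out
}

#' @rdname read_rutin_table
#' @param records Tibble as returned by [read_rutin_table()] or
#'   [simulate_rutin()].
#' @export
write_rutin_table <- function(records, path) {
  df <- data.frame(line = records$line,
                   plant = records$plant_index,
                   seed = records$seed_index,
                   rutin_mg_per_g = records$rutin)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-position nucleotide-count pileup table
#'
#' Expects columns `sample_id`, `cross_type` (`self_cross` or `outcross`),
#' `locus_id`, `pos` (1-based on the cDNA), `ref_base` (A/C/G/T) and
#' `count_A`..`count_T`. Rows are returned sorted by sample, locus and
#' position.
#'
#' @param path Path to a TSV file.
#' @return A tibble with those columns plus `depth` (= sum of the four
#'   counts).
#' @seealso [write_pileup_table()], [simulate_ase()]
#' @export
read_pileup_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c("sample_id", "cross_type", "locus_id", "pos", "ref_base",
            "count_A", "count_C", "count_G", "count_T")
  check_columns(df, cols, "pileup table")
  for (i in seq_len(nrow(df))) {
    if (!df$cross_type[i] %in% c("self_cross", "outcross"))
      stop_row(i, "cross_type %s is not self_cross/outcross",
               dQuote(df$cross_type[i]))
    if (!df$ref_base[i] %in% BASES)
      stop_row(i, "ref_base %s is not one of A,C,G,T", dQuote(df$ref_base[i]))
    if (is.na(df$pos[i]) || df$pos[i] < 1)
      stop_row(i, "position %s is not a 1-based coordinate",
               format(df$pos[i]))
    cts <- c(df$count_A[i], df$count_C[i], df$count_G[i], df$count_T[i])
    if (anyNA(cts) || any(cts < 0))
      stop_row(i, "nucleotide counts must be non-negative integers")
  }
  out <- tibble(sample_id = as.character(df$sample_id),
                cross_type = as.character(df$cross_type),
                locus_id = as.character(df$locus_id),
                pos = as.integer(df$pos),
                ref_base = as.character(df$ref_base),
                count_A = as.integer(df$count_A),
                count_C = as.integer(df$count_C),
                count_G = as.integer(df$count_G),
                count_T = as.integer(df$count_T))
  out <- dplyr::arrange(out, .data$sample_id, .data$locus_id, .data$pos)
  out$depth <- out$count_A + out$count_C + out$count_G + out$count_T
  log_stage("read_pileup_table", "%d pileup columns (%d samples) from %s",
            nrow(out), length(unique(out$sample_id)), path)
  out
}

#' @rdname read_pileup_table
#' @param pileup Tibble of pileup columns.
#' @export
write_pileup_table <- function(pileup, path) {
  cols <- c("sample_id", "cross_type", "locus_id", "pos", "ref_base",
            "count_A", "count_C", "count_G", "count_T")
  write.table(as.data.frame(pileup[cols]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference cDNA sequences from FASTA
#'
#' Sequences are uppercased; duplicate identifiers are an error and
#' characters outside A/C/G/T/N trigger a warning but are kept.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per locus.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA identifier %s",
                 dQuote(ids[duplicated(ids)][1])), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  odd <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(odd))
    warning(sprintf("non-ACGTN characters in %s (kept as-is)",
                    paste(ids[odd], collapse = ", ")), call. = FALSE)
  log_stage("read_fasta", "%d sequences from %s", length(seqs), path)
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read locus metadata
#'
#' Expects columns `locus_id`, `enzyme_family`, `length_bp` and optionally
#' `cds_start` (1-based start of the coding frame; `"-"` when unknown).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `locus_id`, `enzyme_family`, `length_bp`,
#'   `cds_start`.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  check_columns(df, c("locus_id", "enzyme_family", "length_bp"),
                "locus table")
  len <- suppressWarnings(as.integer(df$length_bp))
  cds <- if ("cds_start" %in% names(df)) parse_cell(df$cds_start)
         else rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!df$enzyme_family[i] %in% ENZYME_FAMILIES)
      stop_row(i, "unknown enzyme family %s", dQuote(df$enzyme_family[i]))
    if (is.na(len[i]) || len[i] <= 0)
      stop_row(i, "length_bp must be a positive integer")
    if (!is.na(cds[i]) && (cds[i] < 1 || cds[i] > len[i]))
      stop_row(i, "cds_start outside [1, length_bp]")
  }
  if (anyDuplicated(df$locus_id))
    stop_row(which(duplicated(df$locus_id))[1], "duplicate locus_id")
  tibble(locus_id = df$locus_id,
         enzyme_family = df$enzyme_family,
         length_bp = len,
         cds_start = as.integer(cds))
}

#' Read expression estimates
#'
#' Expects columns `sample_id`, `locus_id`, `est_count`,
#' `effective_length`. TPM is not stored in the file; it is computed by
#' [compute_tpm()].
#'
#' @param path Path to a TSV file.
#' @return A tibble with those four columns.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("sample_id", "locus_id", "est_count",
                      "effective_length"), "expression table")
  for (i in seq_len(nrow(df))) {
    if (is.na(df$est_count[i]) || df$est_count[i] < 0)
      stop_row(i, "negative or missing est_count")
    if (is.na(df$effective_length[i]) || df$effective_length[i] <= 0)
      stop_row(i, "effective_length must be > 0")
  }
  tibble(sample_id = as.character(df$sample_id),
         locus_id = as.character(df$locus_id),
         est_count = as.numeric(df$est_count),
         effective_length = as.numeric(df$effective_length))
}
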