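#' Round half away from zero
#'
#' Report-time rounding used throughout: ties round away from zero
#' (0.375 -> 0.38, -0.375 -> -0.38), unlike base [round()]'s banker's
#' rounding. Computations always run at full precision; this is applied
#' once, when a table is rendered.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_report(c(0.375, 0.5556, -0.375))
round_report <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Format numbers for report tables: NA -> "-", else fixed decimals.
fmt_cell <- function(x, digits = 2) {
  out <- ifelse(is.na(x), "-",
                formatC(round_report(x, digits), format = "f", digits = digits))
  as.character(out)
}

# Parse "-" back to NA, everything else to numeric.
parse_cell <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == "-"] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample-SD with the n-1 denominator; NA for n < 2.
sample_sd <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

BASES <- c("A", "C", "G", "T")

ENZYME_FAMILIES <- c("PAL", "C4H", "4CL", "CHS", "CHI",
                     "F3H", "F3pH", "F3p5pH", "FLS", "GTR")
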