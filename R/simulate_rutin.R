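#' Simulate per-seed rutin measurement tables
#'
#' Draws per-seed rutin contents for parent lines and, optionally, for F1
#' cross lots with a known maternal-effect truth. Each line contributes
#' `n_plants * n_seeds_per_plant` i.i.d. draws from
#' `Normal(rutin_mean, rutin_sd^2)` (an optional plant-level random effect
#' with SD `plant_sd` can be layered on top; default 0). An F1 lot for a
#' cross is drawn from `Normal(m * Pm_mean + (1 - m) * Pp_mean, sd_f1^2)`
#' and keyed by its `cross_id` in the `line` column.
#'
#' Rutin content cannot be negative; under the default
#' `truncation = "clip_resample"` negative draws are redrawn until
#' non-negative (left-truncated normal), which biases the realized mean
#' upward relative to `rutin_mean` when `rutin_sd` is large relative to
#' the mean — the realized shift is logged per line. `truncation = "none"`
#' keeps negative values (useful for exactness checks only).
#'
#' @param lines Tibble with `name`, `rutin_mean`, `rutin_sd`
#'   (e.g. [ref_parent_lines()]).
#' @param crosses Optional tibble with `cross_id`, `maternal`, `pollen`;
#'   both parents must appear in `lines`.
#' @param m_truth Named numeric vector of true maternal effects, one per
#'   `cross_id`; required when `crosses` is given. Values outside
#'   \[-0.5, 1.5\] are rejected as implausible truths.
#' @param n_plants,n_seeds_per_plant Field design (defaults 5 and 15:
#'   75 seeds per line).
#' @param sd_f1 SD of the F1 seed lots (single value or named per cross;
#'   default 0.25, of the order of the parental SDs).
#' @param truncation `"clip_resample"` (default) or `"none"`.
#' @param plant_sd SD of an optional shared per-plant offset (default 0:
#'   all seeds of a line i.i.d.).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A tibble of per-seed records (`line`, `plant_index`,
#'   `seed_index`, `rutin`) covering all lines then all crosses.
#' @export
#' @examples
#' simulate_rutin(ref_parent_lines()[1:2, ], seed = 1)
simulate_rutin <- function(lines, crosses = NULL, m_truth = NULL,
                           n_plants = 5, n_seeds_per_plant = 15,
                           sd_f1 = 0.25,
                           truncation = c("clip_resample", "none"),
                           plant_sd = 0, seed = NULL) {
  truncation <- match.arg(truncation)
  stopifnot(n_plants >= 1, n_seeds_per_plant >= 1, plant_sd >= 0,
            all(lines$rutin_mean >= 0), all(lines$rutin_sd >= 0))
  if (anyDuplicated(lines$name))
    stop("duplicate line name", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  specs <- tibble(name = lines$name, mean = lines$rutin_mean,
                  sd = lines$rutin_sd)
  if (!is.null(crosses)) {
    if (is.null(m_truth) || is.null(names(m_truth)))
      stop("crosses require a named m_truth vector", call. = FALSE)
    for (i in seq_len(nrow(crosses))) {
      cid <- crosses$cross_id[i]
      pm <- lines$rutin_mean[lines$name == crosses$maternal[i]]
      pp <- lines$rutin_mean[lines$name == crosses$pollen[i]]
      if (length(pm) != 1 || length(pp) != 1)
        stop(sprintf("cross %s: unknown parent line", cid), call. = FALSE)
      m <- if (cid %in% names(m_truth)) m_truth[[cid]] else NULL
      if (is.null(m) || is.na(m))
        stop(sprintf("cross %s: no m_truth entry", cid), call. = FALSE)
      if (m < -0.5 || m > 1.5)
        stop(sprintf("cross %s: m_truth %g outside [-0.5, 1.5]", cid, m),
             call. = FALSE)
      sdf <- if (length(sd_f1) > 1) sd_f1[[cid]] else sd_f1
      specs <- dplyr::bind_rows(
        specs, tibble(name = cid, mean = m * pm + (1 - m) * pp, sd = sdf))
    }
  }

  out <- lapply(seq_len(nrow(specs)), function(i) {
    n <- n_plants * n_seeds_per_plant
    shift <- rep(rnorm(n_plants, 0, plant_sd), each = n_seeds_per_plant)
    x <- rnorm(n, specs$mean[i], specs$sd[i]) + shift
    if (truncation == "clip_resample") {
      while (any(x < 0)) {
        neg <- which(x < 0)
        x[neg] <- rnorm(length(neg), specs$mean[i], specs$sd[i]) +
          shift[neg]
      }
      bias <- mean(x) - specs$mean[i]
      if (specs$sd[i] > 0)
        log_stage("simulate_rutin",
                  "%s: realized mean %.4f (spec %.2f, resampling shift %+.4f)",
                  specs$name[i], mean(x), specs$mean[i], bias)
    }
    tibble(line = specs$name[i],
           plant_index = rep(seq_len(n_plants), each = n_seeds_per_plant),
           seed_index = rep(seq_len(n_seeds_per_plant), times = n_plants),
           rutin = x)
  })
  dplyr::bind_rows(out)
}
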