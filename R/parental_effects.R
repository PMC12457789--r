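#' @name parental_effects
#' @title Partitioning maternal and pollen-parent effects on seed rutin
#'
#' @description
#' In an outcrossing crop, the trait value of an F1 seed lot can be
#' modelled as a mixture of the two parental line means,
#' `F1 = m * Pm + (1 - m) * Pp`, where `Pm` and `Pp` are the maternal and
#' pollen-parent mean rutin contents (mg/g) and `m` is the maternal
#' effect. Solving for `m` gives `m = (F1 - Pp) / (Pm - Pp)`; the pollen
#' parent (xenia) effect is its complement `1 - m`, and the mid-parent
#' value is `(Pm + Pp) / 2`. All quantities are computed from unrounded
#' group means and rounded only at report time.
NULL

#' Mid-parent value
#'
#' @param pm_mean,pp_mean Maternal and pollen-parent mean trait values.
#' @return `(pm_mean + pp_mean) / 2`.
#' @export
#' @examples
#' mid_parent_value(0.60, 0.18)  # 0.39
mid_parent_value <- function(pm_mean, pp_mean) {
  stopifnot(is.finite(pm_mean), is.finite(pp_mean))
  (pm_mean + pp_mean) / 2
}

#' Maternal effect value
#'
#' The mixture weight `m` solving `F1 = m * Pm + (1 - m) * Pp` for group
#' means. Deliberately not clamped to \[0, 1\]: sampling noise or
#' non-additive inheritance can push the estimate outside the interval and
#' the value is reported as computed.
#'
#' @param f1_mean F1 seed-lot mean.
#' @param pm_mean,pp_mean Parental line means; must differ.
#' @return The maternal effect `m` (dimensionless).
#' @export
#' @examples
#' maternal_effect(0.40, 0.60, 0.15)  # 0.5556
maternal_effect <- function(f1_mean, pm_mean, pp_mean) {
  stopifnot(is.finite(f1_mean), is.finite(pm_mean), is.finite(pp_mean))
  if (pm_mean == pp_mean)
    stop("maternal effect is undefined when parental means are equal",
         call. = FALSE)
  (f1_mean - pp_mean) / (pm_mean - pp_mean)
}

#' Pollen-parent effect value
#'
#' @param m Maternal effect.
#' @return `1 - m`, the xenia (pollen-parent) effect.
#' @export
pollen_effect <- function(m) {
  stopifnot(is.finite(m))
  1 - m
}

#' Star code for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05; otherwise the
#' p-value itself, printed to two decimals (matching report convention
#' for non-significant comparisons).
#'
#' @param p P-value in \[0, 1\].
#' @param digits Decimals used when printing a non-significant p.
#' @return Character scalar.
#' @export
star_code <- function(p, digits = 2) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else formatC(round_report(p, digits), format = "f", digits = digits)
}

#' Fisher's least significant difference test
#'
#' One-way ANOVA pooled error variance (`MSE`, `df = N - k`) followed by
#' unadjusted pairwise t comparisons:
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))`, two-sided p from
#' the t distribution on `N - k` degrees of freedom. With two groups of
#' equal size this reduces exactly to the pooled two-sample t-test. No
#' multiplicity adjustment is applied (that is the LSD procedure).
#'
#' Degenerate inputs (zero pooled variance) return p = 1 for equal means
#' and p = 0 otherwise, with a warning.
#'
#' @param groups Named list of numeric vectors, each with at least two
#'   values; at least two groups.
#' @return A tibble with one row per unordered pair: `group_i`, `group_j`,
#'   `diff`, `t`, `df`, `p`, `stars`.
#' @export
#' @examples
#' lsd_test(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
lsd_test <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) stop("every group needs >= 2 values", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  N <- sum(sizes); k <- length(groups)
  df <- N - k
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / df
  pairs <- utils::combn(names(groups), 2)
  res <- lapply(seq_len(ncol(pairs)), function(idx) {
    gi <- pairs[1, idx]; gj <- pairs[2, idx]
    d <- means[[gi]] - means[[gj]]
    if (mse == 0) {
      warning("zero pooled variance: degenerate LSD comparison",
              call. = FALSE)
      p <- if (d == 0) 1 else 0
      tval <- if (d == 0) 0 else Inf * sign(d)
    } else {
      tval <- d / sqrt(mse * (1 / sizes[[gi]] + 1 / sizes[[gj]]))
      p <- 2 * pt(-abs(tval), df)
    }
    tibble(group_i = gi, group_j = gj, diff = d, t = tval, df = df,
           p = p, stars = star_code(p))
  })
  dplyr::bind_rows(res)
}

#' Per-cross effect partitioning from per-seed measurements
#'
#' For each cross, computes the maternal, pollen and F1 group means from
#' per-seed rutin records (F1 seeds are keyed by `cross_id` in the `line`
#' column), derives the mid-parent value, maternal effect and pollen
#' effect, and runs the LSD test on the three groups of that cross's field
#' plot, reporting the maternal-vs-F1 and pollen-vs-F1 comparisons.
#' A cross whose parent or F1 measurements are missing is skipped with a
#' warning.
#'
#' @param measurements Tibble of per-seed records ([read_rutin_table()]
#'   layout: `line`, `plant_index`, `seed_index`, `rutin`).
#' @param crosses Tibble with `cross_id`, `maternal`, `pollen` (and
#'   optionally `plot_group`), e.g. [ref_crosses()].
#' @return A tibble with one row per cross: group means and SD, `mp`, `m`,
#'   `pollen_effect`, p-values and star codes for both comparisons, and
#'   `m_outside_01` flagging estimates outside \[0, 1\].
#' @export
compute_effects <- function(measurements, crosses) {
  stopifnot(all(c("cross_id", "maternal", "pollen") %in% names(crosses)))
  out <- lapply(seq_len(nrow(crosses)), function(i) {
    cid <- crosses$cross_id[i]
    pm <- measurements$rutin[measurements$line == crosses$maternal[i]]
    pp <- measurements$rutin[measurements$line == crosses$pollen[i]]
    f1 <- measurements$rutin[measurements$line == cid]
    if (length(pm) < 2 || length(pp) < 2 || length(f1) < 2) {
      warning(sprintf("cross %s: missing measurement group, skipped", cid),
              call. = FALSE)
      return(NULL)
    }
    m <- maternal_effect(mean(f1), mean(pm), mean(pp))
    lsd <- lsd_test(list(Pm = pm, F1 = f1, Pp = pp))
    p_pm <- lsd$p[lsd$group_i == "Pm" & lsd$group_j == "F1"]
    p_pp <- lsd$p[(lsd$group_i == "F1" & lsd$group_j == "Pp") |
                  (lsd$group_i == "Pp" & lsd$group_j == "F1")]
    tibble(cross_id = cid,
           pm_mean = mean(pm), pp_mean = mean(pp),
           f1_mean = mean(f1), f1_sd = sample_sd(f1),
           mp = mid_parent_value(mean(pm), mean(pp)),
           m = m, pollen_effect = pollen_effect(m),
           p_pm_vs_f1 = p_pm, p_pp_vs_f1 = p_pp,
           stars_pm = star_code(p_pm), stars_pp = star_code(p_pp),
           m_outside_01 = m < 0 | m > 1)
  })
  res <- dplyr::bind_rows(out)
  log_stage("compute_effects", "%d of %d crosses computed",
            nrow(res), nrow(crosses))
  res
}

#' Group average of effect values
#'
#' Arithmetic mean of per-cross effect values within a cross-direction
#' group (e.g. all crosses with the high-rutin line as maternal parent).
#'
#' @param effects Numeric vector of effect values (non-empty).
#' @return Their mean.
#' @export
#' @examples
#' group_mean_effects(c(0.35, 0.02, 0.14, 0.25))  # 0.19
group_mean_effects <- function(effects) {
  if (length(effects) == 0) stop("no effect values supplied", call. = FALSE)
  mean(effects)
}

#' Effect partitioning from published group means
#'
#' Desk-scale variant of [compute_effects()] for when only group means are
#' available (no per-seed data, hence no significance testing): computes
#' mid-parent value, maternal effect and pollen effect per cross from a
#' line table and a cross table carrying `f1_mean`.
#'
#' @param lines Tibble with `name`, `rutin_mean` ([ref_parent_lines()]).
#' @param crosses Tibble with `cross_id`, `maternal`, `pollen`, `f1_mean`
#'   ([ref_crosses()]).
#' @return A tibble with `cross_id`, `pm_mean`, `pp_mean`, `f1_mean`,
#'   `mp`, `m`, `pollen_effect`.
#' @export
effects_from_means <- function(lines, crosses) {
  pm <- lines$rutin_mean[match(crosses$maternal, lines$name)]
  pp <- lines$rutin_mean[match(crosses$pollen, lines$name)]
  if (anyNA(pm) || anyNA(pp))
    stop("cross references an unknown parent line", call. = FALSE)
  m <- mapply(maternal_effect, crosses$f1_mean, pm, pp)
  tibble(cross_id = crosses$cross_id,
         pm_mean = pm, pp_mean = pp, f1_mean = crosses$f1_mean,
         mp = mapply(mid_parent_value, pm, pp),
         m = m, pollen_effect = pollen_effect(m))
}
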