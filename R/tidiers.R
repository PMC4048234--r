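# broom-style tidiers for the package's result objects.

#' Tidy an islet score
#'
#' @param x An `islet_score` from [score_islet()].
#' @param ... Unused.
#' @return The one-row feature tibble (area score, stained fraction, islet
#'   size, cell counts, beta-cell density, thresholds).
#' @export
tidy.islet_score <- function(x, ...) x$features

#' @rdname tidy.islet_score
#' @export
glance.islet_score <- function(x, ...) {
  tibble(
    area_score = x$features$area_score,
    islet_size_px = x$features$islet_size_px,
    n_nuclei = x$features$n_nuclei,
    degenerate488 = x$map488$degenerate,
    degenerate555 = x$map555$degenerate
  )
}

#' Tidy a Pearson correlation
#'
#' @param x A `pearson_cor` from [pearson()].
#' @param ... Unused.
#' @return A one-row tibble: `r`, `r2`, `slope`, `intercept`, `p_value`, `n`.
#' @export
tidy.pearson_cor <- function(x, ...) {
  tibble(r = x$r, r2 = x$r2, slope = x$slope, intercept = x$intercept,
         p_value = x$p_value, n = x$n)
}

#' @rdname tidy.pearson_cor
#' @export
glance.pearson_cor <- function(x, ...) tidy.pearson_cor(x)

#' Tidy an unpaired t-test
#'
#' @param x A `ttest_result` from [ttest_unpaired()].
#' @param ... Unused.
#' @return A one-row tibble: `t`, `df`, `p_value`, group means and sizes.
#' @export
tidy.ttest_result <- function(x, ...) {
  tibble(t = x$t, df = x$df, p_value = x$p_value,
         mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.ttest_result
#' @export
glance.ttest_result <- function(x, ...) tidy.ttest_result(x)

#' Tidy an ANCOVA slope comparison
#'
#' @param x An `ancova_slopes` from [ancova_slopes()].
#' @param ... Unused.
#' @return A tibble with one row per group slope plus the interaction row.
#' @export
tidy.ancova_slopes <- function(x, ...) {
  tibble(
    term = c(paste0("slope_", names(x$slopes)), "slope_difference"),
    estimate = c(unname(x$slopes), x$slope_diff),
    statistic = c(NA_real_, NA_real_, x$interaction_t),
    p_value = c(NA_real_, NA_real_, x$interaction_p)
  )
}

#' @rdname tidy.ancova_slopes
#' @export
glance.ancova_slopes <- function(x, ...) {
  tibble(slope_diff = x$slope_diff, interaction_t = x$interaction_t,
         interaction_p = x$interaction_p, df = x$df)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
tidy.cohort_summary <- function(x, ...) x$groups

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n_patients = sum(x$groups$n_patients), total_islets = x$total_islets)
}
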