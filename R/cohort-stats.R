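# Cohort-level statistics: per-patient median aggregation, Pearson
# correlation with two-tailed p, the classic equal-variance unpaired t-test,
# ANCOVA slope comparison via a group x covariate interaction, and the
# clinical-table summary. The test statistics are computed in closed form
# from their defining formulas; no multiple-testing correction is applied
# (p < 0.05 is the significance convention throughout).

#' Aggregate per-islet features to per-patient medians
#'
#' The patient-level quantity of interest is the median over that patient's
#' islets (with an even number of islets, the mean of the two middle values).
#'
#' @param features Data frame with one row per islet. Must contain
#'   `patient_id` and `area_score`; `marker`, `islet_size_px` and
#'   `beta_density_per_1e4px` are used when present.
#' @return A tibble with one row per patient (and per marker when a `marker`
#'   column is present): `median_area_score`, `median_islet_size`,
#'   `median_beta_density` and `n_islets`.
#' @export
aggregate_patients <- function(features) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop_parameter("`features` must be a data frame with at least one row")
  }
  if (!all(c("patient_id", "area_score") %in% names(features))) {
    stop_format("`features` needs columns `patient_id` and `area_score`")
  }
  keys <- intersect(c("patient_id", "marker", "group"), names(features))
  med_or_na <- function(x) if (is.null(x)) NA_real_ else median(x)
  features %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      median_area_score = median(.data$area_score),
      median_islet_size = if ("islet_size_px" %in% names(features))
        median(.data$islet_size_px) else NA_real_,
      median_beta_density = if ("beta_density_per_1e4px" %in% names(features))
        median(.data$beta_density_per_1e4px) else NA_real_,
      n_islets = dplyr::n(),
      .groups = "drop"
    )
}

#' Pearson correlation with least-squares fit
#'
#' Computes the Pearson correlation coefficient, its square, the
#' least-squares slope and intercept, and the two-tailed p-value from the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points, neither
#'   constant.
#' @return An object of class `pearson_cor`: `r`, `r2`, `p_value`, `n`,
#'   `slope`, `intercept`, plus the data for plotting.
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_parameter("`x` and `y` must be numeric vectors of equal length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_parameter("need at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) {
    abort("correlation is undefined for constant input",
          class = "isletscore_error_degenerate")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- r * r
  p <- if (r2 >= 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r2))), df = n - 2)
  structure(
    list(r = r, r2 = r2, p_value = p, n = n, slope = slope,
         intercept = intercept, data = tibble(x = x, y = y)),
    class = "pearson_cor"
  )
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("<pearson_cor> r^2 = %.4f (r = %.4f), slope = %.4g, n = %d, two-tailed p = %.3g\n",
              x$r2, x$r, x$slope, x$n, x$p_value))
  invisible(x)
}

#' Unpaired two-tailed Student's t-test
#'
#' Classic equal-variance form by default, matching the convention that
#' differences between group means are assessed with an unpaired two-tailed
#' Student's t-test at the 95% confidence level. `var_equal = FALSE` gives
#' the Welch form.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param var_equal Pool the variance (default) or use the Welch correction.
#' @return An object of class `ttest_result`: `t`, `p_value`, `df`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_parameter("both groups need at least 2 finite observations")
  }
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) {
      abort("pooled variance is zero: t statistic undefined",
            class = "isletscore_error_degenerate")
    }
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va + vb <= 0) {
      abort("both group variances are zero: t statistic undefined",
            class = "isletscore_error_degenerate")
    }
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  structure(
    list(t = t, p_value = 2 * pt(-abs(t), df = df), df = df,
         mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
         var_equal = var_equal),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t = %.4f (df = %.4g), two-tailed p = %.3g; means %.4g vs %.4g\n",
              x$t, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Compare regression slopes between two groups (ANCOVA interaction)
#'
#' Fits one ordinary-least-squares model with group-specific intercepts and
#' slopes, `y ~ group + x + group:x`. The per-group slope estimates equal the
#' within-group least-squares slopes, and the two-tailed t-test on the
#' interaction coefficient asks whether the two slopes differ — e.g. whether
#' the marker-vs-BMI regressions of ND and T2D patients diverge.
#'
#' @param x Numeric covariate (e.g. BMI).
#' @param y Numeric response (e.g. median area score).
#' @param group Two-level grouping vector aligned with `x` and `y`.
#' @return An object of class `ancova_slopes`: `slopes` (named per group),
#'   `slope_diff`, `interaction_t`, `interaction_p`, `df`, plus the data.
#' @export
ancova_slopes <- function(x, y, group) {
  if (length(x) != length(y) || length(x) != length(group)) {
    stop_parameter("`x`, `y` and `group` must have equal length")
  }
  keep <- is.finite(x) & is.finite(y) & !is.na(group)
  x <- x[keep]; y <- y[keep]; group <- as.character(group)[keep]
  levels <- sort(unique(group))
  if (length(levels) != 2L) {
    stop_parameter(sprintf("`group` must have exactly 2 levels, got %d", length(levels)))
  }
  for (lv in levels) {
    xs <- x[group == lv]
    if (length(xs) < 3L) stop_parameter(sprintf("group `%s` needs at least 3 points", lv))
    if (sum((xs - mean(xs))^2) == 0) {
      stop_parameter(sprintf("covariate is constant within group `%s`", lv))
    }
  }
  g <- as.numeric(group == levels[2])
  X <- cbind(1, g, x, g * x)
  fit <- qr(X)
  beta <- qr.coef(fit, y)
  res <- y - X %*% beta
  df <- length(y) - 4L
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(fit))
  se_int <- sqrt(s2 * XtX_inv[4, 4])
  t_int <- beta[4] / se_int
  p_int <- 2 * pt(-abs(t_int), df = df)
  slopes <- c(beta[3], beta[3] + beta[4])
  names(slopes) <- levels
  structure(
    list(slopes = slopes, slope_diff = unname(beta[4]),
         interaction_t = unname(t_int), interaction_p = unname(p_int),
         df = df, intercepts = setNames(c(beta[1], beta[1] + beta[2]), levels),
         data = tibble(x = x, y = y, group = group)),
    class = "ancova_slopes"
  )
}

#' @export
print.ancova_slopes <- function(x, ...) {
  cat(sprintf(
    "<ancova_slopes> slope[%s] = %.4g, slope[%s] = %.4g; interaction t = %.4f (df = %d), p = %.3g\n",
    names(x$slopes)[1], x$slopes[1], names(x$slopes)[2], x$slopes[2],
    x$interaction_t, x$df, x$interaction_p
  ))
  invisible(x)
}

#' Summarise a cohort table
#'
#' Reproduces the clinical-characteristics style summary: per-group patient
#' counts, mean and sample standard deviation of age and BMI, per-marker and
#' overall totals of pictured islets, mean islets per patient, and per-group
#' counts by tissue source.
#'
#' @param records A cohort tibble from [load_cohort_table()].
#' @return An object of class `cohort_summary` with tibbles `groups`,
#'   `markers`, `sources` and the scalar `total_islets`.
#' @examples
#' cohort <- load_cohort_table(
#'   system.file("extdata", "cohort_table1.csv", package = "isletscore")
#' )
#' summarize_cohort(cohort)
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_parameter("`records` must be a non-empty data frame")
  }
  groups <- records %>%
    group_by(.data$group) %>%
    summarise(
      n_patients = dplyr::n(),
      mean_age = mean(.data$age), sd_age = sd(.data$age),
      mean_bmi = mean(.data$bmi), sd_bmi = sd(.data$bmi),
      .groups = "drop"
    )
  marker_cols <- c(tmem27 = "n_islets_tmem27", bace2 = "n_islets_bace2",
                   insulin = "n_islets_insulin")
  markers <- tibble(
    marker = names(marker_cols),
    total_islets = unname(vapply(marker_cols, function(cl) sum(records[[cl]]), numeric(1))),
    mean_islets_per_patient = unname(vapply(marker_cols, function(cl) mean(records[[cl]]), numeric(1)))
  )
  sources <- records %>% count(.data$group, .data$source, name = "n_patients")
  structure(
    list(groups = groups, markers = markers, sources = sources,
         total_islets = sum(markers$total_islets)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients, %d islets pictured in total\n",
              sum(x$groups$n_patients), x$total_islets))
  print(x$groups)
  print(x$markers)
  invisible(x)
}

#' Group comparison and BMI regressions for a scored cohort
#'
#' Convenience wrapper around the statistics layer: aggregates per-islet
#' features to patient medians, compares the two groups with the unpaired
#' t-test, and regresses the patient medians on BMI within each group with
#' the ANCOVA slope comparison.
#'
#' @param features Per-islet feature tibble with `patient_id` and
#'   `area_score` columns (and optionally `marker`).
#' @param cohort Cohort tibble with `patient_id`, `group` and `bmi` columns,
#'   or a synthetic cohort feature tibble already carrying `group` and `bmi`.
#' @return A list per marker with elements `aggregates`, `ttest` and
#'   `ancova` (the latter `NULL` when BMI is unavailable).
#' @export
cohort_report <- function(features, cohort = NULL) {
  agg <- aggregate_patients(features)
  if (is.null(cohort)) {
    if (!"group" %in% names(agg)) {
      stop_format("`features` lacks a `group` column and no `cohort` was given")
    }
    meta <- dplyr::distinct(features[intersect(c("patient_id", "bmi"), names(features))])
  } else {
    missing_ids <- setdiff(unique(agg$patient_id), cohort$patient_id)
    if (length(missing_ids)) {
      stop_validation(sprintf("patient id(s) absent from cohort table: %s",
                              paste(missing_ids, collapse = ", ")))
    }
    agg <- agg[setdiff(names(agg), c("group", "bmi"))]
    meta <- dplyr::distinct(cohort[intersect(c("patient_id", "group", "bmi"),
                                             names(cohort))])
  }
  agg <- left_join(agg, meta[setdiff(names(meta), setdiff(names(agg), "patient_id"))],
                   by = "patient_id")
  markers <- if ("marker" %in% names(agg)) unique(agg$marker) else NA_character_
  out <- lapply(markers, function(mk) {
    sub <- if (is.na(mk)) agg else filter(agg, .data$marker == mk)
    nd <- sub$median_area_score[sub$group == "ND"]
    t2d <- sub$median_area_score[sub$group == "T2D"]
    tt <- if (length(nd) >= 2 && length(t2d) >= 2) ttest_unpaired(nd, t2d) else NULL
    anc <- if ("bmi" %in% names(sub) &&
               all(table(sub$group) >= 3) && length(unique(sub$group)) == 2) {
      tryCatch(ancova_slopes(sub$bmi, sub$median_area_score, sub$group),
               error = function(e) NULL)
    } else NULL
    list(marker = mk, aggregates = sub, ttest = tt, ancova = anc)
  })
  names(out) <- ifelse(is.na(markers), "all", markers)
  out
}
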