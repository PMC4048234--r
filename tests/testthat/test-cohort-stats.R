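test_that("patient aggregation uses the mean-of-middle-two median convention", {
  f <- tibble::tibble(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    area_score = c(1, 2, 3, 1, 2, 2.4)
  )
  agg <- aggregate_patients(f)
  expect_equal(agg$median_area_score[agg$patient_id == "A"], 2)
  expect_equal(agg$median_area_score[agg$patient_id == "B"], 1.5)
  expect_equal(agg$median_area_score[agg$patient_id == "C"], 2.4)
  expect_equal(agg$n_islets, c(3L, 2L, 1L))
  expect_error(aggregate_patients(f[0, ]), class = "isletscore_error_parameter")

  # permutation invariance and boundedness
  set.seed(1)
  x <- runif(11)
  f2 <- tibble::tibble(patient_id = "P", area_score = x)
  f3 <- tibble::tibble(patient_id = "P", area_score = sample(x))
  expect_equal(aggregate_patients(f2)$median_area_score,
               aggregate_patients(f3)$median_area_score)
  expect_gte(aggregate_patients(f2)$median_area_score, min(x))
  expect_lte(aggregate_patients(f2)$median_area_score, max(x))
})

test_that("pearson matches exact cases and the reference implementation", {
  p <- pearson(c(1, 2, 3), c(2, 4, 6))
  expect_equal(p$r2, 1)
  expect_equal(p$slope, 2)
  q <- pearson(c(1, 2, 3), c(3, 2, 1))
  expect_equal(q$r2, 1)
  expect_equal(q$slope, -1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "isletscore_error_degenerate")

  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    ours <- pearson(x, y)
    ref <- stats::cor.test(x, y)
    fit <- stats::lm(y ~ x)
    expect_equal(ours$r2, unname(ref$estimate)^2, tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(ours$slope, unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(ours$intercept, unname(coef(fit)[1]), tolerance = 1e-8)
  }

  # r^2 is invariant under affine transforms with nonzero scale
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson(x, y)$r2
  expect_equal(pearson(3.2 * x - 7, y)$r2, base, tolerance = 1e-10)
  expect_equal(pearson(x, -0.5 * y + 2)$r2, base, tolerance = 1e-10)
})

test_that("the unpaired t-test matches the reference and is symmetric", {
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(ttest_unpaired(c(1, 1, 1), c(1, 1)),
               class = "isletscore_error_degenerate")

  set.seed(55)
  for (i in 1:5) {
    a <- rnorm(12, 1); b <- rnorm(15)
    ours <- ttest_unpaired(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
    flipped <- ttest_unpaired(b, a)
    expect_equal(flipped$t, -ours$t)
    expect_equal(flipped$p_value, ours$p_value)
    welch <- ttest_unpaired(a, b, var_equal = FALSE)
    refw <- stats::t.test(a, b)
    expect_equal(welch$p_value, refw$p.value, tolerance = 1e-8)
  }
})

test_that("ANCOVA slopes equal within-group fits and match the lm oracle", {
  x <- c(1:6, 1:6)
  g <- rep(c("ND", "T2D"), each = 6)
  y <- ifelse(g == "ND", 2 + 0.5 * x, 2 - 0.5 * x)
  a <- ancova_slopes(x, y, g)
  expect_equal(unname(a$slopes), c(0.5, -0.5))

  y2 <- 1 + 0.3 * x + (g == "T2D") * 2 # same slope, shifted intercept
  a2 <- ancova_slopes(x, y2, g)
  expect_equal(a2$slope_diff, 0, tolerance = 1e-12)

  set.seed(77)
  x <- rnorm(40, 27, 4)
  g <- rep(c("ND", "T2D"), each = 20)
  y <- 1 + 0.05 * x - 0.08 * x * (g == "T2D") + rnorm(40, 0, 0.3)
  ours <- ancova_slopes(x, y, g)
  fit <- stats::lm(y ~ g + x + g:x)
  sm <- summary(fit)$coefficients
  expect_equal(ours$slope_diff, unname(coef(fit)["gT2D:x"]), tolerance = 1e-8)
  expect_equal(ours$interaction_p, sm["gT2D:x", "Pr(>|t|)"], tolerance = 1e-8)
  # per-group slopes equal the within-group least-squares slopes
  expect_equal(unname(ours$slopes["ND"]),
               pearson(x[g == "ND"], y[g == "ND"])$slope, tolerance = 1e-10)
  expect_equal(unname(ours$slopes["T2D"]),
               pearson(x[g == "T2D"], y[g == "T2D"])$slope, tolerance = 1e-10)
  expect_error(ancova_slopes(x, y, rep("ND", 40)),
               class = "isletscore_error_parameter")
})

test_that("cohort summary reproduces the printed clinical characteristics", {
  cohort <- load_cohort_table(table1_path())
  s <- summarize_cohort(cohort)
  expect_equal(s$total_islets, 1974)
  expect_equal(s$markers$total_islets[s$markers$marker == "tmem27"], 528)
  expect_equal(s$markers$total_islets[s$markers$marker == "bace2"], 541)
  expect_equal(s$markers$total_islets[s$markers$marker == "insulin"], 905)
  nd <- s$groups[s$groups$group == "ND", ]
  expect_equal(round(nd$mean_bmi), 26)
  expect_equal(round(nd$mean_age), 66)
  expect_equal(round(nd$sd_age), 14)
  t2d_autopsy <- s$sources$n_patients[s$sources$group == "T2D" &
                                        s$sources$source == "Autopsy"]
  expect_equal(t2d_autopsy, 18L)
  # group patient counts equal the sum over sources within the group
  by_src <- tapply(s$sources$n_patients, s$sources$group, sum)
  expect_equal(as.vector(by_src[s$groups$group]), s$groups$n_patients)

  # totals are linear: summing split summaries reproduces the full totals
  s1 <- summarize_cohort(cohort[1:25, ])
  s2 <- summarize_cohort(cohort[26:60, ])
  expect_equal(s1$total_islets + s2$total_islets, s$total_islets)
  expect_equal(s1$markers$total_islets + s2$markers$total_islets,
               s$markers$total_islets)
})

test_that("cohort_report joins features to metadata and flags unknown ids", {
  coh <- generate_cohort(n_nd = 6, n_t2d = 6, islets_per_patient = 5,
                         effect = 1.0, noise = 0.2, seed = 9)
  rep <- cohort_report(coh$features)
  expect_named(rep, "all")
  expect_s3_class(rep$all$ttest, "ttest_result")
  expect_lt(rep$all$ttest$p_value, 0.05)
  expect_s3_class(rep$all$ancova, "ancova_slopes")

  cohort <- load_cohort_table(table1_path())
  f <- tibble::tibble(patient_id = c("ND01", "NOPE"), area_score = c(1, 2))
  expect_error(cohort_report(f, cohort), regexp = "NOPE",
               class = "isletscore_error_validation")
})

test_that("tidiers return one-row summaries for the result objects", {
  p <- pearson(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
  expect_named(tidy(p), c("r", "r2", "slope", "intercept", "p_value", "n"))
  t <- ttest_unpaired(rnorm(5), rnorm(5))
  expect_equal(nrow(tidy(t)), 1L)
  cohort <- load_cohort_table(table1_path())
  g <- glance(summarize_cohort(cohort))
  expect_equal(g$n_patients, 60L)
  expect_equal(g$total_islets, 1974)
})
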