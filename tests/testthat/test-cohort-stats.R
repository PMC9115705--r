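make_reg_cohort <- function(x, y, variant = "adjusted") {
  df <- data.frame(mvo2_ml_min = x)
  df[[paste0("tpo_", variant, "_j_min")]] <- y
  df[[paste0("efficiency_", variant)]] <- y
  df
}

test_that("regression recovers exact linear relationships", {
  x <- 1:5
  r <- suppressWarnings(fit_power_oxygen_regression(make_reg_cohort(x, 2 * x)))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_power_oxygen_regression(make_reg_cohort(rep(2, 5), 1:5)),
               "degenerate")
  expect_error(fit_power_oxygen_regression(make_reg_cohort(1:2, 1:2)),
               "at least 3")
})

test_that("regression matches the normal-equations oracle on a fixture", {
  x <- c(2.1, 3.7, 4.4, 5.9, 7.2, 8.8)
  y <- c(49.3, 80.1, 95.0, 122.7, 150.2, 171.9)
  r <- fit_power_oxygen_regression(make_reg_cohort(x, y))
  o <- ols_oracle(x, y)
  expect_equal(r$slope, o$slope, tolerance = 1e-10)
  expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(r$r_squared, o$r_squared, tolerance = 1e-10)
  tcrit <- qt(0.975, length(x) - 2)
  expect_equal(unname(r$slope_ci95),
               o$slope + c(-1, 1) * tcrit * o$slope_se, tolerance = 1e-10)
  expect_equal(unname(r$intercept_ci95),
               o$intercept + c(-1, 1) * tcrit * o$intercept_se,
               tolerance = 1e-10)
  # CIs contain their point estimates
  expect_true(r$slope_ci95[1] <= r$slope && r$slope <= r$slope_ci95[2])
  # R^2 equals the squared Pearson correlation (simple-regression identity)
  expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-12)
})

test_that("efficiency correlation detects perfect anti-correlation", {
  x <- c(2, 4, 6, 8, 10)
  df <- data.frame(mvo2_ml_min = x, efficiency_adjusted = 0.9 - 0.05 * x)
  r <- suppressWarnings(efficiency_oxygen_correlation(df))
  expect_equal(r$slope, -0.05, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  o <- ols_oracle(x, df$efficiency_adjusted)
  expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
})

test_that("power fractions summarise by pooled severity class", {
  coh <- data.frame(
    group = c("NYHA_II", "NYHA_II", "NYHA_III", "NYHA_IV"),
    iso_adjusted_j_min = c(50, 60, 80, 90),
    useful_stroke_j_min = c(40, 30, 15, 8),
    tpo_adjusted_j_min = c(100, 100, 100, 100)
  )
  s <- power_fraction_summary(coh, "adjusted")
  expect_setequal(unique(s$group), c("NYHA_II", "NYHA_III_IV"))
  iso_ii <- s[s$group == "NYHA_II" & s$component == "isovolumic", ]
  # spreadsheet-style oracle: mean(50, 60) = 55, SEM = sd/sqrt(2) = 5/sqrt(2)
  expect_equal(iso_ii$mean_percent, 55)
  expect_equal(iso_ii$sem_percent, sd(c(50, 60)) / sqrt(2))
  iso_hi <- s[s$group == "NYHA_III_IV" & s$component == "isovolumic", ]
  expect_equal(iso_hi$mean_percent, 85)
  # closure: per-group component means total 100%
  for (g in unique(s$group)) {
    expect_equal(sum(s$mean_percent[s$group == g]), 100, tolerance = 1e-9)
  }
  # single-record group reports SEM as missing
  s1 <- power_fraction_summary(coh[c(1, 3), ], "adjusted")
  expect_true(all(is.na(s1$sem_percent)))
})

test_that("every NYHA III or IV record lands in exactly one pooled group", {
  coh <- generate_clinical_cohort(cohort_spec(), seed = 2)
  s <- power_fraction_summary(coh, "adjusted")
  n_ii <- unique(s$n[s$group == "NYHA_II"])
  n_hi <- unique(s$n[s$group == "NYHA_III_IV"])
  expect_equal(n_ii + n_hi, nrow(coh))
  expect_equal(n_hi, sum(coh$group %in% c("NYHA_III", "NYHA_IV")))
})

test_that("MANOVA separates groups and degenerates sensibly", {
  # identical group means on all three variables: statistic ~ 0
  base <- data.frame(
    group = rep(c("NYHA_II", "NYHA_III"), each = 4),
    efficiency_elbeery = rep(c(0.3, 0.4, 0.35, 0.25), 2),
    efficiency_adjusted = rep(c(0.5, 0.45, 0.40, 0.55), 2),
    mvo2_ml_min = rep(c(4, 5, 4.5, 5.5), 2))
  m0 <- class_comparison_manova(base)
  expect_lt(m0$value, 1e-10)
  # well-separated groups are detected with high power
  set.seed(9)
  hits <- replicate(60, {
    d <- data.frame(
      group = rep(c("NYHA_II", "NYHA_IV"), each = 6),
      efficiency_elbeery = c(rnorm(6, 0.40, 0.05), rnorm(6, 0.20, 0.05)),
      efficiency_adjusted = c(rnorm(6, 0.50, 0.05), rnorm(6, 0.30, 0.05)),
      mvo2_ml_min = c(rnorm(6, 4, 0.5), rnorm(6, 7, 0.5)))
    class_comparison_manova(d)$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
  expect_error(class_comparison_manova(base[base$group == "NYHA_II", ]),
               "two severity strata")
})

test_that("Wilks and Pillai agree for the two-group case", {
  coh <- manova_fixture()
  p <- class_comparison_manova(coh, "Pillai")
  w <- class_comparison_manova(coh, "Wilks")
  # with one between-group df both statistics give the same F and p
  expect_equal(p$p_value, w$p_value, tolerance = 1e-9)
  expect_equal(nrow(p$post_hoc), 3)
  expect_true(all(p$post_hoc$p_bonferroni >= p$post_hoc$p_raw))
  expect_true(all(p$post_hoc$p_bonferroni <= 1))
})

test_that("validate_cohort assembles the full battery", {
  coh <- generate_clinical_cohort(cohort_spec(), seed = 4)
  v <- validate_cohort(coh)
  expect_s3_class(v$regression$adjusted, "rv_regression")
  expect_s3_class(v$efficiency$elbeery, "rv_regression")
  expect_s3_class(v$manova, "rv_manova")
  expect_equal(v$regression$adjusted$n, nrow(coh))
  expect_output(print(v), "Power output vs oxygen")
})
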