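test_that("Shapiro-Wilk wrapper retains size and power", {
  withr::with_seed(500, {
    null_p <- replicate(500, shapiro_wilk(rnorm(32))$p_value)
    skew_p <- replicate(500, shapiro_wilk(exp(rnorm(32, 0, 1.5)))$p_value)
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  expect_gte(mean(skew_p < 0.05), 0.90)
  expect_error(shapiro_wilk(rep(1, 30)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("paired comparison routes by normality of the differences", {
  withr::with_seed(17, {
    pre <- rnorm(32, 10, 2)
    post_norm <- pre + 1 + rnorm(32, 0, 0.5)
    res <- paired_compare(pre, post_norm)
    expect_equal(res$test_used, "paired_t")
    expect_gt(res$normality_p, 0.05)

    post_skew <- pre + exp(rnorm(32, 0, 1.5))
    res2 <- paired_compare(pre, post_skew)
    expect_equal(res2$test_used, "wilcoxon_signed_rank")
    expect_lt(res2$normality_p, 0.05)
  })
  expect_error(paired_compare(1:5, 1:5), "zero")
  expect_error(paired_compare(1:2, 1:2 + 0.5), "n >= 3")
  expect_error(paired_compare(1:5, 1:4), "equal length")
})

test_that("swapping pre and post flips the statistic but not the p value", {
  withr::with_seed(23, {
    pre <- rnorm(20)
    post <- pre + 0.8 + rnorm(20, 0, 0.6)
  })
  a <- paired_compare(pre, post, force = "paired_t")
  b <- paired_compare(post, pre, force = "paired_t")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, -b$statistic)
  aw <- paired_compare(pre, post, force = "wilcoxon_signed_rank")
  bw <- paired_compare(post, pre, force = "wilcoxon_signed_rank")
  expect_equal(aw$p_value, bw$p_value)
})

test_that("both routes agree on rejection for large effects", {
  withr::with_seed(61, {
    agree <- replicate(100, {
      pre <- rnorm(32, 0.43, 0.11)
      post <- pre - 0.14 + rnorm(32, 0, 0.05)
      pt <- paired_compare(pre, post, force = "paired_t")$p_value
      pw <- paired_compare(pre, post, force = "wilcoxon_signed_rank")$p_value
      (pt <= 0.05) == (pw <= 0.05)
    })
  })
  expect_gte(mean(agree), 0.90)
})

test_that("chi-squared on 2x2 tables matches reference values", {
  expect_lt(chi_squared_2x2(20, 12, 5, 27)$p_value, 0.001)
  expect_equal(round(chi_squared_2x2(10, 22, 4, 28)$p_value, 2), 0.13)
  expect_equal(round(chi_squared_2x2(10, 22, 6, 26)$p_value, 1), 0.4)
  even <- chi_squared_2x2(10, 10, 10, 10)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_error(chi_squared_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_squared_2x2(-1, 2, 3, 4), ">= 0")
})

test_that("continuity correction never makes a table more significant", {
  withr::with_seed(71, {
    for (i in 1:100) {
      tab <- as.vector(stats::rmultinom(1, size = 60, prob = runif(4)))
      if (any(rowSums(matrix(tab, 2, byrow = TRUE)) == 0) ||
          any(colSums(matrix(tab, 2, byrow = TRUE)) == 0)) next
      p_corr <- chi_squared_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
      p_raw <- chi_squared_2x2(tab[1], tab[2], tab[3], tab[4],
                               continuity_correction = FALSE)$p_value
      expect_gte(p_corr, p_raw - 1e-12)
    }
  })
})

test_that("cohort summary reports all variable groups with routed tests", {
  cohort <- generate_cohort(cohort_config(n_subjects = 32, seed = 5),
                            curves = FALSE)
  smry <- summarize_cohort(cohort$records)
  vars <- cohort_variable_defaults()
  dich <- attr(vars, "dichotomous")
  expect_equal(nrow(smry), nrow(vars) + nrow(dich))
  expect_true(all(smry$type[smry$variable %in% c("age_y", "male", "smoker")]
                  == "demographic"))
  cont <- smry[smry$type == "continuous", ]
  expect_true(all(cont$test_used %in% c("paired_t", "wilcoxon_signed_rank")))
  expect_true(all(cont$p_value >= 0 & cont$p_value <= 1))
  expect_true(all(smry$test_used[smry$type == "dichotomous"] == "chi_squared"))
  # groups are ordered demographics -> clinical -> clot panel
  expect_equal(rle(as.character(smry$group))$values,
               c("demographic", "table1", "fig2b"))
})

test_that("cohort summary is invariant to record order and flags degenerate data", {
  cohort <- generate_cohort(cohort_config(n_subjects = 16, seed = 9),
                            curves = FALSE)
  smry1 <- summarize_cohort(cohort$records)
  shuffled <- cohort$records[sample(nrow(cohort$records)), ]
  smry2 <- summarize_cohort(shuffled)
  expect_equal(smry1, smry2)

  vars <- cohort_variable_defaults()
  vars$pre_sd <- 0; vars$post_sd <- 0
  degen <- generate_cohort(cohort_config(n_subjects = 5, variables = vars,
                                         seed = 2), curves = FALSE)
  smry3 <- summarize_cohort(degen$records)
  cont3 <- smry3[smry3$type == "continuous", ]
  expect_true(all(cont3$pre_sd == 0))
  expect_true(all(cont3$test_used == "error"))
})

test_that("subjects missing a period are excluded with a warning", {
  cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 3),
                            curves = FALSE)
  records <- cohort$records[-1, ]  # drop one pre record
  expect_warning(smry <- summarize_cohort(records), "without both periods")
  expect_true(all(smry$n == 5))
})

test_that("cohort summary means converge to the configured population", {
  cohort <- generate_cohort(cohort_config(n_subjects = 2000, seed = 777),
                            curves = FALSE)
  smry <- summarize_cohort(cohort$records)
  vars <- cohort_variable_defaults()
  for (v in c("weight_kg", "max_abs", "lysis_area")) {
    row <- vars[vars$variable == v, ]
    got <- smry[smry$variable == v, ]
    expect_lt(abs(got$pre_mean - row$pre_mean), 3 * row$pre_sd / sqrt(2000))
    expect_lt(abs(got$post_mean - row$post_mean), 3 * row$post_sd / sqrt(2000))
  }
})

test_that("attrition accounting reproduces funnel rates", {
  rep1 <- attrition_report(119, 63, 16, 15)
  expect_equal(round(rep1$rate_pct[rep1$stage == "recruitment"], 2), 52.94)
  expect_equal(round(rep1$rate_pct[rep1$stage == "postoperative_exclusion"]), 25)
  expect_equal(round(rep1$rate_pct[rep1$stage == "followup_attrition"]), 32)
  expect_equal(rep1$n_entered[rep1$stage == "analyzed"], 32)

  rep2 <- attrition_report(100, 100, 0, 0)
  expect_equal(rep2$rate_pct[1:3], c(100, 0, 0))
  expect_error(attrition_report(10, 20, 0, 0), "exceed")
  expect_error(attrition_report(100, 50, 60, 0), "exceed")
  expect_error(attrition_report(-1, 0, 0, 0), ">= 0")
})
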