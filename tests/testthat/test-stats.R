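test_that("paired t test matches the closed-form statistic", {
  res <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$statistic, -2 / (1 / sqrt(3)), tolerance = 1e-4) # -3.4641
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t_test(1:3, 1:4), "length mismatch")
  expect_error(paired_t_test(1, 2), "at least 2")

  # sign flip of the roles negates t and preserves p
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10)
  a <- paired_t_test(x, y); b <- paired_t_test(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("paired t equals the one-sample t on the differences", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- paired_t_test(x, y)
    oracle <- one_sample_t_oracle(x - y)
    expect_equal(res$statistic, oracle$t, tolerance = 1e-12)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("unpaired t uses the pooled (Student) variance", {
  res <- unpaired_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(res$statistic, -2.1909, tolerance = 1e-4)
  expect_equal(res$df, 6)
  expect_equal(res$p_value, 2 * pt(-2.19089, 6), tolerance = 1e-4)
  expect_equal(res$n, c(4, 4))

  ident <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  expect_error(unpaired_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero variance")
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")

  welch <- unpaired_t_test(c(1, 2, 3, 4), c(3, 4, 5, 60), welch = TRUE)
  expect_lt(welch$df, 6) # Welch-Satterthwaite df shrinks under heteroscedasticity
})

test_that("one-way ANOVA matches the hand-computed F", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$statistic, 3) # SSB = 6 on 2 df, SSW = 6 on 6 df
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, 1 - pf(3, 2, 6), tolerance = 1e-12)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # group order is irrelevant
  set.seed(33)
  groups <- replicate(4, rnorm(6), simplify = FALSE)
  f1 <- one_way_anova(groups)$statistic
  f2 <- one_way_anova(rev(groups))$statistic
  expect_equal(f1, f2, tolerance = 1e-12)

  expect_error(one_way_anova(list(1:3)), "at least 2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least 2 observations")
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "zero within-group")
})

test_that("ANOVA with two groups squares the pooled t statistic", {
  set.seed(34)
  for (i in 1:50) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    f <- one_way_anova(list(a, b))
    t <- unpaired_t_test(a, b)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p_value, t$p_value, tolerance = 1e-10)
  }
})

test_that("Fisher exact p values match hypergeometric enumeration", {
  res <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)

  res <- fisher_exact_rxc(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)

  set.seed(35)
  for (i in 1:200) {
    tab <- random_2x2()
    expect_equal(fisher_exact_rxc(tab)$p_value, fisher_2x2_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact test is symmetric under transposition and validates input", {
  set.seed(36)
  for (i in 1:20) {
    tab <- matrix(sample(0:8, 6, replace = TRUE), 2)
    tab[1, 1] <- tab[1, 1] + 1; tab[2, 2] <- tab[2, 2] + 1 # positive margins
    expect_equal(fisher_exact_rxc(tab)$p_value,
                 fisher_exact_rxc(t(tab))$p_value, tolerance = 1e-10)
  }
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact_rxc(matrix(c(-1, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact_rxc(matrix(1:3, 1)), "2 x 2")
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 1, 1), 2)), "margins")
})

test_that("normality annotation flags skew and rejects degenerate input", {
  w <- normality_gate(qnorm(ppoints(20)))
  expect_gt(w$statistic, 0.95)
  expect_true(w$normal_flag)

  set.seed(37)
  skewed <- exp(rnorm(50))
  res <- normality_gate(skewed)
  expect_lt(res$p_value, 0.05)
  expect_false(res$normal_flag)

  expect_error(normality_gate(rep(1, 10)), "zero variance")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("the composition summary reproduces hand-computed means", {
  # two PROS patients with known compositions of the affected thigh
  rc1a <- c(adipose = 0.32, muscle = 0.64, bone = 0.04)
  rc1c <- c(adipose = 0.30, muscle = 0.66, bone = 0.04)
  rc2a <- c(adipose = 0.40, muscle = 0.56, bone = 0.04)
  rc2c <- c(adipose = 0.34, muscle = 0.62, bone = 0.04)
  mk <- function(id, rca, rcc) {
    m <- data.frame(region = c("thigh", "thigh"), side = c("left", "right"),
                    fat_mass_g = c(rca[1] * 1200, rcc[1] * 1000),
                    lean_mass_g = c(rca[2] * 1200, rcc[2] * 1000),
                    bmc_g = c(rca[3] * 1200, rcc[3] * 1000))
    patient_scan(id, m, diagnosis = "PROS",
                 clinical_affected = data.frame(region = "thigh", side = "left"))
  }
  scored <- score_cohort(lo_cohort(list(mk("p1", rc1a, rc1c), mk("p2", rc2a, rc2c))))
  s <- build_composition_summary(scored)
  pros_a <- s[s$diagnosis == "PROS" & s$tissue == "adipose", ]
  expect_equal(pros_a$affected_mean, 100 * mean(c(0.32, 0.40)))
  expect_equal(pros_a$contra_mean, 100 * mean(c(0.30, 0.34)))
  expect_equal(pros_a$delta_mean, mean(c(2, 6)))
  expect_equal(pros_a$delta_sd, sd(c(2, 6)))
  expect_equal(pros_a$n, 2)
  # Total row spans the cohort
  expect_equal(s$n[s$diagnosis == "Total"][1], 2)
})

test_that("identical symmetric patients give zero dRC and a flagged paired test", {
  scans <- lapply(c("p1", "p2", "p3"), function(id) {
    make_scan(id, clinical = data.frame(region = "thigh", side = "left"),
              diagnosis = "PROS")
  })
  scored <- score_cohort(lo_cohort(scans))
  s <- build_composition_summary(scored)
  pros <- s[s$diagnosis == "PROS", ]
  expect_equal(pros$delta_mean, rep(0, 3))
  expect_true(all(is.na(pros$paired_p)))
  expect_true(all(grepl("zero variance", pros$note)))
})

test_that("between-group dRC comparison needs two usable groups", {
  sim <- simulate_cohort(n = 12, seed = 41, mix = "PROS")
  scored <- score_cohort(sim$cohort)
  expect_error(compare_groups_delta_rc(scored), ">= 2")
})

test_that("between-group dRC comparison returns ANOVA plus all pairwise tests", {
  sim <- simulate_cohort(n = 40, seed = 42)
  scored <- score_cohort(sim$cohort)
  cmp <- compare_groups_delta_rc(scored)
  expect_named(cmp, lo_tissues())
  groups <- attr(cmp, "groups")
  expect_gte(length(groups), 2)
  for (tissue in lo_tissues()) {
    expect_s3_class(cmp[[tissue]]$anova, "lo_test")
    expect_equal(nrow(cmp[[tissue]]$pairwise), choose(length(groups), 2))
  }
  holm <- compare_groups_delta_rc(scored, p_adjust = "holm")
  expect_true(all(holm$adipose$pairwise$p_holm >= holm$adipose$pairwise$p_value))
})

test_that("predominant-tissue prevalence test builds the diagnosis x tissue table", {
  sim <- simulate_cohort(n = 60, seed = 43)
  scored <- score_cohort(sim$cohort)
  pt <- predominant_prevalence_test(scored)
  expect_true(all(rowSums(pt$table) > 0))
  expect_equal(sum(pt$table), sum(scored$results$scope == "aggregate"))
  expect_s3_class(pt$test, "lo_test")
  expect_gte(pt$test$p_value, 0)
})

test_that("stats JSON export carries the nested group -> tissue layout", {
  sim <- simulate_cohort(n = 30, seed = 44)
  scored <- score_cohort(sim$cohort)
  s <- build_composition_summary(scored)
  cmp <- compare_groups_delta_rc(scored)
  path <- file.path(withr::local_tempdir(), "stats.json")
  write_stats_json(s, cmp, path)
  back <- jsonlite::read_json(path)
  expect_true("Total" %in% names(back$groups))
  expect_equal(back$groups$Total$adipose$affected_mean,
               s$affected_mean[s$diagnosis == "Total" & s$tissue == "adipose"])
  expect_named(back$comparisons, lo_tissues())
})
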