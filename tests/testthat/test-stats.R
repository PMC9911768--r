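# Normality gate, group comparisons, Pearson chi-square, PVR association
# models and strain-feature regressions.

test_that("normality test separates normal from heavy-tailed samples", {
  set.seed(11)
  p_norm <- replicate(100, normality_test(rnorm(500)))
  expect_gte(sum(p_norm > 0.05), 90L)
  p_heavy <- replicate(100, normality_test(rt(500, df = 2)))
  expect_gte(sum(p_heavy < 0.05), 95L)
  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(1, 10)), "constant")
})

test_that("group comparison gates on normality and detects planted shifts", {
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  lab <- rep(c("a", "b"), each = 5L)
  cg <- compare_groups(x, lab)
  expect_equal(cg$p, 1, tolerance = 1e-9)

  set.seed(12)
  shifted <- c(rnorm(40), rnorm(40, mean = 2))
  cg2 <- compare_groups(shifted, rep(c("a", "b"), each = 40L))
  expect_lt(cg2$p, 0.001)

  gate <- replicate(100, {
    compare_groups(c(rnorm(30), rnorm(30)),
                   rep(c("a", "b"), each = 30L))$test_name
  })
  expect_gte(sum(gate == "t-test"), 90L)

  skewed <- c(rlnorm(40, sdlog = 1.5), rlnorm(40, sdlog = 1.5))
  expect_equal(compare_groups(skewed, rep(c("a", "b"), each = 40L))$test_name,
               "rank-sum")
  expect_error(compare_groups(1:5, rep("a", 5L)), "two observed levels")
})

test_that("Pearson chi-square reproduces the printed cohort tables", {
  sex <- matrix(c(35, 13, 17, 19), 2L, 2L)
  out <- chi2_contingency_test(sex)
  expect_equal(round(out$p, 3), 0.016)
  expect_equal(out$df, 1L)

  repair <- matrix(c(35, 2, 11, 30, 6, 0), 3L, 2L)
  expect_equal(round(chi2_contingency_test(repair)$p, 3), 0.003)

  same <- matrix(c(10, 20, 5, 10), 2L, 2L)   # identical row distributions
  out2 <- chi2_contingency_test(same)
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1)

  expect_error(chi2_contingency_test(matrix(c(0, 0, 3, 4), 2L)), "marginal")
})

test_that("chi-square agrees with an explicit textbook oracle", {
  set.seed(13)
  for (rep in 1:30) {
    r <- sample(2:4, 1L); cc <- sample(2:3, 1L)
    tab <- matrix(rpois(r * cc, 8) + 1L, r, cc)
    got <- chi2_contingency_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$p, pchisq(stat, (r - 1L) * (cc - 1L), lower.tail = FALSE),
                 tolerance = 1e-12)
    # cross-check against the independent stats implementation
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

make_records <- function(n = 84L, seed = 1L) {
  set.seed(seed)
  data.frame(
    group = rep(c("PVR", "NO_PVR"), c(48L, 36L))[seq_len(n)],
    sex = sample(c("M", "F"), n, replace = TRUE),
    repair_type = sample(c("TRANSANNULAR_PATCH", "VALVE_SPARING", "CONDUIT"),
                         n, replace = TRUE, prob = c(0.7, 0.1, 0.2)),
    time_after_repair = rlnorm(n, log(14), 0.5),
    bsa = rnorm(n, 1.55, 0.3)
  )
}

test_that("PVR association recovers planted effects and controls type I error", {
  rec <- make_records()
  g <- as.integer(rec$group == "PVR")
  set.seed(14)
  # planted 1 SD group effect plus confounder contributions
  covered <- replicate(100, {
    y <- g * 1 + 0.5 * scale(rec$time_after_repair) +
      0.3 * (rec$sex == "M") + rnorm(84L)
    a <- pvr_association(as.numeric(y), rec, "SHAPE_MODE")
    beta_std <- 1 / sd(y)   # planted effect on the z-scale of the response
    se <- a$coefficients["groupPVR", "se"]
    abs(a$pvr_coefficient - beta_std) < 2 * se
  })
  expect_gte(sum(covered), 90L)

  # null responses: type-I error near the nominal level
  set.seed(15)
  rejections <- mean(replicate(500, {
    a <- pvr_association(rnorm(84L), rec, "SHAPE_MODE")
    a$pvr_p_value < 0.05
  }))
  expect_gt(rejections, 0.02)
  expect_lt(rejections, 0.09)
})

test_that("a response carried by a confounder loads on it, not on PVR", {
  rec <- make_records(seed = 2L)
  set.seed(16)
  y <- rec$time_after_repair + rnorm(84L, sd = 1e-6 * sd(rec$time_after_repair))
  a <- pvr_association(y, rec, "IMAGING_INDEX")
  expect_lt(a$coefficients["time", "p"], 1e-20)
  expect_lt(abs(a$pvr_coefficient), 1e-4)
})

test_that("BSA enters shape-mode models only, and designs are validated", {
  rec <- make_records(seed = 3L)
  set.seed(17)
  y <- rnorm(84L)
  a_idx <- pvr_association(y, rec, "IMAGING_INDEX")
  a_mod <- pvr_association(y, rec, "SHAPE_MODE")
  expect_false("bsa" %in% rownames(a_idx$coefficients))
  expect_true("bsa" %in% rownames(a_mod$coefficients))

  rec2 <- rec
  rec2$time_after_repair <- rec2$bsa       # aliased continuous predictors
  expect_error(pvr_association(y, rec2, "SHAPE_MODE"), "aliased|rank")
  expect_error(pvr_association(y[1:8], rec[1:8, ], "SHAPE_MODE"), "few")
})

test_that("association p-values are invariant to predictor rescaling and
           internally consistent with the F tail", {
  rec <- make_records(seed = 4L)
  set.seed(18)
  y <- rnorm(84L) + 0.5 * (rec$group == "PVR")
  a1 <- pvr_association(y, rec, "SHAPE_MODE")
  rec2 <- rec
  rec2$time_after_repair <- 3.7 * rec2$time_after_repair - 12
  rec2$bsa <- 0.2 * rec2$bsa + 5
  a2 <- pvr_association(y, rec2, "SHAPE_MODE")
  expect_equal(a2$pvr_p_value, a1$pvr_p_value, tolerance = 1e-10)
  expect_equal(a2$coefficients[, "p"], a1$coefficients[, "p"],
               tolerance = 1e-8)

  tstat <- a1$coefficients["groupPVR", "t"]
  expect_equal(a1$pvr_p_value,
               pf(tstat^2, 1, a1$df_residual, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("strain-feature regression returns slope, r and p", {
  x <- seq(-3, 3, length.out = 50L)
  fit <- suppressWarnings(strain_feature_regression(2 * x, x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  set.seed(19)
  null_p <- replicate(200, {
    strain_feature_regression(rnorm(40), rnorm(40))$p
  })
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 1e-3)

  y <- -x + rnorm(50L, sd = 0.1 * sd(x))
  expect_lt(strain_feature_regression(y, x)$r, -0.9)

  expect_error(strain_feature_regression(rnorm(10), rep(1, 10)), "constant")
  expect_error(strain_feature_regression(rnorm(3), rnorm(4)), "mismatch|length")
})
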