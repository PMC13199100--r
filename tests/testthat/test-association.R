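test_that("normality gate picks Pearson for Gaussian, Spearman for skewed", {
  set.seed(6)
  x <- rnorm(142)
  y <- rnorm(142)
  expect_equal(choose_method(x, y), "pearson")
  z <- exp(rnorm(142, sd = 1.5))  # heavily log-normal
  expect_equal(choose_method(x, z), "spearman")
  expect_error(choose_method(rnorm(3), rnorm(3)), "at least 4")
  expect_error(choose_method(rep(1, 20), rnorm(20)), "constant")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("partial correlation reduces to the simple correlation with no
           covariates and removes a planted confounder", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(500), y = rnorm(500))
  pc <- partial_correlation(d, "x", "y")
  ct <- stats::cor.test(d$x, d$y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pc$df, 498)

  # covariates uncorrelated with x and y barely move the estimate
  d$c1 <- rnorm(500)
  d$c2 <- rnorm(500)
  pc2 <- partial_correlation(d, "x", "y", c("c1", "c2"))
  expect_lt(abs(pc2$r - pc$r), 0.05)

  # shared confounder: large simple r, near-zero partial r
  n <- 800
  conf <- rnorm(n)
  d2 <- tibble::tibble(x = conf + rnorm(n), y = 2 * conf + rnorm(n),
                       conf = conf)
  expect_gt(abs(stats::cor(d2$x, d2$y)), 0.4)
  pc3 <- partial_correlation(d2, "x", "y", "conf")
  expect_lt(abs(pc3$r), 3 / sqrt(n))

  # df bookkeeping at the study's analysis-set size
  d3 <- tibble::tibble(x = rnorm(142), y = rnorm(142), a = rnorm(142),
                       b = rnorm(142), c = rnorm(142), e = rnorm(142))
  pc4 <- partial_correlation(d3, "x", "y", c("a", "b", "c", "e"))
  expect_equal(pc4$df, 136)

  expect_error(partial_correlation(d3[1:6, ], "x", "y",
                                   c("a", "b", "c", "e")), "complete cases")
  d3$a2 <- d3$a
  expect_error(partial_correlation(d3, "x", "y", c("a", "a2")), "collinear")
})

test_that("moderation regression is exact OLS with the fixed design order", {
  # noise-free linear outcome: coefficients recovered to numerical precision
  set.seed(9)
  n <- 200
  d <- tibble::tibble(folate = rnorm(n), alps = rnorm(n), age = rnorm(n),
                      sex = rbinom(n, 1, 0.5),
                      education = rnorm(n), apoe4 = rbinom(n, 1, 0.3))
  beta <- c(0.4, -0.3, 0.25, 0.1, -0.2, 0.15, -0.1)
  X <- cbind(d$folate, d$alps, d$folate * d$alps, d$age, d$sex,
             d$education, d$apoe4)
  d$y <- 2 + as.vector(X %*% beta)
  fit <- interaction_regression(d, "y", standardized = FALSE)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "folate", "alps", "folate:alps",
                          "age", "sex", "education", "apoe"))
  expect_equal(td$estimate, c(2, beta), tolerance = 1e-10)

  # OLS oracle: matches the normal-equations solution on a noisy fit
  d$y <- d$y + rnorm(n)
  fit2 <- interaction_regression(d, "y", standardized = FALSE)
  Xd <- cbind(1, X)
  bhat <- solve(crossprod(Xd), crossprod(Xd, d$y))
  expect_equal(tidy(fit2)$estimate, as.vector(bhat), tolerance = 1e-8)

  expect_error(interaction_regression(d[1:8, ], "y"), "10")
  expect_equal(glance(fit2)$nobs, n)
})

test_that("group comparisons gate on normality and run Bonferroni post-hocs", {
  set.seed(10)
  d <- tibble::tibble(
    group = rep(c("NC", "AD-MCI", "AD-D"), each = 30),
    val = c(rnorm(30, 0), rnorm(30, 0.2), rnorm(30, 3)))  # 3 SD separation
  gc <- group_compare(d, "val")
  expect_equal(gc$test, "anova")
  expect_lt(gc$p, 0.001)
  expect_equal(nrow(gc$posthoc), 3)
  expect_true(all(gc$posthoc$p_bonferroni <= 1))
  expect_true(all(gc$posthoc$p_bonferroni >= gc$posthoc$p_raw))

  # skewed data routes to Kruskal-Wallis
  d2 <- d
  d2$val <- exp(d2$val)
  expect_equal(group_compare(d2, "val")$test, "kruskal-wallis")

  expect_error(group_compare(d[c(1:2, 31:60, 61:90), ], "val"),
               "at least 3")

  # two groups use the two-sample family
  d3 <- d[d$group != "AD-D", ]
  expect_equal(group_compare(d3, "val")$test, "t-test")
})

test_that("the chi-squared route matches a hand-computed statistic", {
  # APOE e4 carrier table: NC(9, 54), MCI(21, 52), AD-D(29, 35)
  d <- tibble::tibble(
    group = rep(c("NC", "AD-MCI", "AD-D"), times = c(63, 73, 64)),
    apoe = c(rep(c("carrier", "non"), c(9, 54)),
             rep(c("carrier", "non"), c(21, 52)),
             rep(c("carrier", "non"), c(29, 35))))
  gc <- group_compare(d, "apoe")
  expect_equal(gc$test, "chi-squared")

  # brute-force oracle: sum (O - E)^2 / E
  tab <- table(d$group, d$apoe)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(gc$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_lt(gc$p, 0.001)
})

test_that("risk stratification partitions at the medians with >= ties high", {
  # four subjects at the quadrant corners: 1 low, 2 moderate, 1 high
  d <- tibble::tibble(folate = c(20, 20, 5, 5), alps = c(1.4, 1.0, 1.4, 1.0))
  r <- risk_stratify(d)
  expect_equal(as.character(r$risk), c("low", "moderate", "moderate",
                                       "high"))
  expect_equal(sum(table(r$risk)), 4)

  # identical folate: nobody falls below the median, high stratum empty
  d2 <- tibble::tibble(folate = rep(10, 40), alps = rnorm(40, 1.2, 0.1))
  expect_warning(r2 <- risk_stratify(d2), "empty risk stratum")
  expect_equal(sum(r2$risk == "high"), 0)
  expect_true(all(r2$risk %in% c("low", "moderate")))

  expect_error(risk_stratify(tibble::tibble(folate = c(1, NA),
                                            alps = c(1, 1))), "non-missing")

  # partition property on random data
  set.seed(12)
  d3 <- tibble::tibble(folate = rnorm(101, 10, 3), alps = rnorm(101, 1.2, .1))
  r3 <- risk_stratify(d3)
  expect_equal(as.integer(sum(table(r3$risk))), 101L)
})

test_that("the planted risk-group cognitive ordering is recovered", {
  means <- sapply(1:40, function(s) {
    coh <- make_cohort(analysis_set_spec(n = 142), seed = 500 + s)
    sc <- score_with_generator_norms(coh)
    r <- risk_stratify(sc)
    tapply(r$composite_memory, r$risk, mean)
  })
  m <- rowMeans(means)
  expect_gt(m["low"], m["moderate"])
  expect_gt(m["moderate"], m["high"])
})

test_that("stratified subgroup comparisons run per stratum", {
  coh <- make_cohort(cohort_spec(), seed = 14)
  st <- stratified_compare(coh, vars = c("folate", "alps"))
  expect_true(all(c("stratum", "variable", "test", "p") %in% names(st)))
  expect_equal(nrow(st), 10)  # 5 strata x 2 variables
  expect_true(all(st$test %in% c("t-test", "mann-whitney")))
})

test_that("the full association report is assembled coherently", {
  coh <- make_cohort(cohort_spec(), seed = 15)
  sc <- score_cognition(coh)
  rep <- run_association(sc)
  expect_s3_class(rep, "association_report")
  expect_equal(nrow(rep$biomarker_alps), 9)
  expect_true(all(rep$biomarker_alps$p_fdr >= rep$biomarker_alps$p))
  expect_equal(nrow(rep$cognition_grid), 42)
  expect_true(all(abs(rep$cognition_grid$r) <= 1))
  expect_equal(rep$apoe_test$test, "chi-squared")
  b3 <- tidy(rep$regressions$composite_memory)
  expect_equal(b3$term[4], "folate:alps")
})
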