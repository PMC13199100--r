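test_that("control-referenced Z-scores have the defining algebra", {
  expect_equal(zscore(10, 10, 2), 0)
  expect_equal(zscore(14, 10, 2), 2)
  expect_error(zscore(1, 0, 0), "positive")

  # self-referenced control sample: mean 0, SD 1 exactly, per test
  coh <- make_cohort(cohort_spec(), seed = 5)
  scored <- score_cognition(coh)
  ref <- attr(scored, "reference")
  nc <- scored[scored$group == "NC", ]
  for (t in ref$test) {
    z <- zscore(nc[[t]], ref$mean[ref$test == t], ref$sd[ref$test == t])
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  }
})

test_that("orientation flips timed tests and is an involution", {
  expect_equal(orient_z("tmt_a", 1.3), -1.3)
  expect_equal(orient_z("avlt", 0.7), 0.7)
  z <- c(-2, 0, 1.5)
  for (t in c("tmt_a", "tmt_b", "scwt_a", "scwt_b", "scwt_c"))
    expect_equal(orient_z(t, orient_z(t, z)), z)
  expect_error(orient_z("nosuch", 1), "unknown test")

  # increasing a raw time strictly decreases the oriented Z
  battery <- cognitive_battery()
  expect_true(all(battery$time_based[battery$test %in%
    c("tmt_a", "tmt_b", "scwt_a", "scwt_b", "scwt_c")]))
  z1 <- orient_z("tmt_b", zscore(100, 120, 40))
  z2 <- orient_z("tmt_b", zscore(140, 120, 40))
  expect_lt(z2, z1)
})

test_that("composites are means of oriented Z with listwise deletion", {
  # executive constituents oriented Z (-1.0, 0.2, 0.5) -> composite -0.1
  ref <- tibble::tibble(test = c("scwt_c", "tmt_b", "vft", "mmse", "moca",
                                 "avlt", "dst", "cdt", "tmt_a", "scwt_a",
                                 "scwt_b"),
                        mean = c(80, 120, 15, 28, 25, 45, 12, 8, 55, 28, 38),
                        sd = c(20, 40, 5, 1.5, 2.5, 9, 2.5, 1.8, 18, 7, 9))
  row <- tibble::tibble(group = "AD",
                        scwt_c = 80 + 20 * 1.0,  # oriented Z = -1.0
                        tmt_b = 120 - 40 * 0.2,  # oriented Z = +0.2
                        vft = 15 + 5 * 0.5,      # Z = +0.5
                        mmse = 28, moca = 25, avlt = 45, dst = 12, cdt = 8,
                        tmt_a = 55, scwt_a = 28, scwt_b = 38)
  sc <- score_cognition(row, reference = ref)
  expect_equal(sc$composite_executive, -0.1)

  # one missing constituent blanks that domain only
  row2 <- row
  row2$tmt_b <- NA
  sc2 <- score_cognition(row2, reference = ref)
  expect_true(is.na(sc2$composite_executive))
  expect_false(is.na(sc2$composite_memory))
  expect_false(is.na(sc2$composite_processing_speed))

  # single-test domains: composite equals the oriented Z
  expect_equal(sc$composite_memory, sc$z_avlt)
})

test_that("missingness bookkeeping reconciles per domain", {
  coh <- make_cohort(cohort_spec(missing_rate = 0.1), seed = 9)
  scored <- score_cognition(coh)
  battery <- cognitive_battery()
  for (dom in c("memory", "executive", "attention", "visuospatial",
                "processing_speed")) {
    comp <- scored[[paste0("composite_", dom)]]
    tests <- battery$test[battery$domain == dom]
    should_miss <- rowSums(is.na(scored[tests])) > 0
    expect_equal(is.na(comp), should_miss)
    expect_equal(sum(!is.na(comp)) + sum(is.na(comp)), nrow(scored))
  }

  # missing_rate = 0 leaves no missing cells
  full <- make_cohort(cohort_spec(missing_rate = 0), seed = 9)
  expect_equal(sum(is.na(full[default_test_norms()$test])), 0)
})

test_that("Cronbach's alpha behaves at its limits", {
  set.seed(2)
  x <- rnorm(60)
  dup <- cbind(x, x, x)
  expect_equal(cronbach_alpha(dup), 1)

  # independent items: alpha near 0
  ind <- matrix(rnorm(300), 100)
  expect_lt(abs(cronbach_alpha(ind)), 0.35)

  expect_true(is.na(cronbach_alpha(matrix(x, ncol = 1))))

  # standardized variant is scale-free
  y <- cbind(x + rnorm(60, sd = 0.5), 100 * (x + rnorm(60, sd = 0.5)))
  a_std <- cronbach_alpha(y, standardized = TRUE)
  y_scaled <- y
  y_scaled[, 2] <- y_scaled[, 2] / 100
  expect_equal(a_std, cronbach_alpha(y_scaled, standardized = TRUE),
               tolerance = 1e-12)
})

test_that("composites are invariant to raw-score shifts when the reference
           is recomputed", {
  coh <- make_cohort(cohort_spec(), seed = 3)
  base <- score_cognition(coh)
  shifted <- coh
  shifted$tmt_b <- shifted$tmt_b + 17
  resc <- score_cognition(shifted)
  expect_equal(resc$composite_executive, base$composite_executive,
               tolerance = 1e-10)
})
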