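#' Normality-gated correlation method choice
#'
#' Pearson's correlation when both variables pass the Shapiro-Wilk test at
#' `alpha`, Spearman's otherwise.
#'
#' @param x,y Numeric vectors (pairwise complete cases are used).
#' @param alpha Shapiro-Wilk significance level.
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant variable: correlation method is undefined")
  normal <- function(v) stats::shapiro.test(v)$p.value > alpha
  if (normal(x) && normal(y)) "pearson" else "spearman"
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p(i) = min_{j>=i}(p(j) * m / j)`, capped at 1,
#' returned in the input order. Adjustment should be applied within one
#' declared family of tests.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))  # all 0.03
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Simple correlation as a tidy row
#'
#' @param data Data frame.
#' @param x,y Column names.
#' @param method `"auto"` (Shapiro-Wilk gate), `"pearson"` or `"spearman"`.
#' @return One-row tibble: `x`, `y`, `method`, `r`, `p`, `n`, `covariates`.
#' @export
correlate <- function(data, x, y, method = "auto") {
  v1 <- data[[x]]; v2 <- data[[y]]
  ok <- stats::complete.cases(v1, v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  if (method == "auto") method <- choose_method(v1, v2)
  ct <- suppressWarnings(stats::cor.test(v1, v2, method = method))
  tibble::tibble(x = x, y = y, method = method,
                 r = unname(ct$estimate), p = ct$p.value,
                 n = length(v1), covariates = "")
}

#' Partial correlation by residualization
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by least
#' squares and correlates the residuals. The p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `n - 2 - k` degrees of
#' freedom (`k` covariates). With zero covariates this reduces exactly to
#' the simple correlation. The Spearman variant rank-transforms all inputs
#' first. With `method = "auto"` the Shapiro-Wilk gate is applied to the
#' Pearson residuals (and the gate decision is recorded).
#'
#' @param data Data frame.
#' @param x,y Column names.
#' @param covariates Character vector of covariate columns (binary columns
#'   are coerced to 0/1).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return One-row tibble like [correlate()], plus `df`.
#' @export
partial_correlation <- function(data, x, y, covariates = character(),
                                method = "pearson") {
  cols <- c(x, y, covariates)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  k <- length(covariates)
  if (n <= k + 3) stop("need n > k + 3 complete cases (n = ", n,
                       ", k = ", k, ")")
  cx <- covariate_matrix(d, covariates)
  if (k >= 2) {
    if (qr(cbind(1, cx))$rank < k + 1) {
      cc <- stats::cor(cx)
      idx <- which(abs(cc - diag(diag(cc))) > 1 - 1e-10, arr.ind = TRUE)
      pair <- if (nrow(idx)) paste(covariates[idx[1, ]], collapse = ", ")
              else paste(covariates, collapse = ", ")
      stop("collinear covariates: ", pair)
    }
  }

  pc <- function(v1, v2, cxm) {
    X <- cbind(1, cxm)
    r1 <- stats::.lm.fit(X, v1)$residuals
    r2 <- stats::.lm.fit(X, v2)$residuals
    stats::cor(r1, r2)
  }
  v1 <- as.numeric(d[[x]]); v2 <- as.numeric(d[[y]])

  if (method == "auto") {
    X <- cbind(1, cx)
    res1 <- stats::.lm.fit(X, v1)$residuals
    res2 <- stats::.lm.fit(X, v2)$residuals
    normal <- function(v) stats::shapiro.test(v)$p.value > 0.05
    method <- if (normal(res1) && normal(res2)) "pearson" else "spearman"
  }
  if (method == "spearman") {
    v1 <- rank(v1); v2 <- rank(v2)
    cx <- apply(cx, 2, rank)
    if (k == 0) cx <- matrix(0, n, 0)
  }
  r <- pc(v1, v2, cx)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(x = x, y = y, method = method, r = r, p = p, n = n,
                 covariates = paste(covariates, collapse = "+"), df = df)
}

covariate_matrix <- function(d, covariates) {
  if (!length(covariates)) return(matrix(0, nrow(d), 0))
  m <- sapply(covariates, function(cv) {
    v <- d[[cv]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) > 2)
        stop("covariate '", cv, "' has more than 2 levels; recode it")
      as.numeric(as.character(v) == lv[length(lv)])
    } else as.numeric(v)
  })
  matrix(m, nrow = nrow(d), dimnames = list(NULL, covariates))
}

#' A family of correlations with FDR adjustment
#'
#' Runs [correlate()] or [partial_correlation()] over every (x, y) pair and
#' appends Benjamini-Hochberg adjusted p-values computed within this family.
#'
#' @param data Data frame.
#' @param xs,ys Column-name vectors; the family is the full xs-by-ys grid.
#' @param covariates Covariates for partial correlations (empty = simple).
#' @param method Correlation method (see [partial_correlation()]).
#' @return Tibble of class `correlation_family`, one row per pair, with
#'   `p_fdr`.
#' @export
correlation_family <- function(data, xs, ys, covariates = character(),
                               method = "auto") {
  grid <- expand.grid(x = xs, y = ys, stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(x, y) {
    if (length(covariates))
      partial_correlation(data, x, y, covariates, method = method)
    else correlate(data, x, y, method = method)
  })
  out$p_fdr <- fdr_adjust(out$p)
  class(out) <- c("correlation_family", class(out))
  out
}

#' Folate-by-ALPS moderation regression
#'
#' Ordinary least squares for
#' `outcome ~ folate + ALPS + folate:ALPS + age + sex + education + APOE`.
#' By default all continuous predictors and the outcome are z-standardized
#' before fitting (standardized betas) and the interaction column is the
#' product of the standardized factors; binary covariates enter as 0/1.
#' The design column order is fixed: intercept, folate, ALPS, interaction,
#' then the four covariates.
#'
#' @param data Data frame (complete cases on all design columns are used).
#' @param outcome Outcome column name (e.g. `"composite_memory"`,
#'   `"z_moca"`).
#' @param folate,alps,age,sex,education,apoe Design column names.
#' @param standardized Standardize continuous variables (default) or fit on
#'   raw scales.
#' @return Object of class `interaction_fit` with [tidy()] and [glance()]
#'   methods; `tidy()` rows follow the fixed design order.
#' @export
interaction_regression <- function(data, outcome, folate = "folate",
                                   alps = "alps", age = "age", sex = "sex",
                                   education = "education", apoe = "apoe4",
                                   standardized = TRUE) {
  cols <- c(outcome, folate, alps, age, sex, education, apoe)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= 10) stop("need more than 10 complete cases (got ", n, ")")

  num <- function(v) if (standardized) as.numeric(scale(v)) else as.numeric(v)
  X <- cbind(
    folate = num(d[[folate]]),
    alps = num(d[[alps]]),
    `folate:alps` = NA_real_,
    age = num(d[[age]]),
    sex = covariate_matrix(d, sex)[, 1],
    education = num(d[[education]]),
    apoe = covariate_matrix(d, apoe)[, 1]
  )
  X[, "folate:alps"] <- X[, "folate"] * X[, "alps"]
  y <- num(d[[outcome]])
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("singular design matrix")

  fit <- stats::lm.fit(Xd, y)
  res <- fit$residuals
  df <- n - ncol(Xd)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xd)))
  se <- sqrt(diag(XtXinv) * sigma2)
  beta <- fit$coefficients
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)

  structure(list(
    outcome = outcome,
    coefficients = tibble::tibble(term = colnames(Xd),
                                  estimate = unname(beta),
                                  std.error = unname(se),
                                  statistic = unname(tval),
                                  p.value = unname(pval)),
    sigma2 = sigma2, df = df, n = n, standardized = standardized,
    r.squared = 1 - sum(res^2) / sum((y - mean(y))^2)
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit> outcome: ", x$outcome, " (n = ", x$n,
      if (x$standardized) ", standardized betas", ")\n", sep = "")
  b3 <- x$coefficients[x$coefficients$term == "folate:alps", ]
  cat(sprintf("  folate:alps  beta = %.3f, p = %.4f\n", b3$estimate,
              b3$p.value))
  invisible(x)
}

#' Group comparison with normality gating
#'
#' Continuous values: Shapiro-Wilk per group gates a one-way ANOVA (all
#' groups normal) versus the Kruskal-Wallis H test; with exactly two groups
#' the corresponding two-sample test (t / Mann-Whitney U) is used. When the
#' omnibus test is significant at `posthoc_alpha`, all pairwise contrasts
#' are run in the matching family (t-test or Mann-Whitney U) with Bonferroni
#' multiplication by the number of contrasts. Character/factor/logical
#' values are routed to a chi-squared test on the contingency table.
#'
#' @param data Data frame.
#' @param value Column to compare.
#' @param group Grouping column.
#' @param posthoc_alpha Omnibus significance level gating the post-hoc step.
#' @return Object of class `group_comparison`: per-group summaries, omnibus
#'   test name/statistic/p, and the (possibly empty) post-hoc table.
#' @export
group_compare <- function(data, value, group = "group",
                          posthoc_alpha = 0.05) {
  v <- data[[value]]
  g <- data[[group]]
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g[ok])
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 non-empty groups")

  if (is.character(v) || is.factor(v) || is.logical(v)) {
    tab <- table(g, v)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(structure(list(
      variable = value, type = "categorical", table = tab,
      test = "chi-squared", statistic = unname(ht$statistic),
      p = ht$p.value, posthoc = tibble::tibble(), data = NULL,
      summaries = tibble::as_tibble(as.data.frame(tab))
    ), class = "group_comparison"))
  }

  sizes <- table(g)
  if (any(sizes < 3)) stop("every group needs at least 3 observations")
  normal <- all(vapply(lev, function(l) {
    x <- v[g == l]
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }, logical(1)))

  if (length(lev) == 2) {
    ht <- if (normal) stats::t.test(v ~ g)
          else suppressWarnings(stats::wilcox.test(v ~ g))
    test <- if (normal) "t-test" else "mann-whitney"
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else if (normal) {
    ht <- summary(stats::aov(v ~ factor(g)))[[1]]
    test <- "anova"
    stat <- ht[["F value"]][1]
    p <- ht[["Pr(>F)"]][1]
  } else {
    ht <- stats::kruskal.test(v, factor(g))
    test <- "kruskal-wallis"
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }

  summaries <- tibble::tibble(
    group = lev,
    n = as.integer(sizes[lev]),
    mean = vapply(lev, function(l) mean(v[g == l]), 1),
    sd = vapply(lev, function(l) stats::sd(v[g == l]), 1),
    median = vapply(lev, function(l) stats::median(v[g == l]), 1),
    q25 = vapply(lev, function(l) stats::quantile(v[g == l], 0.25), 1),
    q75 = vapply(lev, function(l) stats::quantile(v[g == l], 0.75), 1),
    normal_summary = normal
  )

  posthoc <- tibble::tibble()
  if (length(lev) > 2 && !is.na(p) && p < posthoc_alpha) {
    pairs <- utils::combn(sort(lev), 2)
    m <- ncol(pairs)
    posthoc <- purrr::map_dfr(seq_len(m), function(i) {
      a <- v[g == pairs[1, i]]; b <- v[g == pairs[2, i]]
      pt <- if (normal) stats::t.test(a, b)
            else suppressWarnings(stats::wilcox.test(a, b))
      tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                     p_raw = pt$p.value,
                     p_bonferroni = min(1, pt$p.value * m))
    })
  }

  structure(list(variable = value, type = "continuous",
                 summaries = summaries, test = test, statistic = stat,
                 p = p, posthoc = posthoc,
                 data = tibble::tibble(value = v, group = g)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$variable, ": ", x$test, ", statistic = ",
      signif(x$statistic, 4), ", p = ", format.pval(x$p, digits = 3), "\n",
      sep = "")
  if (nrow(x$posthoc)) {
    cat("  post-hoc (Bonferroni):\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s vs %s: p = %.4f\n", x$posthoc$group1[i],
                  x$posthoc$group2[i], x$posthoc$p_bonferroni[i]))
  }
  invisible(x)
}

#' Median-split risk stratification
#'
#' Splits the analysis set at the median serum folate and median ALPS index
#' (values equal to the median count as the "high" side): low risk = high
#' folate and high ALPS, high risk = low folate and low ALPS, moderate risk
#' = the two mixed cells.
#'
#' @param data Data frame with non-missing `folate` and `alps` columns.
#' @param folate,alps Column names.
#' @return `data` with a `risk` factor column (levels low/moderate/high);
#'   thresholds as `attr(, "thresholds")`. Warns if a stratum is empty.
#' @export
risk_stratify <- function(data, folate = "folate", alps = "alps") {
  f <- data[[folate]]; a <- data[[alps]]
  if (anyNA(f) || anyNA(a))
    stop("folate and ALPS must be non-missing for stratification")
  mf <- stats::median(f); ma <- stats::median(a)
  hi_f <- f >= mf; hi_a <- a >= ma
  risk <- dplyr::case_when(hi_f & hi_a ~ "low",
                           !hi_f & !hi_a ~ "high",
                           TRUE ~ "moderate")
  risk <- factor(risk, levels = c("low", "moderate", "high"))
  empty <- setdiff(levels(risk), unique(as.character(risk)))
  if (length(empty))
    warning("empty risk stratum: ", paste(empty, collapse = ", "),
            "; contrasts are restricted to non-empty strata")
  out <- dplyr::mutate(data, risk = risk)
  attr(out, "thresholds") <- c(folate_median = mf, alps_median = ma)
  out
}

#' Cognitive contrasts across risk strata
#'
#' Applies [group_compare()] (with Bonferroni post-hoc) to each outcome
#' across the non-empty risk strata of a [risk_stratify()]-ed table.
#'
#' @param data Output of [risk_stratify()].
#' @param outcomes Outcome column names.
#' @return Named list of `group_comparison` objects.
#' @export
risk_compare <- function(data, outcomes = c("z_mmse", "z_moca",
                                            "composite_memory",
                                            "composite_processing_speed")) {
  stopifnot("risk" %in% names(data))
  d <- data[!is.na(data$risk), , drop = FALSE]
  d$risk <- droplevels(d$risk)
  out <- lapply(outcomes, function(o) group_compare(d, o, group = "risk"))
  names(out) <- outcomes
  out
}

#' Stratified two-group comparisons
#'
#' Config-driven subgroup analysis: within each stratum (e.g. females, age
#' >= 60), compares each variable between two clinical groups with the
#' normality-gated two-sample test from [group_compare()].
#'
#' @param data Cohort tibble.
#' @param vars Variables to compare.
#' @param strata Named list of predicate functions of the data frame, each
#'   returning a logical row filter.
#' @param group Grouping column; rows are restricted to `levels`.
#' @param levels Two group labels to contrast (the second may pool several
#'   labels, e.g. `list("NC", c("AD-MCI", "AD-D"))`).
#' @return Tibble: one row per stratum x variable with test name and p.
#' @export
stratified_compare <- function(data, vars = c("folate", "b12", "hcy",
                                              "alps", "alps_left",
                                              "alps_right"),
                               strata = list(
                                 all = function(d) rep(TRUE, nrow(d)),
                                 female = function(d) d$sex == "female",
                                 male = function(d) d$sex == "male",
                                 late_life = function(d) d$age >= 60,
                                 early = function(d) d$age < 60),
                               group = "group",
                               levels = list("NC", c("AD-MCI", "AD-D"))) {
  purrr::imap_dfr(strata, function(f, stratum) {
    d <- data[f(data), , drop = FALSE]
    d <- d[d[[group]] %in% unlist(levels), , drop = FALSE]
    lab <- vapply(d[[group]], function(g)
      if (g %in% levels[[1]]) "A" else "B", "")
    d$.contrast <- lab
    purrr::map_dfr(vars, function(v) {
      gc <- group_compare(d, v, group = ".contrast")
      tibble::tibble(stratum = stratum, variable = v, test = gc$test,
                     statistic = gc$statistic, p = gc$p,
                     n = nrow(d))
    })
  })
}

#' Full association report
#'
#' Orchestrates the statistical plan on a scored cohort: three-group
#' comparisons of biomarkers and ALPS indices (Bonferroni post-hoc), the
#' APOE contingency test, the biomarker-by-ALPS correlation family in the
#' AD subset (FDR within the 3x3 family), the biomarker/ALPS-by-cognition
#' partial-correlation grid adjusted for age, sex, education and APOE (FDR
#' within that family), moderation regressions per cognitive outcome, and
#' median-split risk stratification with cognitive contrasts.
#'
#' @param scored Output of [score_cognition()] on a cohort with `group`,
#'   biomarker and ALPS columns.
#' @param ad_groups Labels forming the AD analysis subset.
#' @param adjusted_biomarker_alps Adjust the biomarker-ALPS block for the
#'   covariates too (default `FALSE`: simple correlations).
#' @param outcomes Cognitive outcomes for the regression block.
#' @return Object of class `association_report` (a named list of results).
#' @export
run_association <- function(scored, ad_groups = c("AD-MCI", "AD-D"),
                            adjusted_biomarker_alps = FALSE,
                            outcomes = c("composite_memory", "z_moca")) {
  covars <- c("age", "sex", "education", "apoe4")
  ad <- scored[scored$group %in% ad_groups, , drop = FALSE]

  group_tests <- lapply(c("folate", "b12", "hcy", "alps", "alps_left",
                          "alps_right"),
                        function(v) group_compare(scored, v))
  names(group_tests) <- c("folate", "b12", "hcy", "alps", "alps_left",
                          "alps_right")
  apoe_test <- group_compare(dplyr::mutate(scored,
                                           apoe4 = ifelse(apoe4 == 1,
                                                          "carrier",
                                                          "non-carrier")),
                             "apoe4")

  biomarker_alps <- correlation_family(
    ad, xs = c("folate", "b12", "hcy"),
    ys = c("alps", "alps_left", "alps_right"),
    covariates = if (adjusted_biomarker_alps) covars else character())

  cog <- intersect(c("z_mmse", "z_moca", "composite_memory",
                     "composite_executive", "composite_attention",
                     "composite_visuospatial",
                     "composite_processing_speed"), names(scored))
  cognition_grid <- correlation_family(
    ad, xs = c("folate", "b12", "hcy", "alps", "alps_left", "alps_right"),
    ys = cog, covariates = covars, method = "auto")

  regressions <- lapply(outcomes, function(o) interaction_regression(ad, o))
  names(regressions) <- outcomes

  strat <- risk_stratify(ad)
  risk_tests <- risk_compare(strat)

  structure(list(group_tests = group_tests, apoe_test = apoe_test,
                 biomarker_alps = biomarker_alps,
                 cognition_grid = cognition_grid,
                 regressions = regressions,
                 risk_table = strat, risk_tests = risk_tests,
                 stratified = stratified_compare(scored)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report>\n")
  cat("  group comparisons:", length(x$group_tests), "variables\n")
  cat("  biomarker-ALPS family:", nrow(x$biomarker_alps), "correlations\n")
  cat("  cognition grid:", nrow(x$cognition_grid),
      "partial correlations\n")
  cat("  regressions:", paste(names(x$regressions), collapse = ", "), "\n")
  invisible(x)
}
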