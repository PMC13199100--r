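#' Default raw-score norms for the cognitive battery
#'
#' Control-group means and SDs used to map latent standardized scores to raw
#' test units (and, inversely, by the scoring module). Values are plausible
#' clinic norms for an older adult control sample; timed tests are in
#' seconds (higher = worse), the rest in points (higher = better).
#'
#' @return Tibble with columns `test`, `nc_mean`, `nc_sd`.
#' @export
default_test_norms <- function() {
  tibble::tibble(
    test = c("mmse", "moca", "avlt", "scwt_c", "tmt_b", "vft", "dst",
             "cdt", "tmt_a", "scwt_a", "scwt_b"),
    nc_mean = c(28, 25, 45, 85, 120, 17, 12, 8, 55, 28, 38),
    nc_sd = c(1.5, 2.5, 9, 22, 40, 4.5, 2.5, 1.8, 18, 7, 9)
  )
}

#' Default per-group generator parameters
#'
#' Group-wise biomarker, ALPS and demographic distributions for a
#' three-group AD cohort (cognitively normal controls, MCI due to AD,
#' AD dementia). Continuous variables are summarized as mean/SD; binary
#' variables as fractions.
#'
#' @return Tibble, one row per group.
#' @export
default_cohort_groups <- function() {
  tibble::tibble(
    group = c("NC", "AD-MCI", "AD-D"),
    n = c(68L, 75L, 67L),
    folate_mean = c(12.22, 10.92, 8.66), folate_sd = c(5.0, 4.6, 3.4),
    b12_mean = c(595, 528, 497), b12_sd = c(220, 200, 180),
    hcy_mean = c(16.2, 16.8, 18.0), hcy_sd = c(4.5, 4.8, 4.8),
    alps_mean = c(1.26, 1.21, 1.16), alps_sd = c(0.13, 0.14, 0.15),
    age_mean = c(60, 64, 63), age_sd = c(7, 9, 8),
    edu_mean = c(8.8, 9.0, 7.5), edu_sd = c(3.8, 4.0, 3.8),
    bmi_mean = c(23.3, 23.1, 22.5), bmi_sd = c(2.4, 2.7, 2.6),
    female_frac = c(0.632, 0.560, 0.597),
    apoe4_frac = c(0.143, 0.288, 0.453),
    hypertension_frac = c(0.279, 0.380, 0.318),
    diabetes_frac = c(0.059, 0.147, 0.075),
    hyperlipidemia_frac = c(0.235, 0.173, 0.119),
    smoking_frac = c(0.162, 0.187, 0.254),
    drinking_frac = c(0.221, 0.240, 0.328)
  )
}

#' Default cross-variable correlation targets
#'
#' Within-group correlations on the standardized (latent) scale between
#' biomarkers, the ALPS index and the cognitive domain scores. Unlisted
#' pairs default to 0 except the inter-domain cognitive block
#' (`cognitive_r`), reflecting the strong positive manifold of cognitive
#' tests.
#'
#' @param folate_alps,hcy_alps,folate_hcy Biomarker/ALPS targets.
#' @param cognitive_r Common correlation among cognitive domain scores.
#' @return A named correlation matrix over the generator's continuous
#'   variables.
#' @export
default_correlations <- function(folate_alps = 0.212, hcy_alps = -0.299,
                                 folate_hcy = -0.30, cognitive_r = 0.40) {
  vars <- c("folate", "b12", "hcy", "alps", cognitive_domains())
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("folate", "alps", folate_alps)
  set_r("hcy", "alps", hcy_alps)
  set_r("folate", "hcy", folate_hcy)
  set_r("folate", "mmse", 0.258)
  set_r("folate", "moca", 0.238)
  set_r("folate", "executive", 0.238)
  set_r("folate", "memory", 0.15)
  set_r("alps", "mmse", 0.20)
  set_r("alps", "moca", 0.282)
  set_r("alps", "memory", 0.339)
  set_r("alps", "executive", 0.283)
  set_r("alps", "attention", 0.245)
  set_r("alps", "visuospatial", 0.255)
  cg <- cognitive_domains()
  for (i in seq_along(cg)) for (j in seq_along(cg)) {
    if (i < j) set_r(cg[i], cg[j], cognitive_r)
  }
  R
}

cognitive_domains <- function() {
  c("mmse", "moca", "memory", "executive", "attention", "visuospatial",
    "processing_speed")
}

#' Default per-group latent cognitive shifts
#'
#' Mean shifts of the domain scores, in control-group SD units, applied per
#' group before mapping to raw test scores.
#'
#' @return Matrix: groups x domains.
#' @export
default_domain_shifts <- function() {
  m <- rbind(
    "NC" = c(0, 0, 0, 0, 0, 0, 0),
    "AD-MCI" = c(-3.0, -1.42, -1.51, -0.38, -0.16, 0.10, -0.08),
    "AD-D" = c(-14.0, -5.10, -2.64, -1.05, -1.44, -3.22, -1.86)
  )
  colnames(m) <- cognitive_domains()
  m
}

#' Synthetic cohort specification
#'
#' Validates and bundles everything [make_cohort()] needs: per-group
#' distributions, the within-group correlation structure (a Gaussian copula
#' on the standardized scale), the planted folate-by-ALPS interaction on
#' memory and MoCA, and the missing-data rate.
#'
#' @param groups Tibble as [default_cohort_groups()] (any subset of rows /
#'   custom groups is allowed).
#' @param correlations Correlation matrix as [default_correlations()].
#' @param norms Raw-score norms as [default_test_norms()].
#' @param domain_shifts Matrix of per-group latent shifts; rows must cover
#'   all groups (missing groups shift by 0).
#' @param interaction_beta Named vector: standardized folate-by-ALPS effect
#'   added to the `memory` and `moca` latents.
#' @param missing_rate Per-test probability of a missing raw score (MCAR).
#' @param item_noise_sd SD of the within-domain item deviations for
#'   multi-test domains (deviations are centered per subject, so the domain
#'   mean of item Z-scores equals the latent domain score).
#' @param lognormal_biomarkers If `TRUE`, folate/B12/homocysteine marginals
#'   are log-normal with moment-matched mean and SD (right-skewed, as
#'   clinical assays typically are); default Gaussian.
#' @param seed Default seed for [make_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_cohort_groups(),
                        correlations = default_correlations(),
                        norms = default_test_norms(),
                        domain_shifts = default_domain_shifts(),
                        interaction_beta = c(memory = 0.17, moca = 0.184),
                        missing_rate = 0,
                        item_noise_sd = 0.5,
                        lognormal_biomarkers = FALSE,
                        seed = 1L) {
  groups <- tibble::as_tibble(groups)
  if (any(groups$n <= 0)) stop("group counts must be positive")
  sds <- dplyr::select(groups, dplyr::ends_with("_sd"))
  if (any(as.matrix(sds) <= 0)) stop("all SDs must be positive")
  fr <- dplyr::select(groups, dplyr::ends_with("_frac"))
  if (any(as.matrix(fr) < 0 | as.matrix(fr) > 1))
    stop("fractions must lie in [0, 1]")
  stopifnot(missing_rate >= 0, missing_rate <= 1, item_noise_sd >= 0)

  vars <- c("folate", "b12", "hcy", "alps", cognitive_domains())
  if (!identical(dim(correlations), c(length(vars), length(vars))) ||
      !all(rownames(correlations) == vars))
    stop("`correlations` must be a named matrix over: ",
         paste(vars, collapse = ", "))
  off <- correlations[upper.tri(correlations)]
  if (any(abs(off) >= 1)) stop("target correlations must lie in (-1, 1)")
  check_positive_definite(correlations)

  if (!all(names(interaction_beta) %in% c("memory", "moca")))
    stop("`interaction_beta` entries must be named 'memory' and/or 'moca'")

  structure(list(groups = groups, correlations = correlations,
                 norms = tibble::as_tibble(norms),
                 domain_shifts = domain_shifts,
                 interaction_beta = interaction_beta,
                 missing_rate = missing_rate,
                 item_noise_sd = item_noise_sd,
                 lognormal_biomarkers = lognormal_biomarkers,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Cholesky-based PD check; on failure, name the pair of variables loading
# most strongly on the offending (most negative) eigendirection.
check_positive_definite <- function(R) {
  ok <- !inherits(try(chol(R), silent = TRUE), "try-error")
  if (ok) return(invisible(TRUE))
  eg <- eigen(R, symmetric = TRUE)
  v <- abs(eg$vectors[, which.min(eg$values)])
  pair <- rownames(R)[order(v, decreasing = TRUE)[1:2]]
  stop("target correlation matrix is not positive definite; the pair (",
       pair[1], ", ", pair[2],
       ") loads most strongly on the offending direction")
}

#' Generate a synthetic participant cohort
#'
#' Draws, per group, a multivariate Gaussian on the standardized scale with
#' the specified cross-variable correlations, plants the folate-by-ALPS
#' interaction on the memory and MoCA latents
#' (`y <- y + beta * z(folate) * z(ALPS)` after the main-effect structure),
#' applies the per-group latent shifts, and maps latents to raw units:
#' biomarkers/ALPS/demographics by `mean + sd * z`, cognitive tests by
#' inverting the control-referenced Z-score map (timed tests with a sign
#' flip, so larger raw times mean worse performance). Binary columns are
#' Bernoulli draws at the specified fractions and missingness is applied
#' completely at random per test.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. Output is
#'   deterministic for a fixed spec + seed.
#' @return A tibble, one row per subject, with demographics, vascular risk
#'   flags, APOE e4 carrier status, biomarkers, left/right/mean ALPS, raw
#'   scores of the 11 cognitive tests plus ADL and CDR. The norms used for
#'   the inverse Z map are attached as `attr(, "norms")` and a column
#'   data dictionary as `attr(, "dictionary")`.
#' @export
#' @examples
#' coh <- make_cohort(cohort_spec(missing_rate = 0), seed = 7)
#' dplyr::count(coh, group)
make_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  L <- chol(spec$correlations)
  vars <- rownames(spec$correlations)
  battery <- cognitive_battery()

  rows <- purrr::pmap_dfr(spec$groups, function(...) {
    g <- list(...)
    n <- g$n
    Z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
    colnames(Z) <- vars

    # planted moderation: interaction added on the standardized scale
    for (dom in names(spec$interaction_beta))
      Z[, dom] <- Z[, dom] +
        spec$interaction_beta[[dom]] * Z[, "folate"] * Z[, "alps"]

    shifts <- spec$domain_shifts
    if (g$group %in% rownames(shifts))
      Z[, colnames(shifts)] <- sweep(Z[, colnames(shifts), drop = FALSE],
                                     2, shifts[g$group, ], "+")

    to_raw <- function(z, m, s) {
      if (spec$lognormal_biomarkers) {
        sig2 <- log(1 + (s / m)^2)
        exp(log(m) - sig2 / 2 + sqrt(sig2) * z)
      } else m + s * z
    }
    alps_raw <- g$alps_mean + g$alps_sd * Z[, "alps"]
    lr_half <- stats::rnorm(n, sd = 0.02)  # small left/right asymmetry

    out <- tibble::tibble(
      group = g$group,
      age = round(g$age_mean + g$age_sd * Z_indep(n), 1),
      sex = ifelse(stats::runif(n) < g$female_frac, "female", "male"),
      education = pmax(0, round(g$edu_mean + g$edu_sd * Z_indep(n))),
      bmi = round(g$bmi_mean + g$bmi_sd * Z_indep(n), 1),
      hypertension = as.integer(stats::runif(n) < g$hypertension_frac),
      diabetes = as.integer(stats::runif(n) < g$diabetes_frac),
      hyperlipidemia = as.integer(stats::runif(n) < g$hyperlipidemia_frac),
      smoking = as.integer(stats::runif(n) < g$smoking_frac),
      drinking = as.integer(stats::runif(n) < g$drinking_frac),
      apoe4 = as.integer(stats::runif(n) < g$apoe4_frac),
      folate = to_raw(Z[, "folate"], g$folate_mean, g$folate_sd),
      b12 = to_raw(Z[, "b12"], g$b12_mean, g$b12_sd),
      hcy = to_raw(Z[, "hcy"], g$hcy_mean, g$hcy_sd),
      alps_left = alps_raw + lr_half,
      alps_right = alps_raw - lr_half,
      alps = alps_raw
    )

    # raw test scores by inverting the control-referenced Z map; item
    # deviations are centered within each multi-test domain so the mean of
    # the item Z-scores equals the latent domain score
    for (dom in unique(battery$domain)) {
      tests <- battery$test[battery$domain == dom]
      tests <- tests[tests %in% spec$norms$test]
      if (!length(tests)) next
      k <- length(tests)
      # global tests (MMSE, MoCA) are single-test measures with their own
      # latents, never composited, so they carry no item deviations
      e <- if (k > 1 && dom != "global") {
        e0 <- matrix(stats::rnorm(n * k, sd = spec$item_noise_sd), n)
        e0 - rowMeans(e0)  # centered per subject: item mean == latent
      } else matrix(0, n, k)
      for (ti in seq_len(k)) {
        test <- tests[ti]
        lat <- if (dom == "global") Z[, test] else Z[, dom]
        z_item <- lat + e[, ti]
        nm <- spec$norms[spec$norms$test == test, ]
        tb <- battery$time_based[battery$test == test]
        out[[test]] <- nm$nc_mean + nm$nc_sd * (if (tb) -z_item else z_item)
      }
    }

    # functional measures: carried through, never composited
    out$adl <- switch(g$group,
                      "NC" = pmax(20, round(20 + abs(stats::rnorm(n, sd = 1)))),
                      "AD-MCI" = pmax(20, round(21.5 + stats::rnorm(n, sd = 2))),
                      pmax(20, round(32 + stats::rnorm(n, sd = 7))))
    out$cdr <- switch(g$group,
                      "NC" = rep(0, n),
                      "AD-MCI" = rep(0.5, n),
                      sample(c(1, 2, 3), n, replace = TRUE,
                             prob = c(0.6, 0.3, 0.1)))
    out
  })

  if (spec$missing_rate > 0) {
    for (test in spec$norms$test) {
      miss <- stats::runif(nrow(rows)) < spec$missing_rate
      rows[[test]][miss] <- NA_real_
    }
  }

  rows <- dplyr::mutate(rows,
                        subject_id = sprintf("S%03d", dplyr::row_number()),
                        .before = 1)
  attr(rows, "norms") <- spec$norms
  attr(rows, "dictionary") <- cohort_dictionary()
  class(rows) <- c("participant_table", class(rows))
  rows
}

# standard normal helper (independent of the copula draw)
Z_indep <- function(n) stats::rnorm(n)

cohort_dictionary <- function() {
  list(
    subject_id = "participant identifier",
    group = "diagnostic group: NC / AD-MCI / AD-D",
    age = "age, years",
    sex = "self-reported sex: female / male",
    education = "education, years",
    bmi = "body-mass index, kg/m^2",
    hypertension = "vascular risk flag, 0/1",
    diabetes = "vascular risk flag, 0/1",
    hyperlipidemia = "vascular risk flag, 0/1",
    smoking = "vascular risk flag, 0/1",
    drinking = "vascular risk flag, 0/1",
    apoe4 = "APOE e4 carrier, 0/1",
    folate = "serum folate, ng/mL",
    b12 = "serum vitamin B12, pg/mL",
    hcy = "serum homocysteine, umol/L",
    alps_left = "left DTI-ALPS index (dimensionless)",
    alps_right = "right DTI-ALPS index (dimensionless)",
    alps = "mean DTI-ALPS index (dimensionless)",
    mmse = "Mini-Mental State Examination, points",
    moca = "Montreal Cognitive Assessment, points",
    avlt = "Auditory Verbal Learning Test, points",
    scwt_c = "Stroop Color-Word Test C, seconds",
    tmt_b = "Trail Making Test B, seconds",
    vft = "Verbal Fluency Test, points",
    dst = "Digit Span Test, points",
    cdt = "Clock Drawing Test, points",
    tmt_a = "Trail Making Test A, seconds",
    scwt_a = "Stroop Test A, seconds",
    scwt_b = "Stroop Test B, seconds",
    adl = "Activities of Daily Living scale, points",
    cdr = "Clinical Dementia Rating, global score"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> groups: ",
      paste(sprintf("%s (n=%d)", x$groups$group, x$groups$n),
            collapse = ", "),
      "; interaction beta:",
      paste(sprintf("%s=%.3g", names(x$interaction_beta),
                    x$interaction_beta), collapse = ", "),
      "; missing rate ", x$missing_rate, "\n", sep = "")
  invisible(x)
}
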