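#' Cognitive test battery and domain assignment
#'
#' Maps each test to exactly one domain and marks the time-based tests
#' (whose Z-scores are sign-flipped so that higher always means better).
#' Global measures (MMSE, MoCA) are scored individually, never composited;
#' functional measures (ADL, CDR) are carried through unscored.
#'
#' @return Tibble with columns `test`, `domain`, `time_based`.
#' @export
cognitive_battery <- function() {
  tibble::tibble(
    test = c("mmse", "moca", "avlt", "scwt_c", "tmt_b", "vft", "dst",
             "cdt", "tmt_a", "scwt_a", "scwt_b", "adl", "cdr"),
    domain = c("global", "global", "memory", "executive", "executive",
               "executive", "attention", "visuospatial", "processing_speed",
               "processing_speed", "processing_speed", "functional",
               "functional"),
    time_based = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Control-group reference statistics
#'
#' Mean and SD of each raw test score over the control rows of a cohort
#' table; these define the Z-score map for the whole cohort.
#'
#' @param data Cohort tibble with a `group` column and raw test columns.
#' @param battery Battery tibble; only its non-functional tests present in
#'   `data` are used.
#' @param reference_group Group label defining the reference sample.
#' @return Tibble with columns `test`, `mean`, `sd`.
#' @export
reference_stats <- function(data, battery = cognitive_battery(),
                            reference_group = "NC") {
  nc <- data[data$group == reference_group, , drop = FALSE]
  if (nrow(nc) < 2)
    stop("need at least 2 '", reference_group,
         "' rows to compute reference statistics")
  tests <- battery$test[battery$domain != "functional" &
                          battery$test %in% names(data)]
  out <- purrr::map_dfr(tests, function(t) {
    x <- nc[[t]][!is.na(nc[[t]])]
    tibble::tibble(test = t, mean = mean(x), sd = stats::sd(x))
  })
  bad <- out$test[!is.finite(out$sd) | out$sd <= 0]
  if (length(bad))
    stop("reference SD is not positive for: ", paste(bad, collapse = ", "))
  out
}

#' Control-referenced Z-score
#'
#' @param raw Raw score(s).
#' @param mean,sd Reference mean and SD (SD must be positive).
#' @return `(raw - mean) / sd`.
#' @export
zscore <- function(raw, mean, sd) {
  if (any(sd <= 0)) stop("reference SD must be positive")
  (raw - mean) / sd
}

#' Orient a Z-score so higher means better
#'
#' Time-based tests (TMT-A/B, Stroop A/B/C) measure completion time, so
#' their Z-scores are negated; all other tests pass through unchanged.
#' Applying the orientation twice restores the original Z for timed tests.
#'
#' @param test Test identifier (must appear in `battery`).
#' @param z Z-score(s).
#' @param battery Battery tibble.
#' @return Oriented Z-score(s).
#' @export
orient_z <- function(test, z, battery = cognitive_battery()) {
  i <- match(test, battery$test)
  if (any(is.na(i))) stop("unknown test id: ",
                          paste(test[is.na(i)], collapse = ", "))
  sign <- ifelse(battery$time_based[i], -1, 1)  # length of `test`
  sign * z
}

#' Cronbach's alpha
#'
#' Internal consistency over the complete cases of an item matrix:
#' `alpha = k/(k-1) * (1 - sum(var_item) / var(total))`. With
#' `standardized = TRUE` the items are scaled to unit variance first
#' (equivalently, alpha from the average inter-item correlation).
#'
#' @param items Numeric matrix or data frame, one column per item.
#' @param standardized Use the standardized form.
#' @return Alpha, or `NA` for fewer than 2 items or insufficient complete
#'   cases.
#' @export
cronbach_alpha <- function(items, standardized = FALSE) {
  m <- as.matrix(items)
  if (ncol(m) < 2) return(NA_real_)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) return(NA_real_)
  if (standardized) m <- scale(m)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Score a cohort: Z-scores, orientation, domain composites
#'
#' Converts raw test scores to control-referenced Z-scores, orients them so
#' higher is better, and builds domain composites as the mean of constituent
#' oriented Z-scores with listwise deletion within domain: a subject missing
#' any constituent test gets a missing composite for that domain (other
#' domains are unaffected). Global measures yield `z_mmse` / `z_moca`
#' columns. Cronbach's alpha per multi-test domain (complete-case
#' covariances) is attached as `attr(, "alpha")`.
#'
#' @param data Cohort tibble (e.g. from [make_cohort()]).
#' @param battery Battery tibble.
#' @param reference Optional tibble `test`, `mean`, `sd`. By default the
#'   reference is computed from the `NC` rows of `data` via
#'   [reference_stats()], so synthetic cohorts are self-referencing; supply
#'   it explicitly for tables without control rows.
#' @param standardized_alpha Use standardized Cronbach's alpha.
#' @return `data` plus `z_<test>` columns and `composite_<domain>` columns.
#' @export
#' @examples
#' scored <- score_cognition(make_cohort(cohort_spec(), seed = 1))
#' attr(scored, "alpha")
score_cognition <- function(data, battery = cognitive_battery(),
                            reference = NULL, standardized_alpha = FALSE) {
  data <- tibble::as_tibble(data)
  if (is.null(reference)) reference <- reference_stats(data, battery)
  reference <- tibble::as_tibble(reference)
  # accept generator norms (nc_mean/nc_sd) as a reference table
  if (!"mean" %in% names(reference) && "nc_mean" %in% names(reference))
    reference <- dplyr::rename(reference, mean = "nc_mean", sd = "nc_sd")
  tests <- intersect(reference$test, names(data))
  if (!length(tests)) stop("no battery test columns found in `data`")

  for (t in tests) {
    ref <- reference[reference$test == t, ]
    data[[paste0("z_", t)]] <- orient_z(t, zscore(data[[t]], ref$mean,
                                                  ref$sd), battery)
  }

  domains <- setdiff(unique(battery$domain), c("global", "functional"))
  alphas <- list()
  for (dom in domains) {
    constituents <- intersect(battery$test[battery$domain == dom], tests)
    if (!length(constituents))
      stop("domain '", dom, "' has zero constituent tests in the data")
    zm <- as.matrix(data[paste0("z_", constituents)])
    comp <- rowMeans(zm)  # NA whenever any constituent is NA (listwise)
    data[[paste0("composite_", dom)]] <- comp
    alphas[[dom]] <- if (length(constituents) > 1)
      cronbach_alpha(zm, standardized = standardized_alpha) else NA_real_
  }
  attr(data, "alpha") <- tibble::tibble(domain = names(alphas),
                                        n_items = purrr::map_int(domains,
                                          ~sum(battery$domain == .x &
                                                 battery$test %in% tests)),
                                        alpha = unlist(alphas))
  attr(data, "reference") <- reference
  data
}
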