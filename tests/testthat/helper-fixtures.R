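# Shared fixtures: everything is generated in code at test time.

# Small single-region phantom: fast enough for repeated noisy fits.
mini_phantom_spec <- function(noise_sigma = 0, seed = 1L) {
  phantom_spec(
    grid_shape = c(12, 12, 12),
    regions = tibble::tibble(label = "proj", x = 0, y = 0, z = 0,
                             diameter_mm = 7,
                             dxx = 1.2e-3, dyy = 0.8e-3, dzz = 1.6e-3),
    noise_sigma = noise_sigma, seed = seed)
}

# Uniform isotropic phantom (no regions is disallowed, so one isotropic
# region matching the background).
isotropic_phantom_spec <- function(d = 0.8e-3) {
  phantom_spec(
    grid_shape = c(28, 28, 28),
    regions = tibble::tibble(label = c("proj_left", "proj_right",
                                       "assoc_left", "assoc_right"),
                             x = c(-8, 8, -8, 8), y = c(5, 5, -5, -5),
                             z = 0, diameter_mm = 8,
                             dxx = d, dyy = d, dzz = d),
    background = rep(d, 3))
}

# Brute-force lattice enumeration oracle for sphere masks.
enumerate_sphere <- function(center, diameter, shape, voxel, origin) {
  mask <- array(FALSE, shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      p <- origin + (c(i, j, k) - 1) * voxel
      mask[i, j, k] <- sum((p - center)^2) <= (diameter / 2)^2
    }
  mask
}

# Independent step-up FDR oracle (direct evaluation of the definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  adj
}

# Build a tensor_field directly from diagonal component arrays.
diag_tensor_field <- function(dxx, dyy, dzz, voxel_size = 1,
                              origin = NULL) {
  shape <- dim(dxx)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  D <- array(0, c(shape, 6))
  D[, , , 1] <- dxx
  D[, , , 4] <- dyy
  D[, , , 6] <- dzz
  alpsocm:::new_tensor_field(D, voxel_size, origin)
}

# Single analysis-set cohort spec (the AD group of the study design).
analysis_set_spec <- function(n = 142, folate_alps = 0.212,
                              interaction_beta = c(memory = 0.17,
                                                   moca = 0.184),
                              missing_rate = 0, seed = 1L) {
  groups <- default_cohort_groups()[2, ]  # AD-MCI row as the base
  groups$group <- "AD"
  groups$n <- as.integer(n)
  cohort_spec(groups = groups,
              correlations = default_correlations(folate_alps = folate_alps),
              interaction_beta = interaction_beta,
              missing_rate = missing_rate, seed = seed)
}

# Score a single-group cohort against the generator's own norms.
score_with_generator_norms <- function(cohort) {
  score_cognition(cohort, reference = attr(cohort, "norms"))
}
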