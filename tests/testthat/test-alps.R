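test_that("sphere masks match brute-force lattice enumeration", {
  grid <- list(shape = c(15L, 15L, 15L), voxel_size = 1,
               origin = c(-7, -7, -7))

  # 5 mm diameter on a 1 mm grid, center on a voxel center: 81 voxels
  m <- make_sphere_mask(c(0, 0, 0), 5, grid)
  expect_equal(sum(m), 81)

  # 1 mm diameter captures only the central voxel
  expect_equal(sum(make_sphere_mask(c(0, 0, 0), 1, grid)), 1)

  # random centers and diameters against the enumeration oracle
  set.seed(4)
  for (i in 1:25) {
    d <- runif(1, 1.8, 6)
    ctr <- runif(3, -3, 3)
    m <- make_sphere_mask(ctr, d, grid)
    expect_identical(m, enumerate_sphere(ctr, d, grid$shape,
                                         grid$voxel_size, grid$origin))
  }

  # half-voxel offset along x keeps reflection symmetry about x = 0.5,
  # which maps slice index i to 17 - i on this grid
  m2 <- make_sphere_mask(c(0.5, 0, 0), 5, grid)
  counts <- apply(m2, 1, sum)
  expect_equal(counts[2:15], rev(counts[2:15]))
  expect_equal(counts[1], 0)

  expect_error(make_sphere_mask(c(0, 0, 0), 40, grid), "exceeds")
  expect_error(make_sphere_mask(c(0.5, 0.5, 0.5), 0.4, grid), "empty")
})

test_that("ROI means are exact on constant and piecewise-constant fields", {
  shp <- c(24, 24, 24)
  uni <- diag_tensor_field(array(2e-3, shp), array(3e-3, shp),
                           array(4e-3, shp))
  rois <- roi_set()
  d <- extract_roi_diffusivities(uni, rois)
  expect_equal(d$dxx, rep(2e-3, 4))
  expect_equal(d$dyy, rep(3e-3, 4))
  expect_equal(d$dzz, rep(4e-3, 4))
  expect_equal(d$n_excluded, rep(0L, 4))

  # half-in/half-out sphere over two constant half-spaces: the ROI mean is
  # the voxel-count-weighted average
  shp <- c(16, 16, 16)
  dxx <- array(1e-3, shp)
  coords <- alpsocm:::grid_coordinates(shp, 1, -(shp - 1) / 2)
  xpos <- array(coords[, 1] > 0, shp)
  dxx[xpos] <- 5e-3
  tf <- diag_tensor_field(dxx, array(1e-3, shp), array(1e-3, shp))
  mask <- make_sphere_mask(c(0.5, 0, 0), 5, tf)
  expected <- mean(dxx[mask])
  n_lo <- sum(mask & !xpos)
  n_hi <- sum(mask & xpos)
  expect_equal(expected, (n_lo * 1e-3 + n_hi * 5e-3) / (n_lo + n_hi))

  # failed-fit voxels are dropped from the mean with a logged count
  dxx2 <- array(2e-3, shp)
  dxx2[8, 9, 8] <- NaN
  tf2 <- diag_tensor_field(dxx2, array(3e-3, shp), array(4e-3, shp))
  d2 <- extract_roi_diffusivities(tf2, roi_set(
    proj_left = c(-4, 1, 0), proj_right = c(4, 1, 0),
    assoc_left = c(-4, -1, 0), assoc_right = c(4, -1, 0), diameter_mm = 3))
  expect_equal(sum(d2$n_excluded), 0)  # NaN voxel outside these small ROIs

  tf3 <- diag_tensor_field(array(NaN, shp), array(3e-3, shp),
                           array(4e-3, shp))
  expect_error(extract_roi_diffusivities(tf3, roi_set(
    proj_left = c(-4, 1, 0), proj_right = c(4, 1, 0),
    assoc_left = c(-4, -1, 0), assoc_right = c(4, -1, 0),
    diameter_mm = 3)), "failed")
})

test_that("the ALPS ratio matches its hand-computed fixture values", {
  d <- tibble::tibble(
    roi = c("proj_left", "proj_right", "assoc_left", "assoc_right"),
    tract = c("projection", "projection", "association", "association"),
    hemisphere = c("left", "right", "left", "right"),
    n_voxels = 81L, n_excluded = 0L,
    dxx = 1.2e-3,
    dyy = c(0.8e-3, 0.8e-3, 1.6e-3, 1.6e-3),
    dzz = c(1.6e-3, 1.6e-3, 0.8e-3, 0.8e-3))
  r <- compute_alps(d)
  expect_equal(r$alps_left, 1.5)
  expect_equal(r$alps_right, 1.5)
  expect_equal(r$alps_mean, 1.5)
  expect_equal(r$alps_mean, (r$alps_left + r$alps_right) / 2)

  # isotropy: numerator equals denominator
  iso <- d
  iso$dyy <- iso$dzz <- 1.2e-3
  expect_equal(compute_alps(iso)$alps_mean, 1)

  # scale invariance
  for (k in c(0.1, 1, 10)) {
    dk <- d
    dk[, c("dxx", "dyy", "dzz")] <- dk[, c("dxx", "dyy", "dzz")] * k
    expect_equal(compute_alps(dk)$alps_mean, r$alps_mean)
  }

  # degenerate fit is an error, never silently clipped
  bad <- d
  bad$dyy[1] <- 0
  expect_error(compute_alps(bad), "non-positive")
})

test_that("mirroring the tensor field in x swaps the unilateral indices", {
  ph <- make_phantom(phantom_spec(), acquisition_scheme())
  tf <- fit_tensor(ph$dwi, method = "ols")
  # make the field asymmetric so the swap is informative
  tf$dxx[tf$dxx > 1e-3 & alpsocm:::grid_coordinates(dim(tf$dxx), 1,
    tf$origin)[, 1] < 0] <- 1.4e-3
  r <- compute_alps(extract_roi_diffusivities(tf, roi_set()))

  flip <- tf
  for (f in c("dxx", "dyy", "dzz")) {
    flip[[f]] <- flip[[f]][dim(flip[[f]])[1]:1, , ]
  }
  rf <- compute_alps(extract_roi_diffusivities(flip, roi_set()))
  expect_equal(rf$alps_left, r$alps_right)
  expect_equal(rf$alps_right, r$alps_left)
})

test_that("ROI sets enforce mirror symmetry and the RAS convention", {
  expect_error(roi_set(proj_left = c(-8, 5, 2)), "mirror")
  expect_error(roi_set(proj_left = c(8, 5, 0), proj_right = c(-8, 5, 0)),
               "x < 0")
  rs <- roi_set(diameter_mm = 4)
  expect_equal(rs$diameter_mm, 4)
  expect_equal(nrow(rs$rois), 4)
})

test_that("end-to-end phantom pipeline reproduces the analytic index", {
  r <- alps_pipeline(phantom_spec(), method = "wls")
  expect_equal(r$alps_left, 1.5, tolerance = 1e-6)
  expect_equal(r$alps_right, 1.5, tolerance = 1e-6)
  expect_equal(r$alps_mean, 1.5, tolerance = 1e-6)
  td <- tidy(r)
  expect_equal(td$alps, c(r$alps_left, r$alps_right, r$alps_mean))
  expect_s3_class(autoplot(r), "ggplot")
})
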