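test_that("acquisition scheme validates geometry", {
  sch <- acquisition_scheme()
  expect_length(sch$bvals, 69)
  expect_equal(sum(sch$bvals == 0), 5)
  dw <- sch$bvals > 0
  expect_true(all(abs(sqrt(rowSums(sch$bvecs[dw, ]^2)) - 1) < 1e-8))
  bad <- fibonacci_directions(64) * 1.01
  expect_error(acquisition_scheme(directions = bad), "unit norm")
})

test_that("noise-free signal follows the mono-exponential tensor model", {
  # isotropic D = 1e-3 * I: g' D g = 1e-3 for every unit g, so at b = 1000
  # every weighted volume is s0 * exp(-1) and every b=0 volume is s0
  spec <- isotropic_phantom_spec(d = 1e-3)
  sch <- acquisition_scheme(n_dirs = 12)
  ph <- make_phantom(spec, sch)
  s0 <- spec$s0
  b0 <- ph$dwi$data[, , , 1]
  expect_equal(max(abs(b0 - s0)), 0)
  for (v in 6:17) {
    expect_equal(max(abs(ph$dwi$data[, , , v] - s0 * exp(-1))), 0,
                 tolerance = 1e-12)
  }

  # anisotropic tensor sampled along z: exponent is b * Dzz = 1.6
  spec2 <- mini_phantom_spec()
  gz <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
              fibonacci_directions(9))
  sch2 <- acquisition_scheme(n_dirs = 12, n_b0 = 1, directions = gz)
  ph2 <- make_phantom(spec2, sch2)
  center <- ph2$dwi$data[7, 7, 7, ]
  expect_equal(center[2] / spec2$s0, exp(-1.6), tolerance = 1e-12)
  expect_equal(center[3] / spec2$s0, exp(-1.2), tolerance = 1e-12)
  expect_equal(center[4] / spec2$s0, exp(-0.8), tolerance = 1e-12)
})

test_that("noise-free signal is non-increasing in b for fixed direction", {
  g <- c(0.6, 0.64, sqrt(1 - 0.6^2 - 0.64^2))
  bs <- c(250, 500, 1000, 2000)
  sig <- sapply(bs, function(b) {
    sch <- acquisition_scheme(n_dirs = 7, n_b0 = 1, bval = b,
                              directions = rbind(g,
                                                 fibonacci_directions(6)))
    ph <- make_phantom(mini_phantom_spec(), sch)
    ph$dwi$data[7, 7, 7, 2]
  })
  s0 <- mini_phantom_spec()$s0
  expect_true(all(diff(c(s0, sig)) <= 0))
})

test_that("phantom output is deterministic for a fixed seed", {
  spec <- mini_phantom_spec(noise_sigma = 30, seed = 42L)
  sch <- acquisition_scheme(n_dirs = 12)
  a <- make_phantom(spec, sch)
  b <- make_phantom(spec, sch)
  expect_identical(a$dwi$data, b$dwi$data)
  c <- make_phantom(spec, sch, seed = 43L)
  expect_false(identical(a$dwi$data, c$dwi$data))
})

test_that("ground truth matches the painted region tensors", {
  spec <- mini_phantom_spec()
  ph <- make_phantom(spec, acquisition_scheme(n_dirs = 12))
  expect_equal(ph$truth$dxx[7, 7, 7], 1.2e-3)
  expect_equal(ph$truth$dyy[7, 7, 7], 0.8e-3)
  expect_equal(ph$truth$dzz[7, 7, 7], 1.6e-3)
  expect_equal(ph$truth$dxx[1, 1, 1], 0.8e-3)  # background
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(regions = tibble::tibble(
    label = "out", x = 14, y = 0, z = 0, diameter_mm = 8,
    dxx = 1e-3, dyy = 1e-3, dzz = 1e-3)), "exceeds")
  expect_error(phantom_spec(regions = tibble::tibble(
    label = c("a", "b"), x = c(0, 2), y = 0, z = 0, diameter_mm = 6,
    dxx = c(1e-3, 2e-3), dyy = 1e-3, dzz = 1e-3)), "conflicting tensors")
  expect_error(phantom_spec(regions = tibble::tibble(
    label = "neg", x = 0, y = 0, z = 0, diameter_mm = 6,
    dxx = -1e-3, dyy = 1e-3, dzz = 1e-3)), "positive")
  expect_error(phantom_spec(noise_sigma = -1))
})

test_that("rigid motion resampling has the expected exact cases", {
  spec <- mini_phantom_spec()
  sch <- acquisition_scheme(n_dirs = 6, n_b0 = 1)
  ph <- make_phantom(spec, sch)

  # zero trace is the identity
  still <- apply_motion(ph$dwi, motion_trace(7))
  expect_equal(still$data, ph$dwi$data)

  # uniform volume is invariant to interior translation
  uni <- ph$dwi
  uni$data[] <- 5
  tr <- motion_trace(7)
  tr$tx[3] <- 2.5
  moved <- apply_motion(uni, tr, pad = 5)
  expect_equal(moved$data[, , , 3], uni$data[, , , 3])

  # a one-voxel-edge integer shift moves an impulse to the neighbor index
  imp <- ph$dwi
  imp$data[] <- 0
  imp$data[6, 6, 6, 2] <- 1
  tr2 <- motion_trace(7)
  tr2$tx[2] <- spec$voxel_size_mm
  shifted <- apply_motion(imp, tr2)
  expect_equal(shifted$data[7, 6, 6, 2], 1)
  expect_equal(sum(shifted$data[, , , 2]), 1)

  # trace is carried as metadata; mismatched length errors
  expect_identical(shifted$motion, tr2)
  expect_error(apply_motion(ph$dwi, motion_trace(5)), "match")
})
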