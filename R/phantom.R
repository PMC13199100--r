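#' Phantom specification for synthetic DWI
#'
#' Describes a rectangular voxel grid in template (RAS) space populated with
#' spherical regions of known diagonal diffusion tensors, embedded in an
#' isotropic background. The default geometry realizes the fiber layout the
#' ALPS index assumes at the level of the lateral-ventricle body: projection
#' fibers (superior corona radiata) dominant along z, association fibers
#' (superior longitudinal fasciculus) dominant along y, with left/right
#' mirror pairs in x (x < 0 is left).
#'
#' @param grid_shape Integer length-3: voxels per axis.
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param regions Tibble with columns `label`, `x`, `y`, `z` (center, mm),
#'   `diameter_mm`, `dxx`, `dyy`, `dzz` (tensor diagonal, mm^2/s).
#' @param background Length-3 tensor diagonal for non-region voxels, mm^2/s.
#' @param s0 Unweighted signal amplitude.
#' @param noise_sigma Rician noise scale (same units as `s0`); 0 = noise-free.
#' @param seed Integer seed used by [make_phantom()].
#'
#' @details The grid is centered on the origin: voxel centers run from
#'   `-(n-1)/2 * voxel_size` to `+(n-1)/2 * voxel_size` per axis. With the
#'   default tensors (projection diag(1.2, 0.8, 1.6)e-3, association
#'   diag(1.2, 1.6, 0.8)e-3 mm^2/s) the analytic ALPS index is
#'   mean(1.2, 1.2)/mean(0.8, 0.8) = 1.5 in both hemispheres. These are
#'   hand-computable fixture values, not literature diffusivities.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size_mm = 1,
                         regions = default_phantom_regions(),
                         background = c(0.8e-3, 0.8e-3, 0.8e-3),
                         s0 = 1000,
                         noise_sigma = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            voxel_size_mm > 0, length(background) == 3,
            all(background > 0), s0 > 0, noise_sigma >= 0)
  regions <- tibble::as_tibble(regions)
  need <- c("label", "x", "y", "z", "diameter_mm", "dxx", "dyy", "dzz")
  if (!all(need %in% names(regions)))
    stop("`regions` must have columns: ", paste(need, collapse = ", "))
  if (any(regions$diameter_mm <= 0)) stop("region diameters must be positive")
  if (any(regions[, c("dxx", "dyy", "dzz")] <= 0))
    stop("all tensor diagonals must be strictly positive")

  origin <- -(grid_shape - 1) / 2 * voxel_size_mm
  lo <- origin
  hi <- origin + (grid_shape - 1) * voxel_size_mm
  r <- regions$diameter_mm / 2
  ctr <- as.matrix(regions[, c("x", "y", "z")])
  for (ax in 1:3) {
    if (any(ctr[, ax] - r < lo[ax]) || any(ctr[, ax] + r > hi[ax]))
      stop("region sphere '", regions$label[which.max(abs(ctr[, ax]))],
           "' exceeds the voxel grid")
  }
  # overlapping spheres with different tensors are ambiguous
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d < r[i] + r[j]) {
        same <- all(abs(unlist(regions[i, c("dxx", "dyy", "dzz")]) -
                        unlist(regions[j, c("dxx", "dyy", "dzz")])) < 1e-15)
        if (!same)
          stop("regions '", regions$label[i], "' and '", regions$label[j],
               "' overlap with conflicting tensors")
      }
    }
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 origin = origin, regions = regions,
                 background = as.numeric(background), s0 = s0,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom regions
#'
#' Two mirror pairs: projection-fiber spheres (z-dominant tensor) and
#' association-fiber spheres (y-dominant tensor).
#' @param diameter_mm Region sphere diameter.
#' @return A tibble suitable for [phantom_spec()].
#' @export
default_phantom_regions <- function(diameter_mm = 8) {
  tibble::tibble(
    label = c("proj_left", "proj_right", "assoc_left", "assoc_right"),
    x = c(-8, 8, -8, 8),
    y = c(5, 5, -5, -5),
    z = 0,
    diameter_mm = diameter_mm,
    dxx = 1.2e-3,
    dyy = c(0.8e-3, 0.8e-3, 1.6e-3, 1.6e-3),
    dzz = c(1.6e-3, 1.6e-3, 0.8e-3, 0.8e-3)
  )
}

#' Voxel-center coordinates of a grid
#' @param shape,voxel_size,origin Grid metadata.
#' @return An nvox x 3 matrix (x fastest), mm.
#' @keywords internal
grid_coordinates <- function(shape, voxel_size, origin) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * voxel_size)
  cbind(rep(ax[[1]], times = shape[2] * shape[3]),
        rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
        rep(ax[[3]], each = shape[1] * shape[2]))
}

#' Generate a DWI phantom with known ground truth
#'
#' Paints the region tensors into the grid and synthesizes the diffusion
#' signal per volume under the mono-exponential tensor model
#' `S = s0 * exp(-b * g' D g)`, optionally corrupted by Rician noise
#' (magnitude of a complex Gaussian perturbation), the standard noise model
#' for magnitude MRI.
#'
#' @param spec A [phantom_spec()].
#' @param scheme An [acquisition_scheme()].
#' @param seed Integer seed; defaults to `spec$seed`. Fixed seed gives
#'   bit-identical output.
#'
#' @return A list with `dwi` (class `dwi_dataset`: 4-D signal array plus
#'   scheme and grid metadata) and `truth` (class `tensor_field`, the
#'   ground-truth tensors painted into each voxel).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 0), acquisition_scheme())
#' dim(ph$dwi$data)
make_phantom <- function(spec, scheme, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "acq_scheme"))
  shape <- spec$grid_shape
  nvox <- prod(shape)
  coords <- grid_coordinates(shape, spec$voxel_size_mm, spec$origin)

  # per-voxel tensor as 6 unique components (xx, xy, xz, yy, yz, zz)
  D <- matrix(0, nvox, 6)
  D[, 1] <- spec$background[1]
  D[, 4] <- spec$background[2]
  D[, 6] <- spec$background[3]
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    inside <- (coords[, 1] - rg$x)^2 + (coords[, 2] - rg$y)^2 +
      (coords[, 3] - rg$z)^2 <= (rg$diameter_mm / 2)^2
    D[inside, 1] <- rg$dxx
    D[inside, 4] <- rg$dyy
    D[inside, 6] <- rg$dzz
  }

  # S = s0 * exp(-b g' D g); for the 6-component layout the quadratic form
  # is D . (gx^2, 2gxgy, 2gxgz, gy^2, 2gygz, gz^2)
  g <- scheme$bvecs
  q <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2) * scheme$bvals
  S <- spec$s0 * exp(-tcrossprod(D, q))  # nvox x nvol

  if (spec$noise_sigma > 0) {
    set.seed(seed)
    n1 <- matrix(stats::rnorm(length(S), sd = spec$noise_sigma), nrow(S))
    n2 <- matrix(stats::rnorm(length(S), sd = spec$noise_sigma), nrow(S))
    S <- sqrt((S + n1)^2 + n2^2)
  }

  dwi <- new_dwi_dataset(array(S, c(shape, length(scheme$bvals))), scheme,
                         spec$voxel_size_mm, spec$origin)
  truth <- new_tensor_field(array(D, c(shape, 6)), spec$voxel_size_mm,
                            spec$origin)
  list(dwi = dwi, truth = truth)
}

new_dwi_dataset <- function(data, scheme, voxel_size, origin, motion = NULL) {
  stopifnot(length(dim(data)) == 4,
            dim(data)[4] == length(scheme$bvals))
  structure(list(data = data, scheme = scheme, voxel_size = voxel_size,
                 origin = origin, motion = motion),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_dataset> ", paste(d[1:3], collapse = "x"), " voxels (",
      x$voxel_size, " mm), ", d[4], " volumes\n", sep = "")
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$grid_shape, collapse = "x"), " @ ",
      x$voxel_size_mm, " mm, ", nrow(x$regions), " regions, s0=", x$s0,
      ", noise_sigma=", x$noise_sigma, "\n", sep = "")
  invisible(x)
}
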