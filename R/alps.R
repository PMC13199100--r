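#' Spherical ROI voxel mask
#'
#' A voxel belongs to the sphere when its center lies within
#' `diameter_mm / 2` of the sphere center (no partial-volume weighting, so
#' the mask is exactly reproducible by lattice enumeration).
#'
#' @param center_mm Length-3 sphere center, mm (template space).
#' @param diameter_mm Sphere diameter, mm.
#' @param grid A `tensor_field`/`dwi_dataset`, or a list with elements
#'   `shape`, `voxel_size`, `origin`.
#' @return A logical 3-D array.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(), acquisition_scheme(n_dirs = 6))
#' sum(make_sphere_mask(c(0, 0, 0), 5, ph$truth))  # 81 on a 1 mm grid
make_sphere_mask <- function(center_mm, diameter_mm, grid) {
  g <- as_grid(grid)
  stopifnot(length(center_mm) == 3, diameter_mm > 0)
  lo <- g$origin
  hi <- g$origin + (g$shape - 1) * g$voxel_size
  if (any(center_mm - diameter_mm / 2 < lo) ||
      any(center_mm + diameter_mm / 2 > hi))
    stop("sphere at (", paste(center_mm, collapse = ", "),
         ") exceeds the voxel grid")
  coords <- grid_coordinates(g$shape, g$voxel_size, g$origin)
  d2 <- (coords[, 1] - center_mm[1])^2 + (coords[, 2] - center_mm[2])^2 +
    (coords[, 3] - center_mm[3])^2
  mask <- array(d2 <= (diameter_mm / 2)^2, g$shape)
  if (!any(mask))
    stop("empty sphere mask: diameter ", diameter_mm,
         " mm captures no voxel centers at this grid spacing; ",
         "refine the grid or recenter the sphere")
  mask
}

as_grid <- function(x) {
  if (inherits(x, "tensor_field"))
    list(shape = dim(x$D)[1:3], voxel_size = x$voxel_size, origin = x$origin)
  else if (inherits(x, "dwi_dataset"))
    list(shape = dim(x$data)[1:3], voxel_size = x$voxel_size,
         origin = x$origin)
  else {
    stopifnot(all(c("shape", "voxel_size", "origin") %in% names(x)))
    x
  }
}

#' ROI set for the ALPS computation
#'
#' Four spheres: projection-fiber (superior corona radiata) and
#' association-fiber (superior longitudinal fasciculus) ROIs in each
#' hemisphere. Left/right centers must mirror in x (x < 0 is left in RAS
#' template space).
#'
#' The default centers are placeholders consistent with the shipped phantom
#' geometry, not literature MNI coordinates; analyses of real template-space
#' maps must supply study-specific centers.
#'
#' @param proj_left,proj_right,assoc_left,assoc_right Length-3 centers, mm.
#' @param diameter_mm Sphere diameter (default 5 mm).
#' @param mirror_tol_mm Tolerated left/right mirror asymmetry.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(proj_left = c(-8, 5, 0), proj_right = c(8, 5, 0),
                    assoc_left = c(-8, -5, 0), assoc_right = c(8, -5, 0),
                    diameter_mm = 5, mirror_tol_mm = 0.5) {
  stopifnot(diameter_mm > 0)
  centers <- rbind(proj_left, proj_right, assoc_left, assoc_right)
  if (ncol(centers) != 3) stop("ROI centers must be length-3 coordinates")
  mirr <- function(a, b) {
    max(abs(a[1] + b[1]), abs(a[2] - b[2]), abs(a[3] - b[3]))
  }
  if (mirr(proj_left, proj_right) > mirror_tol_mm ||
      mirr(assoc_left, assoc_right) > mirror_tol_mm)
    stop("left/right ROI centers must mirror in x (tolerance ",
         mirror_tol_mm, " mm)")
  if (proj_left[1] >= 0 || assoc_left[1] >= 0)
    stop("left ROIs must have x < 0 (RAS convention)")
  structure(list(
    rois = tibble::tibble(
      roi = c("proj_left", "proj_right", "assoc_left", "assoc_right"),
      tract = c("projection", "projection", "association", "association"),
      hemisphere = c("left", "right", "left", "right"),
      x = centers[, 1], y = centers[, 2], z = centers[, 3]),
    diameter_mm = diameter_mm), class = "roi_set")
}

#' Mean axis-wise diffusivities per ROI
#'
#' Arithmetic mean of Dxx, Dyy and Dzz over the in-mask voxels of each ROI
#' sphere. Voxels with non-finite fitted components (failed fits) are
#' excluded from the mean and counted; an ROI whose voxels all failed is an
#' error.
#'
#' @param tensors A `tensor_field`.
#' @param rois A [roi_set()].
#' @return A tibble with one row per ROI: `roi`, `tract`, `hemisphere`,
#'   `n_voxels`, `n_excluded`, `dxx`, `dyy`, `dzz` (mm^2/s).
#' @export
extract_roi_diffusivities <- function(tensors, rois) {
  stopifnot(inherits(tensors, "tensor_field"), inherits(rois, "roi_set"))
  purrr::pmap_dfr(rois$rois, function(roi, tract, hemisphere, x, y, z) {
    mask <- make_sphere_mask(c(x, y, z), rois$diameter_mm, tensors)
    vx <- tensors$dxx[mask]
    vy <- tensors$dyy[mask]
    vz <- tensors$dzz[mask]
    ok <- is.finite(vx) & is.finite(vy) & is.finite(vz)
    if (!any(ok))
      stop("all voxels in ROI '", roi, "' have failed tensor fits")
    tibble::tibble(roi = roi, tract = tract, hemisphere = hemisphere,
                   n_voxels = sum(ok), n_excluded = sum(!ok),
                   dxx = mean(vx[ok]), dyy = mean(vy[ok]),
                   dzz = mean(vz[ok]))
  })
}

#' DTI-ALPS index
#'
#' Per hemisphere, the index is the ratio of the mean diffusivity along x
#' (perpendicular to both fiber populations, parallel to the perivascular
#' spaces at the lateral-ventricle body) to the mean diffusivity
#' perpendicular to each fiber tract:
#' \deqn{ALPS = \frac{mean(D_{x,proj}, D_{x,assoc})}{mean(D_{y,proj}, D_{z,assoc})}}
#' The whole-brain index is the mean of the two hemispheric indices. The
#' index is dimensionless and invariant to a global rescaling of all
#' diffusivities.
#'
#' @param diffusivities Tibble from [extract_roi_diffusivities()] (or with
#'   the same columns).
#' @return An object of class `alps_result`: list with `alps_left`,
#'   `alps_right`, `alps_mean` and the per-ROI diffusivity table.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   roi = c("proj_left", "proj_right", "assoc_left", "assoc_right"),
#'   tract = rep(c("projection", "association"), each = 2),
#'   hemisphere = rep(c("left", "right"), 2),
#'   n_voxels = 81, n_excluded = 0,
#'   dxx = 1.2e-3, dyy = c(0.8e-3, 0.8e-3, 1.6e-3, 1.6e-3),
#'   dzz = c(1.6e-3, 1.6e-3, 0.8e-3, 0.8e-3))
#' compute_alps(d)$alps_mean  # 1.5
compute_alps <- function(diffusivities) {
  d <- tibble::as_tibble(diffusivities)
  need <- c("tract", "hemisphere", "dxx", "dyy", "dzz")
  stopifnot(all(need %in% names(d)))
  one_side <- function(h) {
    proj <- d[d$tract == "projection" & d$hemisphere == h, ]
    assoc <- d[d$tract == "association" & d$hemisphere == h, ]
    if (nrow(proj) != 1 || nrow(assoc) != 1)
      stop("need exactly one projection and one association ROI per hemisphere")
    vals <- c(proj$dxx, assoc$dxx, proj$dyy, assoc$dzz)
    if (any(vals <= 0))
      stop("non-positive ROI diffusivity in ", h,
           " hemisphere: degenerate tensor fit")
    mean(c(proj$dxx, assoc$dxx)) / mean(c(proj$dyy, assoc$dzz))
  }
  left <- one_side("left")
  right <- one_side("right")
  structure(list(alps_left = left, alps_right = right,
                 alps_mean = (left + right) / 2,
                 diffusivities = d),
            class = "alps_result")
}

#' Phantom-to-ALPS convenience pipeline
#'
#' Chains [make_phantom()], [fit_tensor()] and [compute_alps()]; useful for
#' end-to-end validation against the phantom's analytic ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param scheme An [acquisition_scheme()].
#' @param rois A [roi_set()]; the default matches the default phantom.
#' @param method Tensor fit method.
#' @param drop_volumes Passed to [fit_tensor()].
#' @return An `alps_result` with the fitted `tensor_field` attached as
#'   attribute `"tensors"`.
#' @export
alps_pipeline <- function(spec, scheme = acquisition_scheme(),
                          rois = roi_set(), method = "wls",
                          drop_volumes = NULL) {
  ph <- make_phantom(spec, scheme)
  tf <- fit_tensor(ph$dwi, method = method, drop_volumes = drop_volumes)
  res <- compute_alps(extract_roi_diffusivities(tf, rois))
  attr(res, "tensors") <- tf
  res
}

#' @export
print.alps_result <- function(x, ...) {
  cat("<alps_result> left = ", signif(x$alps_left, 5), ", right = ",
      signif(x$alps_right, 5), ", mean = ", signif(x$alps_mean, 5), "\n",
      sep = "")
  invisible(x)
}
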