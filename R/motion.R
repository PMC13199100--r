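#' Rigid-body motion trace
#'
#' One row per acquired volume: three translations (mm) and three rotations
#' (radians), relative to the reference (first) volume, which must be the
#' zero transform.
#'
#' @param n_volumes Number of volumes; returns the zero (still) trace.
#' @param translations Optional n x 3 matrix, mm.
#' @param rotations Optional n x 3 matrix, radians.
#' @return A tibble of class `motion_trace` with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
#' @examples
#' motion_trace(5)
motion_trace <- function(n_volumes = NULL, translations = NULL,
                         rotations = NULL) {
  if (is.null(translations) && is.null(rotations)) {
    stopifnot(!is.null(n_volumes), n_volumes >= 1)
    translations <- matrix(0, n_volumes, 3)
    rotations <- matrix(0, n_volumes, 3)
  }
  if (is.null(translations)) translations <- matrix(0, nrow(rotations), 3)
  if (is.null(rotations)) rotations <- matrix(0, nrow(translations), 3)
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations))
  if (any(abs(c(translations[1, ], rotations[1, ])) > 0))
    stop("the first volume must be the zero transform (reference volume)")
  out <- tibble::tibble(tx = translations[, 1], ty = translations[, 2],
                        tz = translations[, 3], rx = rotations[, 1],
                        ry = rotations[, 2], rz = rotations[, 3])
  class(out) <- c("motion_trace", class(out))
  out
}

#' Framewise displacement
#'
#' Power-style FD: the sum of absolute frame-to-frame changes of the six
#' rigid-body parameters, with rotations converted to arc length on a sphere
#' of radius `rotation_radius_mm` (default 50 mm, a typical head radius).
#' The first volume has FD 0 by definition.
#'
#' @param trace A [motion_trace()].
#' @param rotation_radius_mm Radius for the rotation-to-displacement
#'   conversion, mm.
#' @return Numeric vector of per-volume FD, mm.
#' @export
#' @examples
#' tr <- motion_trace(3)
#' tr$tx[2] <- 1; tr$ty[2] <- 1; tr$tz[2] <- 1
#' compute_fd(tr)  # 0 3 0
compute_fd <- function(trace, rotation_radius_mm = 50) {
  stopifnot(inherits(trace, "motion_trace"), rotation_radius_mm > 0)
  p <- as.matrix(trace[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Motion quality control
#'
#' Applies three rule families to a motion trace:
#' \describe{
#'   \item{flag}{volumes with FD above `fd_flag_mm` or a frame-to-frame
#'     rotation change above `rot_flag_deg` are high-motion frames
#'     (strict `>`; a volume exactly at the threshold is not flagged);}
#'   \item{replace}{volumes whose absolute position (relative to the
#'     reference volume) exceeds `trans_replace_mm` translation or
#'     `rot_replace_deg` rotation on any axis are marked for replacement and
#'     should be dropped from the tensor fit;}
#'   \item{exclude}{the subject is excluded when the flagged fraction
#'     exceeds `flag_frac_exclude` or mean FD exceeds `mean_fd_exclude_mm`.}
#' }
#'
#' @param trace A [motion_trace()].
#' @param fd_flag_mm FD flag threshold, mm.
#' @param rot_flag_deg Rotation-delta flag threshold, degrees.
#' @param trans_replace_mm,rot_replace_deg Replacement thresholds.
#' @param flag_frac_exclude Maximum tolerated flagged fraction.
#' @param mean_fd_exclude_mm Maximum tolerated mean FD, mm.
#' @param rotation_radius_mm Passed to [compute_fd()].
#' @return An object of class `motion_qc`: per-volume FD and rotation
#'   series, flagged/replaced indices, mean FD, and the exclusion decision
#'   with its reason.
#' @export
motion_qc <- function(trace, fd_flag_mm = 1.5, rot_flag_deg = 2,
                      trans_replace_mm = 2, rot_replace_deg = 2,
                      flag_frac_exclude = 0.15, mean_fd_exclude_mm = 1.5,
                      rotation_radius_mm = 50) {
  thr <- c(fd_flag_mm, rot_flag_deg, trans_replace_mm, rot_replace_deg,
           flag_frac_exclude, mean_fd_exclude_mm, rotation_radius_mm)
  if (any(thr <= 0)) stop("all QC thresholds must be positive")
  stopifnot(inherits(trace, "motion_trace"))

  fd <- compute_fd(trace, rotation_radius_mm)
  rot <- as.matrix(trace[, c("rx", "ry", "rz")]) * 180 / pi
  rot_delta <- c(0, apply(abs(diff(rot)), 1, max))
  rot_abs <- apply(abs(rot), 1, max)
  trans_abs <- apply(abs(as.matrix(trace[, c("tx", "ty", "tz")])), 1, max)

  flagged <- which(fd > fd_flag_mm | rot_delta > rot_flag_deg)
  replaced <- which(trans_abs > trans_replace_mm | rot_abs > rot_replace_deg)

  n <- nrow(trace)
  frac <- length(flagged) / n
  mean_fd <- mean(fd)
  excluded <- frac > flag_frac_exclude || mean_fd > mean_fd_exclude_mm
  reason <- if (!excluded) NA_character_ else paste(c(
    if (frac > flag_frac_exclude)
      sprintf("flagged fraction %.1f%% > %.0f%%", 100 * frac,
              100 * flag_frac_exclude),
    if (mean_fd > mean_fd_exclude_mm)
      sprintf("mean FD %.2f mm > %.2f mm", mean_fd, mean_fd_exclude_mm)),
    collapse = "; ")

  structure(list(fd_series = fd, rotation_series = rot_delta,
                 flagged_volumes = flagged, replaced_volumes = replaced,
                 mean_fd = mean_fd, excluded = excluded, reason = reason,
                 n_volumes = n,
                 thresholds = list(fd_flag_mm = fd_flag_mm,
                                   rot_flag_deg = rot_flag_deg,
                                   trans_replace_mm = trans_replace_mm,
                                   rot_replace_deg = rot_replace_deg,
                                   flag_frac_exclude = flag_frac_exclude,
                                   mean_fd_exclude_mm = mean_fd_exclude_mm,
                                   rotation_radius_mm = rotation_radius_mm)),
            class = "motion_qc")
}

#' Apply rigid-body motion to a DWI dataset
#'
#' Resamples each volume by its rigid transform (rotation about the grid
#' center followed by translation) using trilinear interpolation; samples
#' falling outside the grid take `pad`. The trace is stored in the returned
#' dataset so downstream QC operates on known ground truth.
#'
#' @param dwi A `dwi_dataset`.
#' @param trace A [motion_trace()] with one row per volume.
#' @param pad Background value for out-of-grid samples.
#' @return A `dwi_dataset` with moved volumes and `motion = trace`.
#' @export
apply_motion <- function(dwi, trace, pad = 0) {
  stopifnot(inherits(dwi, "dwi_dataset"), inherits(trace, "motion_trace"))
  nvol <- dim(dwi$data)[4]
  if (nrow(trace) != nvol)
    stop("trace length (", nrow(trace), ") must match volume count (",
         nvol, ")")
  shape <- dim(dwi$data)[1:3]
  coords <- grid_coordinates(shape, dwi$voxel_size, dwi$origin)
  center <- dwi$origin + (shape - 1) / 2 * dwi$voxel_size
  pc <- sweep(coords, 2, center)  # coordinates relative to rotation center

  out <- dwi$data
  p <- as.matrix(trace)
  for (v in seq_len(nvol)) {
    if (all(p[v, ] == 0)) next
    R <- rotation_matrix(p[v, 4], p[v, 5], p[v, 6])
    # moved image I_v(x) = I_0(T^-1 x), T x = R (x - c) + c + t
    src <- sweep(pc, 2, p[v, 1:3]) %*% R  # (x - c - t) R = R^-1 (x - c - t)
    src <- sweep(src, 2, center, FUN = "+")
    out[, , , v] <- array(trilinear_sample(dwi$data[, , , v], src,
                                           dwi$voxel_size, dwi$origin, pad),
                          shape)
  }
  new_dwi_dataset(out, dwi$scheme, dwi$voxel_size, dwi$origin,
                  motion = trace)
}

rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# Trilinear interpolation of a 3-D array at arbitrary mm coordinates.
# Points outside the voxel-center bounding box fall back to `pad` through a
# one-voxel pad border.
trilinear_sample <- function(vol, pts_mm, voxel_size, origin, pad) {
  shape <- dim(vol)
  idx <- sweep(pts_mm, 2, origin) / voxel_size + 1  # fractional voxel index
  padded <- array(pad, shape + 2)
  padded[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)] <- vol

  outside <- idx[, 1] < 0 | idx[, 1] > shape[1] + 1 |
    idx[, 2] < 0 | idx[, 2] > shape[2] + 1 |
    idx[, 3] < 0 | idx[, 3] > shape[3] + 1
  idx[outside, ] <- 1  # placeholder; overwritten with pad below

  f <- floor(idx)
  w <- idx - f
  f <- f + 1  # shift into padded array
  f <- pmin(pmax(f, 1), matrix(shape + 1, nrow(f), 3, byrow = TRUE))

  d12 <- (shape[1] + 2) * (shape[2] + 2)
  base <- function(ox, oy, oz) {
    (f[, 1] + ox) + (f[, 2] + oy - 1) * (shape[1] + 2) +
      (f[, 3] + oz - 1) * d12
  }
  val <-
    padded[base(0, 0, 0)] * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    padded[base(1, 0, 0)] * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    padded[base(0, 1, 0)] * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    padded[base(1, 1, 0)] * w[, 1] * w[, 2] * (1 - w[, 3]) +
    padded[base(0, 0, 1)] * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    padded[base(1, 0, 1)] * w[, 1] * (1 - w[, 2]) * w[, 3] +
    padded[base(0, 1, 1)] * (1 - w[, 1]) * w[, 2] * w[, 3] +
    padded[base(1, 1, 1)] * w[, 1] * w[, 2] * w[, 3]
  val[outside] <- pad
  val
}

#' @export
print.motion_qc <- function(x, ...) {
  cat("<motion_qc> ", x$n_volumes, " volumes; mean FD = ",
      signif(x$mean_fd, 3), " mm; flagged ", length(x$flagged_volumes),
      ", replaced ", length(x$replaced_volumes), "; excluded: ",
      x$excluded, if (x$excluded) paste0(" (", x$reason, ")"), "\n",
      sep = "")
  invisible(x)
}
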