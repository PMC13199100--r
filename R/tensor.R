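#' Tensor field container with derived maps
#'
#' Stores the per-voxel symmetric diffusion tensor as 6 unique components in
#' the order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) and derives eigenvalue maps,
#' mean diffusivity and fractional anisotropy. Negative eigenvalues (which
#' can arise from noisy fits) are clamped to zero for the MD/FA maps only;
#' the raw tensor components are retained.
#'
#' @param D 4-D array: grid x 6 components.
#' @param voxel_size,origin Grid metadata (mm).
#' @return An object of class `tensor_field` with elements `D`, `lambda`
#'   (sorted, clamped eigenvalues), `md`, `fa`, `dxx`, `dyy`, `dzz`.
#' @keywords internal
new_tensor_field <- function(D, voxel_size, origin) {
  stopifnot(length(dim(D)) == 4, dim(D)[4] == 6)
  shape <- dim(D)[1:3]
  Dm <- matrix(D, ncol = 6)
  lam <- tensor_eigenvalues(Dm)
  lam_c <- pmax(lam, 0)
  md <- rowMeans(lam_c)
  num <- (lam_c[, 1] - md)^2 + (lam_c[, 2] - md)^2 + (lam_c[, 3] - md)^2
  den <- rowSums(lam_c^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  structure(list(
    D = D,
    lambda = array(lam_c, c(shape, 3)),
    md = array(md, shape),
    fa = array(fa, shape),
    dxx = array(Dm[, 1], shape),
    dyy = array(Dm[, 4], shape),
    dzz = array(Dm[, 6], shape),
    voxel_size = voxel_size, origin = origin
  ), class = "tensor_field")
}

# Analytic eigenvalues of symmetric 3x3 matrices, vectorized over rows of the
# 6-component layout (xx, xy, xz, yy, yz, zz). Smith's trigonometric method;
# returns decreasing order.
tensor_eigenvalues <- function(Dm) {
  a <- Dm[, 1]; d <- Dm[, 2]; e <- Dm[, 3]
  b <- Dm[, 4]; f <- Dm[, 5]; c <- Dm[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q  # non-finite inputs propagate NaN eigenvalues
  nz <- is.finite(p) & is.finite(q) &
    p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    ai <- a[nz] - q[nz]; bi <- b[nz] - q[nz]; ci <- c[nz] - q[nz]
    di <- d[nz]; ei <- e[nz]; fi <- f[nz]
    # det of (D - qI) / p
    detB <- (ai * (bi * ci - fi^2) - di * (di * ci - fi * ei) +
               ei * (di * fi - bi * ei)) / p[nz]^3
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

#' Fit the diffusion tensor per voxel
#'
#' Log-linear least-squares tensor estimation: regress `log(S)` on the
#' design `[1, -b*(gx^2, 2gxgy, 2gxgz, gy^2, 2gygz, gz^2)]` so the slope
#' coefficients are the 6 unique tensor components directly. With
#' `method = "wls"` (the default) a first OLS pass predicts the signal and
#' its square is used as the per-measurement weight, the usual variance
#' stabilization for log-transformed Rician data. Signals at or below zero
#' are clamped to `floor_frac * s0` (per-voxel mean b = 0 signal) before the
#' log so background voxels never raise an error.
#'
#' @param dwi A `dwi_dataset`.
#' @param scheme Acquisition scheme; defaults to the one stored in `dwi`.
#' @param method `"wls"` or `"ols"`.
#' @param floor_frac Signal floor as a fraction of the per-voxel b0 mean.
#' @param drop_volumes Optional integer indices of volumes to exclude from
#'   the fit (e.g. those marked for replacement by motion QC).
#' @return A `tensor_field` with Dxx/Dyy/Dzz, eigenvalue, MD and FA maps,
#'   plus attribute `"log_s0"` (the fitted log intercept map).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(12, 12, 12),
#'                    regions = default_phantom_regions(diameter_mm = 7)),
#'                    acquisition_scheme())
#' tf <- fit_tensor(ph$dwi, method = "ols")
#' max(abs(tf$dxx - ph$truth$dxx))
fit_tensor <- function(dwi, scheme = dwi$scheme,
                       method = c("wls", "ols"),
                       floor_frac = 1e-6,
                       drop_volumes = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_dataset"), inherits(scheme, "acq_scheme"))
  keep <- setdiff(seq_along(scheme$bvals), drop_volumes)
  b <- scheme$bvals[keep]
  g <- scheme$bvecs[keep, , drop = FALSE]
  if (length(keep) < 7 || !any(b == 0))
    stop("tensor fit needs >= 7 volumes including >= 1 b=0 volume")

  X <- cbind(1, -b * cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2))
  if (qr(X)$rank < 7)
    stop("degenerate direction set: tensor design matrix is rank-deficient")

  shape <- dim(dwi$data)[1:3]
  nvox <- prod(shape)
  S <- matrix(dwi$data, nvox)[, keep, drop = FALSE]

  s0vox <- rowMeans(S[, b == 0, drop = FALSE])
  floor_val <- pmax(floor_frac * s0vox, .Machine$double.xmin)
  S <- pmax(S, floor_val)  # recycles floor_val down columns
  Y <- log(S)

  qrX <- qr(X)
  B <- qr.coef(qrX, t(Y))  # 7 x nvox

  if (method == "wls") {
    W <- exp(2 * (X %*% B))  # predicted signal squared, nvol x nvox
    for (v in seq_len(nvox)) {
      sw <- sqrt(W[, v])
      B[, v] <- .lm.fit(X * sw, Y[v, ] * sw)$coefficients
    }
  }

  tf <- new_tensor_field(array(t(B[2:7, , drop = FALSE]), c(shape, 6)),
                         dwi$voxel_size, dwi$origin)
  attr(tf, "log_s0") <- array(B[1, ], shape)
  attr(tf, "method") <- method
  tf
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$D)[1:3], collapse = "x"),
      " voxels (", x$voxel_size, " mm); mean MD = ",
      signif(mean(x$md), 4), " mm^2/s, mean FA = ",
      signif(mean(x$fa), 3), "\n", sep = "")
  invisible(x)
}
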