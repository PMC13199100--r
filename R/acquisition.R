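#' Diffusion acquisition scheme
#'
#' Bundle b-values and unit gradient directions, one per acquired volume.
#' The default mirrors a common single-shell clinical protocol: 64 diffusion
#' directions at b = 1000 s/mm^2 preceded by 5 b = 0 volumes.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param bval b-factor for the weighted volumes, s/mm^2.
#' @param n_b0 Number of unweighted (b = 0) volumes, stored first.
#' @param directions Optional `n_dirs` x 3 matrix of unit vectors. When
#'   `NULL`, a deterministic spherical Fibonacci layout is used, which gives
#'   near-uniform angular coverage (adequate for tensor fitting, where only
#'   the second-order design rank matters).
#'
#' @return An object of class `acq_scheme`: a list with `bvals` (length-n
#'   numeric), `bvecs` (n x 3 matrix, zero rows for b = 0 volumes) and
#'   `n_b0`.
#' @export
#' @examples
#' sch <- acquisition_scheme()
#' length(sch$bvals)
acquisition_scheme <- function(n_dirs = 64, bval = 1000, n_b0 = 5,
                               directions = NULL) {
  stopifnot(n_dirs >= 6, n_b0 >= 0, bval > 0)
  if (is.null(directions)) directions <- fibonacci_directions(n_dirs)
  directions <- as.matrix(directions)
  if (nrow(directions) != n_dirs || ncol(directions) != 3)
    stop("`directions` must be an n_dirs x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("gradient directions must have unit norm (tolerance 1e-8)")
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), directions)
  new_acq_scheme(bvals, bvecs, n_b0)
}

new_acq_scheme <- function(bvals, bvecs, n_b0) {
  stopifnot(length(bvals) == nrow(bvecs), all(bvals >= 0))
  dw <- bvals > 0
  nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("non-b0 gradient directions must have unit norm (tolerance 1e-8)")
  structure(list(bvals = as.numeric(bvals), bvecs = unname(bvecs),
                 n_b0 = as.integer(n_b0)),
            class = "acq_scheme")
}

#' Spherical Fibonacci point set
#'
#' Deterministic, near-uniform unit vectors on the sphere; used as the
#' default gradient table.
#'
#' @param n Number of points.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n
  theta <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(theta), r * sin(theta), z)
  m / sqrt(rowSums(m^2))
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("<acq_scheme> ", length(x$bvals), " volumes: ", x$n_b0, " b=0 + ",
      sum(x$bvals > 0), " at b=", max(x$bvals), " s/mm^2\n", sep = "")
  invisible(x)
}
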