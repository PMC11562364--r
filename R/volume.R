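#' Construct a CTVolume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric(3) or scalar, mm per voxel (isotropic if scalar).
#' @param origin numeric(3), world coordinate (mm) of the center of the
#'   first voxel.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- ctVolume(array(0, c(10, 10, 10)), spacing = 0.3)
#' dim(v)
#' @export
ctVolume <- function(data, spacing = 0.3, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Map between voxel indices and world coordinates
#'
#' Voxel-center convention: the world position of the 1-based array index
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`. `worldToIndex`
#' returns fractional (continuous) 1-based indices.
#'
#' @param v a [CTVolume-class].
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param world n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 numeric matrix.
#' @export
indexToWorld <- function(v, idx) {
  idx <- rbindable(idx)
  sweep(sweep(idx - 1, 2L, v@spacing, `*`), 2L, v@origin, `+`)
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(v, world) {
  world <- rbindable(world)
  sweep(sweep(world, 2L, v@origin, `-`), 2L, v@spacing, `/`) + 1
}

rbindable <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else
    matrix(as.numeric(x), nrow = nrow(x), ncol = ncol(x))
}

#' Sample a volume at arbitrary world positions by trilinear interpolation
#'
#' @param v a [CTVolume-class].
#' @param world n x 3 matrix (or length-3 vector) of mm positions; all must
#'   lie inside the voxel-center bounding box of the grid.
#' @return numeric(n) interpolated intensities.
#' @export
sampleVolume <- function(v, world) {
  idx <- worldToIndex(v, world)
  d <- dim(v@data)
  if (any(idx < 1 - 1e-9) || any(sweep(idx, 2L, d, `-`) > 1e-9))
    stop("sample position outside the volume grid")
  idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3L, byrow = TRUE))
  i0 <- pmin(floor(idx), matrix(d - 1L, nrow(idx), 3L, byrow = TRUE))
  i0 <- pmax(i0, 1)
  f <- idx - i0
  out <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    out <- out + w * v@data[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}

#' Separable Gaussian filtering of a volume
#'
#' Convolves the intensity grid with an isotropic Gaussian of standard
#' deviation `sigma` (mm), axis by axis, using replicate padding at the
#' faces so constant regions are preserved. The kernel is truncated at
#' 4 sigma and normalized.
#'
#' @param v a [CTVolume-class].
#' @param sigma Gaussian scale in mm.
#' @return A [CTVolume-class] with the filtered grid (same geometry).
#' @export
gaussianFilterVolume <- function(v, sigma) {
  stopifnot(sigma > 0)
  a <- v@data
  d <- dim(a)
  for (ax in 1:3) {
    s_vox <- sigma / v@spacing[ax]
    r <- max(1L, ceiling(4 * s_vox))
    k <- exp(-(seq(-r, r))^2 / (2 * s_vox^2))
    k <- k / sum(k)
    n <- d[ax]
    # replicate-pad index vector, then fold kernel as a (n x (2r+1)) gather
    pad_idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    K <- matrix(0, n + 2L * r, n)
    for (j in seq_len(n)) K[j:(j + 2L * r), j] <- K[j:(j + 2L * r), j] + k
    # collapse padded rows onto source rows
    M <- matrix(0, n, n)
    for (p in seq_len(n + 2L * r)) M[pad_idx[p], ] <- M[pad_idx[p], ] + K[p, ]
    a <- filterAxis(a, M, ax)
  }
  new("CTVolume", data = a, spacing = v@spacing, origin = v@origin)
}

# apply n x n smoothing matrix M along axis ax of 3D array a (a' = M^T gather)
filterAxis <- function(a, M, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  m2 <- crossprod(M, m)
  ap2 <- array(m2, dim = d[perm])
  aperm(ap2, order(perm))
}
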