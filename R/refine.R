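#' Parameters for sub-voxel path refinement
#'
#' Each chain node is refined over a rectangular grid of offsets
#' `gridStep * (x, y, z)` with integer `x, y, z` in
#' `[-gridHalf, gridHalf]` (343 offsets at the defaults: 0.12 mm step,
#' half-extent 3, i.e. a +/- 0.36 mm window). Grid candidates are scored by
#' `-G_sigma(I(c))` (the Gaussian blob response of the image at scale
#' `sigma = 0.3` mm) plus a distance penalty with weights `alpha10 = 50`
#' (too short, per mm) and `alpha11 = 20` (too long, per mm), accumulated
#' by the same beam search as the voxel-level localization.
#'
#' @param gridStep grid step in mm (alpha8).
#' @param gridHalf integer half-extent of grid indices (alpha9).
#' @param sigma Gaussian blob-response scale in mm.
#' @param alpha10,alpha11 distance-penalty weights per mm.
#' @param beamWidth beam width P.
#' @return A list of class `RefineParams`.
#' @export
refineParams <- function(gridStep = 0.12, gridHalf = 3L, sigma = 0.3,
                         alpha10 = 50, alpha11 = 20, beamWidth = 10L) {
  stopifnot(gridStep > 0, gridHalf >= 1, sigma > 0, beamWidth >= 1)
  structure(list(gridStep = gridStep, gridHalf = as.integer(gridHalf),
                 sigma = sigma, alpha10 = alpha10, alpha11 = alpha11,
                 beamWidth = as.integer(beamWidth)),
            class = "RefineParams")
}

#' Gaussian blob response of a volume at arbitrary points
#'
#' Value of the volume convolved with an isotropic Gaussian of scale
#' `sigma`, evaluated exactly at the (sub-voxel) query position: the
#' response is the Gaussian-weighted average of the voxel intensities in a
#' 4-sigma window around the point, with the kernel centred on the query
#' position itself and normalized over the in-volume support. Evaluating
#' the continuous kernel at the query point keeps the response smooth in
#' the position (a trilinearly interpolated discrete filter is piecewise
#' multilinear and peaks only at voxel centres, which would pin sub-voxel
#' refinement to the voxel grid). At voxel centres the response coincides
#' with the separable discrete filter of [gaussianFilterVolume()]. A
#' constant volume returns the constant everywhere (normalized kernel) and
#' the response is linear in the image.
#'
#' @param v a [CTVolume-class].
#' @param points n x 3 matrix (or numeric(3)) of mm positions inside the
#'   volume.
#' @param sigma Gaussian scale in mm.
#' @return numeric(n).
#' @export
blobResponse <- function(v, points, sigma = 0.3) {
  points <- rbindable(points)
  d <- dim(v@data)
  idx <- worldToIndex(v, points)
  if (any(idx < 1 - 1e-9) || any(sweep(idx, 2L, d, `-`) > 1e-9))
    stop("blob-response position outside the volume grid")
  r <- pmax(1L, ceiling(4 * sigma / v@spacing))
  out <- numeric(nrow(points))
  for (q in seq_len(nrow(points))) {
    ctr <- idx[q, ]
    lo <- pmax(floor(ctr) - r, 1L)
    hi <- pmin(ceiling(ctr) + r, d)
    wx <- exp(-((seq(lo[1], hi[1]) - ctr[1]) * v@spacing[1])^2 /
              (2 * sigma^2))
    wy <- exp(-((seq(lo[2], hi[2]) - ctr[2]) * v@spacing[2])^2 /
              (2 * sigma^2))
    wz <- exp(-((seq(lo[3], hi[3]) - ctr[3]) * v@spacing[3])^2 /
              (2 * sigma^2))
    block <- v@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    w <- wx %o% wy %o% wz
    out[q] <- sum(block * w) / sum(w)
  }
  out
}

#' Sub-voxel refinement of an electrode chain
#'
#' Runs a level-wise beam search over per-node offset grids (see
#' [refineParams()]): level `i` candidates are the grid around chain node
#' `i`; the cost of a grid candidate is its negative Gaussian blob response
#' plus a penalty on the deviation of its distance from the previously
#' refined node from the expected gap. The first node has no predecessor,
#' so its distance term is referenced to its (unrefined) successor; for a
#' single-node chain the distance term is dropped. Grid points falling
#' outside the volume are clipped away with a warning.
#'
#' @param v the [CTVolume-class] the chain was localized in.
#' @param path an [ElectrodePath-class] (voxel-level).
#' @param spec the [EASpec-class] of the array.
#' @param rp a [refineParams()] list.
#' @return An [ElectrodePath-class] with sub-voxel node positions; the
#'   `steps` breakdown holds the blob term in `costI` and the distance
#'   term in `costS`.
#' @export
refinePath <- function(v, path, spec, rp = refineParams()) {
  nodes <- path@nodes
  k <- nrow(nodes)
  offs <- as.matrix(expand.grid(x = -rp$gridHalf:rp$gridHalf,
                                y = -rp$gridHalf:rp$gridHalf,
                                z = -rp$gridHalf:rp$gridHalf)) * rp$gridStep
  grids <- vector("list", k)
  resp <- vector("list", k)
  d <- dim(v@data)
  loW <- v@origin
  hiW <- v@origin + (d - 1) * v@spacing
  clipped <- FALSE
  for (i in seq_len(k)) {
    g <- sweep(offs, 2L, nodes[i, ], `+`)
    inside <- g[, 1] >= loW[1] & g[, 1] <= hiW[1] &
              g[, 2] >= loW[2] & g[, 2] <= hiW[2] &
              g[, 3] >= loW[3] & g[, 3] <= hiW[3]
    if (!all(inside)) clipped <- TRUE
    g <- g[inside, , drop = FALSE]
    if (nrow(g) == 0L)
      stop("refinement grid for node ", i, " lies entirely outside the volume")
    grids[[i]] <- g
    resp[[i]] <- blobResponse(v, g, rp$sigma)
  }
  if (clipped)
    warning("refinement grid clipped at volume bounds for some nodes")
  dstPen <- function(dist, gap) refineDstPenalty(dist - gap, rp)
  # level 1: blob term plus (for multi-node chains) a distance term
  # referenced to the unrefined successor
  cost1 <- -resp[[1]]
  s1 <- rep(0, nrow(grids[[1]]))
  if (k >= 2L) {
    d1 <- sqrt(colSums((t(grids[[1]]) - nodes[2, ])^2))
    s1 <- dstPen(d1, gapFromBase(spec, 1L))
    cost1 <- cost1 + s1
  }
  beams <- vector("list", k)
  beam <- pruneBeam(data.frame(cost = cost1,
                               last = seq_len(nrow(grids[[1]])),
                               parent = NA_integer_), rp$beamWidth)
  beams[[1]] <- beam
  for (i in seq.int(2L, length.out = max(0L, k - 1L))) {
    gap <- gapFromBase(spec, i - 1L)
    prevPts <- grids[[i - 1L]][beam$last, , drop = FALSE]
    m <- nrow(grids[[i]])
    distM <- sqrtSafe(outer(rowSums(prevPts^2), rowSums(grids[[i]]^2), `+`) -
                      2 * prevPts %*% t(grids[[i]]))
    pen <- dstPen(distM, gap)
    costM <- beam$cost + pen + rep(-resp[[i]], each = nrow(beam))
    nb <- data.frame(cost = as.numeric(costM),
                     last = rep(seq_len(m), each = nrow(beam)),
                     parent = rep(seq_len(nrow(beam)), m))
    beam <- pruneBeam(nb, rp$beamWidth)
    beams[[i]] <- beam
  }
  # backtrack the best chain through the per-level beams
  rows <- integer(k)
  best <- which.min(beam$cost)
  rows[k] <- beam$last[best]
  par <- beam$parent[best]
  if (k >= 2L) {
    for (i in seq.int(k - 1L, 1L)) {
      rows[i] <- beams[[i]]$last[par]
      par <- beams[[i]]$parent[par]
    }
  }
  refined <- t(vapply(seq_len(k), function(i) grids[[i]][rows[i], ],
                      numeric(3)))
  # per-step breakdown along the selected chain
  blob <- vapply(seq_len(k), function(i) -resp[[i]][rows[i]], 0)
  dterm <- numeric(k)
  if (k >= 2L) {
    dterm[1] <- dstPen(sqrt(sum((refined[1, ] - nodes[2, ])^2)),
                       gapFromBase(spec, 1L))
    for (i in 2:k)
      dterm[i] <- dstPen(sqrt(sum((refined[i, ] - refined[i - 1L, ])^2)),
                         gapFromBase(spec, i - 1L))
  }
  steps <- data.frame(costI = blob, costS = dterm, costR = 0,
                      total = blob + dterm)
  new("ElectrodePath", nodes = unname(refined), cost = min(beam$cost),
      steps = steps, complete = path@complete)
}

# keep the P lowest-cost rows, stable in generation order; skips sorting
# when the beam already fits
pruneBeam <- function(df, P) {
  if (nrow(df) <= P) return(df)
  nonfin <- !is.finite(df$cost)
  if (any(nonfin)) df <- df[!nonfin, , drop = FALSE]
  if (nrow(df) <= P) return(df)
  df[sort(order(df$cost, seq_len(nrow(df)))[seq_len(P)]), , drop = FALSE]
}

sqrtSafe <- function(x) sqrt(pmax(x, 0))

# refinement distance penalty on the signed gap deviation Dst (mm)
refineDstPenalty <- function(dst, rp = refineParams()) {
  ifelse(dst < 0, -rp$alpha10 * dst, rp$alpha11 * dst)
}
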