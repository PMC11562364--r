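#' Intensity cutoff from the cumulative histogram of an ROI
#'
#' Interprets the threshold `alpha1` (percent) as "retain the top `alpha1`
#' percent brightest voxels of the region of interest": the returned cutoff
#' is the smallest intensity `t` such that the fraction of ROI voxels with
#' intensity `>= t` is at most `alpha1 / 100`. Ties at the cutoff are kept
#' above it, so the retained count can fall short of, but never exceed,
#' `alpha1` percent.
#'
#' @param roi a [CTVolume-class] (typically from [extractROI()]).
#' @param alpha1 percent of voxels to retain, in (0, 100).
#' @return Intensity cutoff (scalar). For a constant volume the constant is
#'   returned with a warning (all voxels retained).
#' @examples
#' v <- ctVolume(array(seq_len(1000), c(10, 10, 10)))
#' cumulativeThreshold(v, 10)  # keeps the 100 brightest voxels
#' @export
cumulativeThreshold <- function(roi, alpha1) {
  stopifnot(alpha1 > 0, alpha1 < 100)
  x <- as.numeric(roi@data)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant-intensity ROI: cumulative-histogram threshold is ",
            "degenerate, retaining all voxels")
    return(rng[1])
  }
  cutoffFromSorted(sort(x, decreasing = TRUE), alpha1)
}

# sorted_desc: intensities sorted decreasing; smallest t with
# count(x >= t) <= floor(alpha1/100 * n)
cutoffFromSorted <- function(sorted_desc, alpha1) {
  n <- length(sorted_desc)
  k <- floor(alpha1 / 100 * n)
  if (k < 1L) return(sorted_desc[1] + 1)
  t <- sorted_desc[k]
  # push the cutoff up past a tie block straddling rank k
  if (k < n && sorted_desc[k + 1L] == t) {
    above <- which(sorted_desc > t)
    if (length(above) == 0L) return(t + 1)
    t <- sorted_desc[max(above)]
  }
  t
}

#' Binary mask of voxels at or above an intensity cutoff
#'
#' @param roi a [CTVolume-class].
#' @param cutoff finite intensity threshold.
#' @return Logical 3D array, `TRUE` where `intensity >= cutoff`.
#' @export
binaryMask <- function(roi, cutoff) {
  stopifnot(is.finite(cutoff))
  roi@data >= cutoff
}

#' Skeletonize a binary mask to centerline voxels
#'
#' 3D topological thinning for (26, 6) connectivity with endpoint
#' preservation: border voxels are iteratively peeled in six directional
#' subiterations, deleting only simple points that are not curve endpoints,
#' so the connectivity of every component and the ends of thin structures
#' (such as dim apical electrode blobs) are preserved.
#'
#' @param mask logical 3D array.
#' @return Logical 3D array of skeleton voxels (a subset of `mask`).
#' @export
skeletonize3D <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  out <- .thinMask3D(as.logical(mask), as.integer(dim(mask)))
  array(out, dim = dim(mask))
}

#' Extract candidate electrode locations from a mask
#'
#' Thins `mask` to its centerline and returns every skeleton voxel as a
#' candidate point with its world coordinate and raw voxel intensity.
#'
#' @param mask logical 3D array (same shape as `roi`), typically from
#'   [binaryMask()].
#' @param roi the [CTVolume-class] the mask was derived from.
#' @param alpha1,cutoff provenance of the mask, stored in the result.
#' @return A [CandidateSet-class]; empty when `mask` has no foreground.
#' @export
extractCandidates <- function(mask, roi, alpha1 = NA_real_,
                              cutoff = NA_real_) {
  stopifnot(identical(dim(mask), dim(roi@data)))
  skel <- skeletonize3D(mask)
  idx <- which(skel, arr.ind = TRUE)
  new("CandidateSet",
      coords = indexToWorld(roi, idx),
      intensity = roi@data[idx],
      alpha1 = as.numeric(alpha1), cutoff = as.numeric(cutoff))
}

#' Candidate set for a region of interest at a given threshold
#'
#' Convenience wrapper chaining [cumulativeThreshold()], [binaryMask()] and
#' [extractCandidates()].
#'
#' @param roi a [CTVolume-class].
#' @param alpha1 cumulative-histogram threshold in percent.
#' @return A [CandidateSet-class].
#' @export
candidatesFromROI <- function(roi, alpha1) {
  cutoff <- cumulativeThreshold(roi, alpha1)
  extractCandidates(binaryMask(roi, cutoff), roi, alpha1 = alpha1,
                    cutoff = cutoff)
}

#' Sweep the cumulative-histogram threshold and pick the coverage-optimal value
#'
#' For each threshold on the grid (default 0.01\% to 3\% in steps of
#' 0.01\%), candidates are extracted and the coverage is computed: the
#' percentage of ground-truth electrodes with at least one candidate within
#' `radius_mm` (default 0.9 mm). The chosen threshold is the smallest grid
#' value attaining the maximum coverage, which also minimizes the number of
#' candidates generated on distractor structures.
#'
#' @param roi a [CTVolume-class].
#' @param gt n x 3 matrix of ground-truth electrode positions (mm), or a
#'   data.frame from [readCoordinates()].
#' @param lo,hi,step threshold grid in percent.
#' @param radius_mm coverage radius in mm.
#' @return A list with `curve` (data.frame: `alpha1`, `cutoff`, `nVoxels`,
#'   `nCandidates`, `coverage`) and `alpha1` (the chosen threshold).
#' @export
parametrizeThreshold <- function(roi, gt, lo = 0.01, hi = 3.0, step = 0.01,
                                 radius_mm = 0.9) {
  if (is.data.frame(gt)) gt <- coordsMatrix(gt)
  gt <- rbindable(gt)
  if (nrow(gt) == 0L) stop("ground-truth coordinate list is empty")
  grid <- seq(lo, hi, by = step)
  sorted <- sort(as.numeric(roi@data), decreasing = TRUE)
  cutoffs <- vapply(grid, function(a) cutoffFromSorted(sorted, a), 0)
  curve <- data.frame(alpha1 = grid, cutoff = cutoffs,
                      nVoxels = NA_integer_, nCandidates = NA_integer_,
                      coverage = NA_real_)
  cache <- list()
  for (i in seq_along(grid)) {
    key <- sprintf("%.17g", cutoffs[i])
    if (is.null(cache[[key]])) {
      cs <- extractCandidates(binaryMask(roi, cutoffs[i]), roi,
                              alpha1 = grid[i], cutoff = cutoffs[i])
      cache[[key]] <- list(
        nVoxels = sum(sorted >= cutoffs[i]),
        nCandidates = nrow(cs@coords),
        coverage = candidateCoverage(cs, gt, radius_mm))
    }
    curve$nVoxels[i] <- cache[[key]]$nVoxels
    curve$nCandidates[i] <- cache[[key]]$nCandidates
    curve$coverage[i] <- cache[[key]]$coverage
  }
  best <- max(curve$coverage)
  list(curve = curve, alpha1 = grid[which(curve$coverage == best)[1]])
}

#' Percentage of ground-truth electrodes covered by a candidate set
#'
#' @param cs a [CandidateSet-class].
#' @param gt n x 3 matrix of ground-truth positions (mm).
#' @param radius_mm coverage radius in mm.
#' @return Percent of electrodes with at least one candidate within
#'   `radius_mm`.
#' @export
candidateCoverage <- function(cs, gt, radius_mm = 0.9) {
  gt <- rbindable(gt)
  if (nrow(cs@coords) == 0L) return(0)
  covered <- vapply(seq_len(nrow(gt)), function(i) {
    d2 <- colSums((t(cs@coords) - gt[i, ])^2)
    any(d2 <= radius_mm^2)
  }, logical(1))
  100 * mean(covered)
}
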