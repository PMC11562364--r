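#' End-to-end electrode localization in a volume
#'
#' Runs the full pipeline on a volume with known ground-truth (seed)
#' coordinates: ROI extraction around the array, cumulative-histogram
#' thresholding, centerline candidate extraction, beam-search path finding
#' from the most basal ground-truth position, and (optionally) sub-voxel
#' refinement.
#'
#' @param v a [CTVolume-class].
#' @param gt ground truth: a `GroundTruth`, a data.frame from
#'   [readCoordinates()], or an L x 3 matrix (base to apex). The most basal
#'   position seeds the search and the ROI is defined around all of them.
#' @param spec an [EASpec-class] or registered array name.
#' @param thresholdMode `"sweep"` (parametrize on this volume; default),
#'   `"individual"` (registry per-array threshold), `"generalized"`
#'   (2.66\%), or `"value"` (use `alpha1`).
#' @param alpha1 threshold in percent when `thresholdMode = "value"`.
#' @param params a [costParams()] list (advanced cost variant by default).
#' @param refine logical; run [refinePath()] on the result.
#' @param rp a [refineParams()] list.
#' @param margin_mm ROI margin in mm.
#' @return A list: `path` (the final [ElectrodePath-class]), `voxelPath`
#'   (before refinement), `candidates`, `roi`, `alpha1`, `report` (an
#'   [EvalReport-class] against `gt`).
#' @examples
#' ph <- phantomPreset("clean", "Flex 16", seed = 1)
#' res <- localizeElectrodes(ph$volume, ph$gt, ph$spec,
#'                           thresholdMode = "value", alpha1 = 0.3)
#' res$report
#' @export
localizeElectrodes <- function(v, gt, spec,
                               thresholdMode = c("sweep", "individual",
                                                 "generalized", "value"),
                               alpha1 = NULL, params = costParams(),
                               refine = TRUE, rp = refineParams(),
                               margin_mm = 3.0) {
  thresholdMode <- match.arg(thresholdMode)
  if (is.character(spec)) spec <- getSpec(spec)
  gtm <- if (inherits(gt, "GroundTruth")) gt$positions
         else if (is.data.frame(gt)) coordsMatrix(gt)
         else rbindable(gt)
  roi <- extractROI(v, gtm, margin_mm = margin_mm)
  a1 <- switch(thresholdMode,
    sweep = parametrizeThreshold(roi, gtm)$alpha1,
    individual = getThreshold(spec@name, "individual"),
    generalized = getThreshold(spec@name, "generalized"),
    value = {
      if (is.null(alpha1)) stop("alpha1 required for thresholdMode 'value'")
      alpha1
    })
  cs <- candidatesFromROI(roi, a1)
  voxelPath <- findPath(cs, seed = gtm[1, ], spec = spec, params = params,
                        imax = max(roi@data))
  path <- if (refine) refinePath(roi, voxelPath, spec, rp) else voxelPath
  list(path = path, voxelPath = voxelPath, candidates = cs, roi = roi,
       alpha1 = a1, report = evaluatePath(path, gtm))
}
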