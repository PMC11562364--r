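#' @import methods
#' @importFrom stats rnorm setNames approx quantile dist aggregate
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib CIlocate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CTVolume: a 3D intensity volume with world-coordinate geometry
#'
#' Container for a scalar 3D image grid together with its voxel spacing and
#' world origin. All geometry in the package is expressed in millimetres;
#' the world position of voxel `(i, j, k)` (1-based array index) is
#' `origin + (c(i, j, k) - 1) * spacing` (voxel-center convention).
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel along each axis, all > 0.
#' @slot origin numeric(3), world coordinate (mm) of the center of voxel
#'   `(1, 1, 1)`.
#'
#' @seealso [ctVolume()], [readVolume()], [extractROI()]
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (length(msg)) msg else TRUE
  }
)

#' EASpec: electrode-array geometry specification
#'
#' Geometry of one cochlear-implant electrode array: the number of active
#' contacts, the inter-electrode gap distances, an optional non-stimulating
#' marker contact, and the number of apical contacts that image with reduced
#' intensity (the MED-EL Flex single-contact design).
#'
#' Gap distances are stored apex-to-base: `gapDistances(x)[i]` is the
#' distance in mm between electrodes `i` and `i + 1` counted from the apex.
#' Use [gapFromBase()] for the base-to-apex indexing used during path
#' construction.
#'
#' @slot name array model name.
#' @slot manufacturer manufacturer name.
#' @slot nElectrodes integer, number of active contacts L (>= 2).
#' @slot nMarkers integer, number of non-stimulating marker contacts.
#' @slot gapDistances numeric(L - 1), inter-electrode distances in mm,
#'   apex-to-base.
#' @slot markerGap mm from the most basal electrode to the marker contact,
#'   or `NA_real_` when absent/unknown.
#' @slot apicalLowIntensity integer, number of most-apical contacts imaged
#'   with reduced intensity (0 when not applicable).
#'
#' @seealso [getSpec()], [eaRegistry()]
#' @export
setClass("EASpec",
  representation(name = "character", manufacturer = "character",
    nElectrodes = "integer", nMarkers = "integer",
    gapDistances = "numeric", markerGap = "numeric",
    apicalLowIntensity = "integer"),
  validity = function(object) {
    msg <- character()
    L <- object@nElectrodes
    if (length(L) != 1L || is.na(L) || L < 2L)
      msg <- c(msg, "nElectrodes must be a single integer >= 2")
    if (length(object@gapDistances) != L - 1L)
      msg <- c(msg, sprintf("gapDistances must have length nElectrodes - 1 (%d)",
                            L - 1L))
    if (any(!is.finite(object@gapDistances)) || any(object@gapDistances <= 0))
      msg <- c(msg, "all gap distances must be finite and > 0")
    if (object@nMarkers < 0L)
      msg <- c(msg, "nMarkers must be >= 0")
    if (object@apicalLowIntensity < 0L || object@apicalLowIntensity > L)
      msg <- c(msg, "apicalLowIntensity must be in [0, nElectrodes]")
    if (length(msg)) msg else TRUE
  }
)

#' CandidateSet: candidate electrode locations
#'
#' World-coordinate points (centerline voxels of the thresholded region of
#' interest) that are eligible to become electrode positions, each carrying
#' the raw voxel intensity at its location, plus the threshold that produced
#' them.
#'
#' @slot coords n x 3 numeric matrix of world positions (mm).
#' @slot intensity numeric(n), raw voxel intensity per candidate.
#' @slot alpha1 percent threshold used to form the mask (`NA` if the set was
#'   built directly from an intensity cutoff).
#' @slot cutoff intensity cutoff corresponding to `alpha1`.
#'
#' @seealso [extractCandidates()], [cumulativeThreshold()]
#' @export
setClass("CandidateSet",
  representation(coords = "matrix", intensity = "numeric",
    alpha1 = "numeric", cutoff = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3L)
      msg <- c(msg, "coords must have 3 columns")
    if (length(object@intensity) != nrow(object@coords))
      msg <- c(msg, "intensity must have one value per candidate")
    if (length(msg)) msg else TRUE
  }
)

#' ElectrodePath: an ordered chain of localized electrode positions
#'
#' Result of the beam search (and, optionally, sub-voxel refinement): an
#' ordered chain of node positions from the most basal electrode (node 1,
#' the seed) towards the apex, with the accumulated cost and the per-step
#' cost breakdown.
#'
#' @slot nodes k x 3 numeric matrix of node positions (mm), base to apex.
#' @slot cost accumulated path cost.
#' @slot steps data.frame with one row per extension step: columns
#'   `costI`, `costS`, `costR`, `total`.
#' @slot complete logical, `TRUE` when the chain reached the full electrode
#'   count L of its array specification.
#'
#' @seealso [findPath()], [refinePath()]
#' @export
setClass("ElectrodePath",
  representation(nodes = "matrix", cost = "numeric", steps = "data.frame",
    complete = "logical"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@nodes) != 3L)
      msg <- c(msg, "nodes must have 3 columns")
    if (nrow(object@nodes) < 1L)
      msg <- c(msg, "path must contain at least the seed node")
    if (length(msg)) msg else TRUE
  }
)

#' EvalReport: localization scores against ground truth
#'
#' Per-case evaluation of a predicted electrode chain against ground truth:
#' mean localization error, detection rate at the 0.9 mm radius, conditional
#' accuracy over detected electrodes, per-electrode flags and distances, and
#' automated error-class labels.
#'
#' @slot accuracy mean localization error L_a in mm (over labels present in
#'   the prediction).
#' @slot detectionRate percent of electrodes detected (error <= radius).
#' @slot conditionalAccuracy mean error in mm over detected electrodes only
#'   (`NaN` when none detected).
#' @slot perElectrode data.frame: `electrode`, `error_mm`, `detected`,
#'   `predicted` (FALSE for labels missing from an incomplete chain).
#' @slot errorLabels character vector, subset of `"artifact_detection"`,
#'   `"double_detection"`, `"ab_confusion_basal_revisit"`,
#'   `"ab_confusion_reversal"` (automated classification).
#' @slot radius detection radius in mm used (default 0.9).
#'
#' @seealso [evaluatePath()], [classifyErrors()]
#' @export
setClass("EvalReport",
  representation(accuracy = "numeric", detectionRate = "numeric",
    conditionalAccuracy = "numeric", perElectrode = "data.frame",
    errorLabels = "character", radius = "numeric"))
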