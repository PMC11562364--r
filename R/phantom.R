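#' Arc-length-parameterized helical (cochlea-like) curve
#'
#' Builds a spiral curve emulating the cochlear lumen: radius shrinking
#' geometrically with angle, constant height gain per radian. The curve is
#' parameterized by arc length from its basal (outer) end; arc length is
#' computed by trapezoidal integration of the analytic speed on a dense
#' angle grid (the default grid keeps the numerical arc length accurate to
#' well under 0.01 mm over two turns).
#'
#' @param center numeric(3), mm, center of the spiral axis at height 0.
#' @param baseRadius starting (basal) radius in mm, > 0.
#' @param radiusDecay per-radian geometric shrink factor in (0, 1].
#' @param pitch mm height gain per radian, >= 0.
#' @param totalAngle total available insertion angle in degrees, > 0.
#' @param startAngle angular offset of the basal end in degrees.
#' @param nGrid number of grid points for the arc-length table.
#' @return An object of class `spiralCurve` with `curveLength()`,
#'   `curvePoint()` and `curveAngle()` support.
#' @examples
#' cu <- spiralCurve(baseRadius = 3, radiusDecay = 1, pitch = 0,
#'                   totalAngle = 360)
#' curveLength(cu)  # 2 * pi * 3
#' @export
spiralCurve <- function(center = c(0, 0, 0), baseRadius = 3.0,
                        radiusDecay = 0.955, pitch = 0.4,
                        totalAngle = 720, startAngle = 0,
                        nGrid = 20000L) {
  if (!is.finite(baseRadius) || baseRadius <= 0)
    stop("baseRadius must be > 0")
  if (!is.finite(radiusDecay) || radiusDecay <= 0 || radiusDecay > 1)
    stop("radiusDecay must be in (0, 1]")
  if (!is.finite(pitch) || pitch < 0) stop("pitch must be >= 0")
  if (!is.finite(totalAngle) || totalAngle <= 0)
    stop("totalAngle must be > 0")
  thetaMax <- totalAngle * pi / 180
  theta <- seq(0, thetaMax, length.out = nGrid)
  r <- baseRadius * radiusDecay^theta
  dr <- r * log(radiusDecay)
  speed <- sqrt(dr^2 + r^2 + pitch^2)
  ds <- diff(theta) * (head(speed, -1) + tail(speed, -1)) / 2
  cumlen <- c(0, cumsum(ds))
  structure(list(center = as.numeric(center), baseRadius = baseRadius,
                 radiusDecay = radiusDecay, pitch = pitch,
                 thetaMax = thetaMax, startAngle = startAngle * pi / 180,
                 theta = theta, cumlen = cumlen),
            class = "spiralCurve")
}

#' @rdname spiralCurve
#' @param curve a `spiralCurve`.
#' @export
curveLength <- function(curve) {
  tail(curve$cumlen, 1L)
}

#' @rdname spiralCurve
#' @param s arc length(s) in mm from the basal end, within
#'   `[0, curveLength(curve)]`.
#' @return `curvePoint`: length(s) x 3 matrix of mm positions;
#'   `curveAngle`: angle in degrees travelled from the basal end at `s`.
#' @export
curvePoint <- function(curve, s) {
  theta <- curveThetaAt(curve, s)
  r <- curve$baseRadius * curve$radiusDecay^theta
  a <- curve$startAngle + theta
  cbind(curve$center[1] + r * cos(a),
        curve$center[2] + r * sin(a),
        curve$center[3] + curve$pitch * theta)
}

#' @rdname spiralCurve
#' @export
curveAngle <- function(curve, s) {
  curveThetaAt(curve, s) * 180 / pi
}

curveThetaAt <- function(curve, s) {
  if (any(s < -1e-9) || any(s > tail(curve$cumlen, 1L) + 1e-9))
    stop("arc length outside the curve (available ",
         format(tail(curve$cumlen, 1L), digits = 6), " mm)")
  approx(curve$cumlen, curve$theta, xout = pmin(pmax(s, 0),
         tail(curve$cumlen, 1L)), ties = "ordered")$y
}

#' Place electrode contacts along a curve
#'
#' Places the `L` contacts of an array specification on an arc-length
#' parameterized curve so that consecutive straight-line (chord) distances
#' equal the spec's gap distances: starting from the apical contact
#' (`apicalArcOffset` mm of arc before the apical end of the curve), each
#' more basal contact is found by root-solving for the arc position whose
#' chord distance to its neighbor equals the gap. Contacts are returned
#' ordered base to apex. Chord placement models a rigid array whose
#' contact-to-contact spacing is the manufacturer gap; on a straight
#' "curve" chord and arc coincide exactly.
#'
#' @param curve a [spiralCurve()] (or any object with `curveLength` /
#'   `curvePoint` / `curveAngle` support).
#' @param spec an [EASpec-class].
#' @param apicalArcOffset arc length in mm left free beyond the apical
#'   contact.
#' @return A list of class `GroundTruth`: `positions` (L x 3 mm matrix,
#'   base to apex), `insertionAngle` (degrees at the apical contact),
#'   `arcLengths` (per-contact arc positions), `spec` (array name).
#' @export
placeElectrodes <- function(curve, spec, apicalArcOffset = 0.5) {
  S <- curveLength(curve)
  need <- sum(spec@gapDistances) + apicalArcOffset
  if (need > S)
    stop(sprintf(
      "curve too short: %.3f mm arc required (gaps %.3f + offset %.3f), %.3f mm available",
      need, sum(spec@gapDistances), apicalArcOffset, S))
  sApex <- S - apicalArcOffset
  L <- spec@nElectrodes
  sPos <- numeric(L)
  sPos[L] <- sApex
  # apex-to-base: gapDistances[g] separates electrodes (L - g) and
  # (L - g + 1) counted from base
  for (g in seq_len(L - 1L)) {
    iBase <- L - g
    ref <- curvePoint(curve, sPos[iBase + 1L])
    gap <- spec@gapDistances[g]
    f <- function(s) sqrt(sum((curvePoint(curve, s) - ref)^2)) - gap
    loS <- max(0, sPos[iBase + 1L] - 2.5 * gap)
    if (f(loS) < 0)
      stop(sprintf(
        "curve too short: cannot place electrode %d at chord %.3f mm (%.3f mm arc remaining)",
        iBase, gap, sPos[iBase + 1L]))
    sPos[iBase] <- stats::uniroot(f, c(loS, sPos[iBase + 1L]),
                                  tol = 1e-9)$root
  }
  structure(list(positions = curvePoint(curve, sPos),
                 insertionAngle = curveAngle(curve, sApex),
                 arcLengths = sPos, spec = spec@name),
            class = "GroundTruth")
}

#' Rendering parameters for synthetic CBCT phantoms
#'
#' Defaults model the clinical imaging regime: isotropic 0.3 mm voxels,
#' electrode blooming rendered as isotropic Gaussian blobs of scale
#' 0.45 mm with peak 2000 (so the intensity-cost normalization by 2000 maps
#' into `[0, 1]`), additive Gaussian noise (sigma 50, clipped at zero) and a
#' 0.5 intensity factor for the reduced-intensity apical contacts of
#' single-contact (MED-EL Flex style) designs.
#'
#' @param voxelSpacing isotropic voxel spacing in mm.
#' @param psfSigma Gaussian blob scale in mm.
#' @param electrodePeak blob peak intensity.
#' @param apicalPeakFactor multiplier in (0, 1] applied to the
#'   `apicalLowIntensity` most apical contacts of the spec.
#' @param noiseSigma additive Gaussian noise sigma (0 disables noise).
#' @param backgroundLevel constant background intensity.
#' @param rngSeed integer seed making the rendering deterministic.
#' @param margin mm of empty volume kept around the ground-truth bounding
#'   box.
#' @return A list of class `RenderParams`.
#' @export
renderParams <- function(voxelSpacing = 0.3, psfSigma = 0.45,
                         electrodePeak = 2000, apicalPeakFactor = 0.5,
                         noiseSigma = 50, backgroundLevel = 0,
                         rngSeed = 1L, margin = 4.0) {
  stopifnot(voxelSpacing > 0, psfSigma > 0,
            apicalPeakFactor > 0, apicalPeakFactor <= 1,
            noiseSigma >= 0, margin >= 3)
  structure(list(voxelSpacing = voxelSpacing, psfSigma = psfSigma,
                 electrodePeak = electrodePeak,
                 apicalPeakFactor = apicalPeakFactor,
                 noiseSigma = noiseSigma, backgroundLevel = backgroundLevel,
                 rngSeed = as.integer(rngSeed), margin = margin),
            class = "RenderParams")
}

#' Distractor structures for phantom rendering
#'
#' `boneSlab` contributes an extended box of moderate intensity (cortical
#' bone images at up to about 300 intensity units in CBCT); `wireLead`
#' contributes a bright thin tube leaving the array basally, emulating the
#' implant lead.
#'
#' @param center numeric(3) mm, slab center.
#' @param size numeric(3) mm, slab edge lengths.
#' @param peak slab intensity.
#' @return A list of class `distractor`, to be passed to [renderPhantom()].
#' @export
boneSlab <- function(center, size = c(6, 6, 1.5), peak = 300) {
  structure(list(kind = "bone_slab", center = as.numeric(center),
                 size = as.numeric(size), peak = peak),
            class = "distractor")
}

#' @rdname boneSlab
#' @param from numeric(3) mm, attachment point (typically the most basal
#'   electrode).
#' @param direction numeric(3), direction the lead leaves in (normalized
#'   internally).
#' @param length lead length in mm.
#' @param sigma tube Gaussian radius in mm.
#' @export
wireLead <- function(from, direction, length = 6, sigma = 0.25,
                     peak = 1800) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("wireLead direction must be non-zero")
  structure(list(kind = "wire_lead", from = as.numeric(from),
                 direction = direction / nrm, length = length,
                 sigma = sigma, peak = peak),
            class = "distractor")
}

#' Render a synthetic CBCT phantom volume
#'
#' Produces `background + electrode blobs + distractors + noise`: each
#' contact becomes an isotropic Gaussian blob (peak reduced by
#' `apicalPeakFactor` for the spec's reduced-intensity apical contacts),
#' distractor fields are added, and seeded Gaussian noise (clipped at 0) is
#' applied last. Rendering is bit-deterministic given `rngSeed`. The volume
#' extent is the ground-truth bounding box padded by `margin` mm.
#'
#' @param gt a `GroundTruth` from [placeElectrodes()], or an L x 3 matrix.
#' @param spec the [EASpec-class] of the array.
#' @param rp a [renderParams()] list.
#' @param distractors list of [boneSlab()] / [wireLead()] objects.
#' @return A [CTVolume-class].
#' @export
renderPhantom <- function(gt, spec, rp = renderParams(),
                          distractors = list()) {
  pos <- if (inherits(gt, "GroundTruth")) gt$positions else rbindable(gt)
  L <- nrow(pos)
  lo <- apply(pos, 2L, min) - rp$margin
  hi <- apply(pos, 2L, max) + rp$margin
  dims <- as.integer(ceiling((hi - lo) / rp$voxelSpacing)) + 1L
  v <- ctVolume(array(rp$backgroundLevel, dim = dims),
                spacing = rp$voxelSpacing, origin = lo)
  if (any(worldToIndex(v, pos) < 1) ||
      any(sweep(worldToIndex(v, pos), 2L, dims, `-`) > 0))
    stop("electrode positions fall outside the phantom volume")
  peaks <- rep(rp$electrodePeak, L)
  nDim <- min(spec@apicalLowIntensity, L)
  if (nDim > 0L)
    peaks[(L - nDim + 1L):L] <- rp$electrodePeak * rp$apicalPeakFactor
  for (i in seq_len(L))
    v@data <- addBlob(v, pos[i, ], peaks[i], rp$psfSigma)
  for (d in distractors)
    v@data <- v@data + distractorField(d, v)
  if (rp$noiseSigma > 0) {
    v@data <- withSeed(rp$rngSeed, {
      pmax(v@data + array(rnorm(length(v@data), 0, rp$noiseSigma),
                          dim = dims), 0)
    })
  }
  v
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# add one Gaussian blob to the grid (local 4.5-sigma window)
addBlob <- function(v, center, peak, sigma) {
  d <- dim(v@data)
  r <- 4.5 * sigma
  lo <- pmax(floor((center - r - v@origin) / v@spacing) + 1, 1)
  hi <- pmin(ceiling((center + r - v@origin) / v@spacing) + 1, d)
  xs <- v@origin[1] + (seq(lo[1], hi[1]) - 1) * v@spacing[1]
  ys <- v@origin[2] + (seq(lo[2], hi[2]) - 1) * v@spacing[2]
  zs <- v@origin[3] + (seq(lo[3], hi[3]) - 1) * v@spacing[3]
  gx <- exp(-(xs - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(ys - center[2])^2 / (2 * sigma^2))
  gz <- exp(-(zs - center[3])^2 / (2 * sigma^2))
  blob <- peak * (gx %o% gy %o% gz)
  v@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    v@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  v@data
}

distractorField <- function(d, v) {
  dims <- dim(v@data)
  field <- array(0, dim = dims)
  if (d$kind == "bone_slab") {
    lo <- pmax(floor((d$center - d$size / 2 - v@origin) / v@spacing) + 1, 1)
    hi <- pmin(ceiling((d$center + d$size / 2 - v@origin) / v@spacing) + 1,
               dims)
    if (all(hi >= lo))
      field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- d$peak
  } else if (d$kind == "wire_lead") {
    # Gaussian tube: pointwise max over densely sampled centers so the
    # tube's peak stays uniform along the lead
    ts <- seq(0, d$length, by = min(0.1, d$sigma / 2))
    centers <- t(d$from + outer(d$direction, ts))
    r <- 4 * d$sigma
    for (i in seq_len(nrow(centers))) {
      ce <- centers[i, ]
      lo <- pmax(floor((ce - r - v@origin) / v@spacing) + 1, 1)
      hi <- pmin(ceiling((ce + r - v@origin) / v@spacing) + 1, dims)
      if (any(hi < lo)) next
      xs <- v@origin[1] + (seq(lo[1], hi[1]) - 1) * v@spacing[1]
      ys <- v@origin[2] + (seq(lo[2], hi[2]) - 1) * v@spacing[2]
      zs <- v@origin[3] + (seq(lo[3], hi[3]) - 1) * v@spacing[3]
      g <- d$peak *
        (exp(-(xs - ce[1])^2 / (2 * d$sigma^2)) %o%
         exp(-(ys - ce[2])^2 / (2 * d$sigma^2)) %o%
         exp(-(zs - ce[3])^2 / (2 * d$sigma^2)))
      cur <- field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(cur, g)
    }
  } else stop("unknown distractor kind: ", d$kind)
  field
}

#' Shipped phantom presets
#'
#' Three study conditions, each deterministic given `seed`:
#' \describe{
#'   \item{`clean`}{noise-free, uniformly bright contacts, no distractors;
#'     a gently wound spiral (pitch 0.55 mm/rad) whose adjacent turns stay
#'     clearly separated relative to the array spacing.}
#'   \item{`confusion`}{the apical-basal confusion regime: a deep insertion
#'     (> 360 degrees at the apex) on a tight spiral (base radius 3.2 mm,
#'     radius decay 0.9534 per rad, pitch 0.28 mm/rad) whose adjacent-turn
#'     separation (~1.95 mm for the default Flex 24 geometry) falls inside
#'     the spacing acceptance window, with reduced-intensity apical
#'     contacts and noise.}
#'   \item{`artifacts`}{the clean geometry plus a bone slab and a wire lead
#'     distractor, with noise.}
#' }
#'
#' @param preset `"clean"`, `"confusion"` or `"artifacts"`.
#' @param spec an [EASpec-class] or a registered array name (default
#'   `"Flex 24"`).
#' @param seed integer; drives the rendering noise.
#' @param noiseSigma override the preset's noise level (e.g. 0 for a
#'   noise-free confusion geometry).
#' @return A list: `volume` ([CTVolume-class]), `gt` (`GroundTruth`),
#'   `spec`, `params` (the [renderParams()] used), `distractors`.
#' @export
phantomPreset <- function(preset = c("clean", "confusion", "artifacts"),
                          spec = "Flex 24", seed = 1L, noiseSigma = NULL) {
  preset <- match.arg(preset)
  if (is.character(spec)) spec <- getSpec(spec)
  geom <- switch(preset,
    clean = , artifacts = list(baseRadius = 3.0, radiusDecay = 0.955,
                               pitch = 0.55),
    confusion = list(baseRadius = 3.2, radiusDecay = 0.9534, pitch = 0.28))
  curve <- spiralCurve(center = c(0, 0, 0), baseRadius = geom$baseRadius,
                       radiusDecay = geom$radiusDecay, pitch = geom$pitch,
                       totalAngle = 1440)
  gt <- placeElectrodes(curve, spec,
                        apicalArcOffset = curveLength(curve) -
                          sum(spec@gapDistances) - 1.0)
  rp <- switch(preset,
    clean = renderParams(noiseSigma = 0, apicalPeakFactor = 1,
                         rngSeed = seed),
    confusion = renderParams(noiseSigma = 50, apicalPeakFactor = 0.5,
                             rngSeed = seed),
    artifacts = renderParams(noiseSigma = 50, apicalPeakFactor = 1,
                             rngSeed = seed))
  if (!is.null(noiseSigma)) rp$noiseSigma <- noiseSigma
  distractors <- list()
  if (preset == "artifacts") {
    base <- gt$positions[1, ]
    away <- base - colMeans(gt$positions)
    distractors <- list(
      boneSlab(center = colMeans(gt$positions) + c(0, 0, -3.2)),
      wireLead(from = base, direction = away + c(0, 0, -0.5), length = 5))
  }
  vol <- renderPhantom(gt, spec, rp, distractors)
  list(volume = vol, gt = gt, spec = spec, params = rp,
       distractors = distractors, preset = preset)
}
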