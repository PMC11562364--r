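test_that("spiral arc length matches closed forms and fine quadrature", {
  circ <- spiralCurve(baseRadius = 3, radiusDecay = 1, pitch = 0,
                      totalAngle = 360)
  expect_equal(curveLength(circ), 2 * pi * 3, tolerance = 1e-5)
  # half a turn on a planar circle lands diametrically opposite the start
  p0 <- curvePoint(circ, 0)
  pHalf <- curvePoint(circ, 3 * pi)
  expect_equal(sqrt(sum((pHalf - p0)^2)), 6, tolerance = 1e-4)

  # cochlear-like parameters over two turns vs chord quadrature at 10x the
  # arc-length grid resolution
  cu <- spiralCurve(baseRadius = 3, radiusDecay = 0.955, pitch = 0.4,
                    totalAngle = 720, nGrid = 20000L)
  th <- seq(0, 720 * pi / 180, length.out = 200000L)
  r <- 3 * 0.955^th
  pts <- cbind(r * cos(th), r * sin(th), 0.4 * th)
  quadrature <- sum(sqrt(rowSums(diff(pts)^2)))
  expect_equal(curveLength(cu), quadrature, tolerance = 1e-5)
  expect_lt(abs(curveLength(cu) - quadrature), 0.01)

  expect_error(spiralCurve(baseRadius = -1), "baseRadius")
  expect_error(spiralCurve(radiusDecay = 1.2), "radiusDecay")
  expect_error(spiralCurve(totalAngle = 0), "totalAngle")
})

test_that("electrode placement reproduces the spec gaps as chord distances", {
  cu <- spiralCurve(baseRadius = 4.5, radiusDecay = 0.99, pitch = 0.8,
                    totalAngle = 720)
  spec <- getSpec("Flex 24")
  gt <- placeElectrodes(cu, spec, apicalArcOffset = 1)
  expect_identical(nrow(gt$positions), 12L)
  chords <- sqrt(rowSums(diff(gt$positions)^2))
  expect_equal(chords, rep(1.9, 11), tolerance = 2e-2)
  expect_lt(max(abs(chords - 1.9) / 1.9), 0.02)
  # base-to-apex ordering: arc positions increase
  expect_true(all(diff(gt$arcLengths) > 0))
  expect_equal(gt$insertionAngle,
               curveAngle(cu, max(gt$arcLengths)), tolerance = 1e-6)

  # nearly straight curve: chords equal the gaps essentially exactly
  line <- spiralCurve(baseRadius = 1e-4, radiusDecay = 1, pitch = 2,
                      totalAngle = 1080)
  spec2 <- toySpec(5, c(1.2, 1.1, 1.0, 0.9))
  gl <- placeElectrodes(line, spec2, apicalArcOffset = 0.5)
  chordsL <- sqrt(rowSums(diff(gl$positions)^2))
  # gaps are stored apex-to-base; chords run base-to-apex
  expect_equal(chordsL, rev(c(1.2, 1.1, 1.0, 0.9)), tolerance = 1e-6)

  # deep placement: minimum distance between electrode 1 and the apical
  # half equals the brute-force pairwise minimum
  deep <- phantomPreset("confusion", "Flex 24", seed = 1, noiseSigma = 0)
  pd <- as.matrix(dist(deep$gt$positions))
  expect_equal(min(pd[1, 9:12]), min(sapply(9:12, function(j)
    sqrt(sum((deep$gt$positions[1, ] - deep$gt$positions[j, ])^2)))))

  shortCurve <- spiralCurve(baseRadius = 2, radiusDecay = 1, pitch = 0,
                            totalAngle = 90)
  expect_error(placeElectrodes(shortCurve, spec), "curve too short")
})

test_that("ground-truth chords stay within 2% of spec gaps for all presets", {
  for (preset in c("clean", "confusion", "artifacts")) {
    ph <- phantomPreset(preset, "Flex 24", seed = 1, noiseSigma = 0)
    chords <- sqrt(rowSums(diff(ph$gt$positions)^2))
    gaps <- rev(gapDistances(ph$spec))
    expect_lt(max(abs(chords - gaps) / gaps), 0.02)
  }
})

test_that("rendering is deterministic, blob-centred and additive", {
  spec <- toySpec(3, 2.0)
  gt <- rbind(c(0, 0, 0), c(2, 0, 0.2), c(3.6, 0.9, 0.6))
  rp <- renderParams(noiseSigma = 0, apicalPeakFactor = 1, rngSeed = 7)
  v <- renderPhantom(gt, spec, rp)
  # noise-free: the global maximum lies within one voxel of a blob center
  mx <- which(v@data == max(v@data), arr.ind = TRUE)[1, , drop = TRUE]
  w <- indexToWorld(v, mx)
  expect_lt(min(sqrt(rowSums(sweep(gt, 2L, as.numeric(w), `-`)^2))),
            sqrt(3) * 0.3 + 1e-9)

  # identical seeds give bit-identical noisy volumes
  rpN <- renderParams(noiseSigma = 40, apicalPeakFactor = 1, rngSeed = 42)
  expect_identical(intensities(renderPhantom(gt, spec, rpN)),
                   intensities(renderPhantom(gt, spec, rpN)))
  rpN2 <- renderParams(noiseSigma = 40, apicalPeakFactor = 1, rngSeed = 43)
  expect_false(identical(intensities(renderPhantom(gt, spec, rpN)),
                         intensities(renderPhantom(gt, spec, rpN2))))

  # rendering is additive in distractors (noise-free)
  slab <- boneSlab(center = c(1.8, -2, 0))
  lead <- wireLead(from = gt[1, ], direction = c(-1, -0.3, 0), length = 4)
  vA <- renderPhantom(gt, spec, rp, list(slab))
  vB <- renderPhantom(gt, spec, rp, list(lead))
  vAB <- renderPhantom(gt, spec, rp, list(slab, lead))
  base <- renderPhantom(gt, spec, rp)
  expect_equal(intensities(vAB),
               intensities(vA) + intensities(vB) - intensities(base),
               tolerance = 1e-12)

  # apical dimming: mean peak of the dim apical blobs is half the basal one
  flex <- getSpec("Flex 28")
  ph <- phantomPreset("confusion", flex, seed = 1, noiseSigma = 0)
  peaks <- sampleVolume(ph$volume, ph$gt$positions)
  apical <- mean(peaks[8:12])   # 5 most apical contacts are dimmed
  basal <- mean(peaks[1:7])
  expect_equal(apical / basal, 0.5, tolerance = 0.05)

  expect_error(renderPhantom(gt, spec, renderParams(margin = 2)), "margin")
})

test_that("confusion preset creates the deep-insertion inter-turn regime", {
  ph <- phantomPreset("confusion", "Flex 24", seed = 1, noiseSigma = 0)
  expect_gt(ph$gt$insertionAngle, 360)
  spacing <- gapDistances(ph$spec)[1]
  pd <- as.matrix(dist(ph$gt$positions))
  # some non-neighbouring (inter-turn) pair falls inside the spacing
  # acceptance window (d/2, 2d): the precondition for apical-basal
  # confusion
  interTurn <- abs(row(pd) - col(pd)) >= 6
  win <- pd > spacing / 2 & pd < 2 * spacing
  expect_true(any(interTurn & win))
  # adjacent-turn separation within [0.5x, 2x] of the spacing
  sep <- min(pd[1, 8:12])
  expect_gte(sep, 0.5 * spacing)
  expect_lte(sep, 2 * spacing)
})

test_that("bone slab stays below the electrode threshold and attracts no candidates", {
  base <- phantomPreset("clean", "Flex 24", seed = 3)
  slab <- boneSlab(center = colMeans(base$gt$positions) + c(0, 0, -3.2))
  vol <- renderPhantom(base$gt, base$spec,
                       renderParams(noiseSigma = 50, apicalPeakFactor = 1,
                                    rngSeed = 3), list(slab))
  roi <- extractROI(vol, base$gt$positions)
  sw <- parametrizeThreshold(roi, base$gt$positions)
  cs <- candidatesFromROI(roi, sw$alpha1)
  # with the coverage-optimal threshold the cutoff exceeds the bone peak
  expect_gt(cs@cutoff, 300)
  lo <- slab$center - slab$size / 2
  hi <- slab$center + slab$size / 2
  cc <- coords(cs)
  onSlab <- cc[, 1] >= lo[1] & cc[, 1] <= hi[1] &
            cc[, 2] >= lo[2] & cc[, 2] <= hi[2] &
            cc[, 3] >= lo[3] & cc[, 3] <= hi[3]
  expect_identical(sum(onSlab), 0L)
})
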