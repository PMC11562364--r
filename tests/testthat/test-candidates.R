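test_that("cumulative-histogram cutoff matches the sort-based oracle", {
  set.seed(5)
  # large volume with distinct intensities: exact top-quantile counts
  n <- 10^6
  x <- sample(seq_len(n))
  v <- ctVolume(array(x, c(100, 100, 100)))
  cut <- cumulativeThreshold(v, 0.08)
  expect_identical(sum(x >= cut), 800L)
  expect_identical(sum(x >= cut), thresholdCountOracle(x, 0.08))

  # heavily tied intensities: retained count never exceeds the quota and
  # matches the oracle exactly
  y <- round(rnorm(40^3, 500, 100) / 25) * 25
  vy <- ctVolume(array(y, c(40, 40, 40)))
  for (a in c(0.08, 0.6, 2.66)) {
    cutY <- cumulativeThreshold(vy, a)
    expect_identical(sum(y >= cutY), thresholdCountOracle(y, a), info = a)
    expect_lte(sum(y >= cutY), floor(a / 100 * length(y)))
  }

  # constant volume degenerates with a warning, retaining everything
  vc <- ctVolume(array(7, c(5, 5, 5)))
  expect_warning(cc <- cumulativeThreshold(vc, 1), "constant")
  expect_identical(cc, 7)

  expect_error(cumulativeThreshold(v, 0), "alpha1 > 0")
})

test_that("binary mask thresholds inclusively", {
  v <- ctVolume(array(seq_len(27), c(3, 3, 3)))
  expect_false(any(binaryMask(v, 28)))
  expect_true(all(binaryMask(v, 1)))
  m <- binaryMask(v, 14)
  expect_identical(sum(m), 14L)
  expect_true(m[c(14)])
})

test_that("3D thinning preserves points, lines and endpoints and is idempotent", {
  # an isolated voxel survives
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_identical(skeletonize3D(m), m)

  # a 1-voxel-thick 20-voxel straight segment is returned unchanged
  m <- array(FALSE, c(24, 5, 5)); m[3:22, 3, 3] <- TRUE
  expect_identical(skeletonize3D(m), m)

  # a solid cube collapses to a small centred core
  m <- array(FALSE, c(11, 11, 11)); m[3:9, 3:9, 3:9] <- TRUE
  s <- skeletonize3D(m)
  idx <- which(s, arr.ind = TRUE)
  expect_gte(nrow(idx), 1L)
  expect_lte(nrow(idx), 9L)
  expect_lt(max(sqrt(rowSums(sweep(idx, 2L, c(6, 6, 6), `-`)^2))), 3)
  # skeleton is a subset of the mask and thinning is idempotent
  expect_true(all(m[idx]))
  expect_identical(skeletonize3D(s), s)

  # a thick tube thins to a connected centerline along its axis
  m <- array(FALSE, c(30, 9, 9))
  co <- as.matrix(expand.grid(3:28, 1:9, 1:9))
  keep <- (co[, 2] - 5)^2 + (co[, 3] - 5)^2 <= 4
  m[co[keep, ]] <- TRUE
  s <- skeletonize3D(m)
  idx <- which(s, arr.ind = TRUE)
  expect_true(all(abs(idx[, 2] - 5) <= 1 & abs(idx[, 3] - 5) <= 1))
  expect_gte(length(unique(idx[, 1])), 20L)
})

test_that("candidate extraction reports world coordinates and raw intensities", {
  v <- blobVolume(rbind(c(0, 0, 0), c(2.4, 0.3, 0.3)), peaks = 2000)
  cut <- cumulativeThreshold(v, 0.5)
  cs <- extractCandidates(binaryMask(v, cut), v, alpha1 = 0.5, cutoff = cut)
  expect_gt(nrow(coords(cs)), 0L)
  expect_true(all(intensities(cs) >= cut))
  # every candidate's intensity equals the voxel value at its position
  expect_equal(intensities(cs), sampleVolume(v, coords(cs)),
               tolerance = 1e-12)
  # each blob has a candidate close to its centre
  for (ctr in list(c(0, 0, 0), c(2.4, 0.3, 0.3)))
    expect_lt(min(sqrt(colSums((t(coords(cs)) - ctr)^2))), 0.45)
  # empty mask yields an empty candidate set
  empty <- extractCandidates(binaryMask(v, max(v@data) + 1), v)
  expect_identical(nrow(coords(empty)), 0L)
  # a single isolated voxel above cutoff is its own candidate
  one <- array(FALSE, dim(v@data)); one[10, 10, 10] <- TRUE
  cs1 <- extractCandidates(one, v)
  expect_equal(coords(cs1), indexToWorld(v, c(10, 10, 10)),
               ignore_attr = TRUE)
})

test_that("threshold sweep covers all electrodes and picks the smallest optimum", {
  ph <- phantomPreset("clean", "Flex 20", seed = 2)
  roi <- extractROI(ph$volume, ph$gt$positions)
  sw <- parametrizeThreshold(roi, ph$gt$positions, lo = 0.01, hi = 0.5,
                             step = 0.01)
  expect_equal(sw$curve$alpha1, seq(0.01, 0.5, by = 0.01))
  expect_equal(max(sw$curve$coverage), 100)
  # chosen threshold is the smallest grid value attaining max coverage
  expect_identical(sw$alpha1,
                   sw$curve$alpha1[which(sw$curve$coverage == 100)[1]])
  # retained-voxel count is non-decreasing in alpha1; the skeleton size
  # follows the same trend up to single-voxel dips where thinning merges
  # branches (topological thinning is not strictly monotone in the mask)
  expect_true(all(diff(sw$curve$nVoxels) >= 0))
  expect_true(all(cummax(sw$curve$nCandidates) - sw$curve$nCandidates <= 2))
  expect_gte(tail(sw$curve$nCandidates, 1), sw$curve$nCandidates[1])
  # retained voxel fraction never exceeds alpha1
  expect_true(all(sw$curve$nVoxels <=
                  floor(sw$curve$alpha1 / 100 * length(roi@data))))

  # dim apical contacts: a too-low threshold misses them
  phDim <- phantomPreset("confusion", "Flex 24", seed = 2, noiseSigma = 0)
  roiDim <- extractROI(phDim$volume, phDim$gt$positions)
  csLow <- candidatesFromROI(roiDim, 0.2)
  covLow <- candidateCoverage(csLow, phDim$gt$positions)
  expect_lt(covLow, 100)
  # and the uncovered electrodes are the apical (dim) ones
  gtp <- phDim$gt$positions
  nd <- sapply(seq_len(nrow(gtp)), function(i)
    min(sqrt(colSums((t(coords(csLow)) - gtp[i, ])^2))))
  expect_true(all(which(nd > 0.9) >= 8))

  expect_error(parametrizeThreshold(roi, matrix(numeric(0), 0, 3)),
               "empty")
})
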