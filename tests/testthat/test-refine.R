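test_that("blob response preserves constants, peaks at blob centres and is linear", {
  vConst <- ctVolume(array(123.4, c(15, 15, 15)), 0.3, c(0, 0, 0))
  pts <- rbind(c(1, 1, 1), c(2.05, 1.77, 0.93))
  expect_equal(blobResponse(vConst, pts, 0.3), c(123.4, 123.4),
               tolerance = 1e-12)

  ctr <- c(2.02, 1.91, 2.13)
  vb <- blobVolume(ctr, peaks = 1000, sigma = 0.45, margin = 2)
  central <- blobResponse(vb, ctr, 0.3)
  for (dlt in list(c(0.12, 0, 0), c(-0.12, 0, 0), c(0, 0.12, 0),
                   c(0, -0.12, 0), c(0, 0, 0.12), c(0, 0, -0.12)))
    expect_gt(central, blobResponse(vb, ctr + dlt, 0.3))

  # linear in the image: response(A + B) = response(A) + response(B)
  ctr2 <- c(3.1, 2.2, 1.4)
  vb2 <- blobVolume(rbind(ctr, ctr2), peaks = c(1000, 700), sigma = 0.45,
                    margin = 2)
  q <- c(2.5, 2.0, 1.8)
  respSum <- blobResponse(vb2, q, 0.3)
  # build each blob separately on vb2's grid
  singles <- lapply(list(list(ctr, 1000), list(ctr2, 700)), function(b) {
    idx <- which(array(TRUE, dim(vb2@data)), arr.ind = TRUE)
    w <- indexToWorld(vb2, idx)
    a <- array(0, dim(vb2@data))
    a[idx] <- b[[2]] * exp(-rowSums(sweep(w, 2L, b[[1]], `-`)^2) /
                           (2 * 0.45^2))
    ctVolume(a, voxelSpacing(vb2), worldOrigin(vb2))
  })
  expect_equal(respSum,
               blobResponse(singles[[1]], q, 0.3) +
               blobResponse(singles[[2]], q, 0.3),
               tolerance = 1e-9)

  # at voxel centres the continuous evaluation agrees with the separable
  # discrete filter
  g <- gaussianFilterVolume(vb, 0.3)
  vc <- indexToWorld(vb, c(8, 8, 8))
  expect_equal(blobResponse(vb, vc, 0.3), sampleVolume(g, vc),
               tolerance = 1e-6 * max(vb@data))

  expect_error(blobResponse(vb, c(-5, 0, 0), 0.3), "outside")
})

test_that("refinement distance weights match the published constants", {
  rp <- refineParams()
  expect_equal(CIlocate:::refineDstPenalty(-0.1, rp), 5.0)
  expect_equal(CIlocate:::refineDstPenalty(0.1, rp), 2.0)
  expect_equal(CIlocate:::refineDstPenalty(0, rp), 0)
})

test_that("a node at an isolated blob centre with ideal spacing stays put", {
  spec <- toySpec(2, 1.8)
  ctrs <- rbind(c(3.0, 3.0, 3.0), c(4.8, 3.0, 3.0))
  v <- blobVolume(ctrs, peaks = 2000, sigma = 0.45, margin = 2.5)
  # nodes exactly at blob centres (centres sit on the voxel grid)
  path <- voxelPathFrom(ctrs)
  ref <- refinePath(v, path, spec, refineParams())
  expect_equal(pathNodes(ref), ctrs, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("an off-grid blob centre is recovered to within one grid step", {
  spec <- toySpec(2, 1.8)
  ctr <- c(3.05, 3.11, 2.93)  # displaced off the 0.3 mm voxel grid
  v <- blobVolume(ctr, peaks = 2000, sigma = 0.45, margin = 2.5)
  node <- c(2.9, 3.2, 3.1)    # a nearby voxel-grid point
  # single-node chain: distance term disabled
  path <- voxelPathFrom(matrix(node, 1), complete = FALSE)
  ref <- refinePath(v, path, toySpec(2, 1.8), refineParams())
  err <- sqrt(sum((pathNodes(ref) - ctr)^2))
  expect_lte(err, 0.12)
  # dense-grid oracle over the same window agrees
  offs <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3)) * 0.12
  g <- sweep(offs, 2L, node, `+`)
  bestOracle <- g[which.max(blobResponse(v, g, 0.3)), ]
  expect_equal(pathNodes(ref)[1, ], bestOracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("refinement never moves a node beyond the grid diagonal", {
  ph <- phantomPreset("clean", "Flex 20", seed = 5)
  res <- localizeElectrodes(ph$volume, ph$gt, ph$spec,
                            thresholdMode = "sweep", refine = FALSE)
  rp <- refineParams()
  ref <- refinePath(res$roi, res$path, ph$spec, rp)
  moved <- sqrt(rowSums((pathNodes(ref) - pathNodes(res$path))^2))
  expect_true(all(moved <= rp$gridStep * rp$gridHalf * sqrt(3) + 1e-12))
})

test_that("beam refinement equals exhaustive grid minimization (small chains)", {
  spec <- toySpec(2, 1.8)
  set.seed(17)
  ctrs <- rbind(c(3.02, 3.1, 2.95), c(4.87, 3.04, 3.12))
  v <- blobVolume(ctrs, peaks = 2000, sigma = 0.45, margin = 2.5)
  nodes <- round(ctrs / 0.3) * 0.3
  path <- voxelPathFrom(nodes)
  big <- refinePath(v, path, spec, refineParams(beamWidth = 10^6))
  expect_equal(pathCost(big), refineDPOracle(v, nodes, spec),
               tolerance = 1e-9)
  # the default narrow beam achieves the same optimum here
  small <- refinePath(v, path, spec, refineParams())
  expect_equal(pathCost(small), pathCost(big), tolerance = 1e-9)
})
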