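test_that("intensity cost normalizes and relaxes at the configured depth", {
  p <- costParams()
  expect_equal(costIntensity(2000, 1, 2000, p), 0)
  expect_equal(costIntensity(2000, 14, 2000, p), 0)
  expect_equal(costIntensity(0, 1, 2000, p), 1.0)
  expect_equal(costIntensity(0, 13, 2000, p), 1.0)
  expect_equal(costIntensity(0, 14, 2000, p), 0.1)
  expect_equal(costIntensity(c(500, 1500), 2, 2000, p), c(0.75, 0.25))
})

test_that("initial shape cost is the signed gap deviation from the seed", {
  seedPt <- c(0, 0, 0)
  expect_equal(costShapeInitial(matrix(c(1.9, 0, 0), 1), seedPt, 1.9), 0)
  expect_equal(costShapeInitial(matrix(c(2, 0, 0), 1), seedPt, 1.9), 0.1)
  expect_equal(costShapeInitial(matrix(c(1, 0, 0), 1), seedPt, 1.9), -0.9)
})

test_that("bend cosine distinguishes continuation, turn and reversal", {
  pPrev <- c(0, 0, 0); pLast <- c(1, 0, 0)
  expect_equal(bendCosine(matrix(c(2, 0, 0), 1), pLast, pPrev), 1)
  expect_equal(bendCosine(matrix(c(1, 1, 0), 1), pLast, pPrev), 0)
  expect_equal(bendCosine(matrix(c(0.2, 0, 0), 1), pLast, pPrev), -1)
  expect_error(bendCosine(matrix(c(1, 0, 0), 1), pLast, pPrev),
               "zero-length")
  expect_error(bendCosine(matrix(c(2, 0, 0), 1), pLast, pLast),
               "zero-length")
})

test_that("shape cost applies the published distance weights and bend penalty", {
  p <- costParams()
  path2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  # ideal continuation: gap exactly met, collinear
  expect_equal(costShape(matrix(c(2, 0, 0), 1), path2, 1, p), 0)
  # 0.1 mm too close / too far
  expect_equal(costShape(matrix(c(1.9, 0, 0), 1), path2, 1, p),
               0.52, tolerance = 1e-9)
  expect_equal(costShape(matrix(c(2.1, 0, 0), 1), path2, 1, p),
               0.20, tolerance = 1e-9)
  # right-angle bend at exact distance costs alpha5 * (1 - 0)
  expect_equal(costShape(matrix(c(1, 1, 0), 1), path2, 1, p), 1)
  # reversal costs 2 * alpha5 (distance term zero at exact gap)
  expect_equal(costShape(matrix(c(0, 0, 0), 1), path2, 1, p), 2)
  # gentle continuation above the 0.5 cosine threshold is free
  gentle <- matrix(c(1.9, 0.4, 0), 1)
  cz <- bendCosine(gentle, path2[2, ], path2[1, ])
  expect_gt(cz, 0.5)
  d <- sqrt(sum((gentle - path2[2, ])^2))
  expect_equal(costShape(gentle, path2, d, p), 0)
  # the literal printed formula is available behind the variant flag
  pPrint <- costParams(smoothingVariant = "as_printed")
  expect_equal(costShape(matrix(c(1, 1, 0), 1), path2, 1, pPrint), 0)
  expect_equal(costShape(matrix(c(2, 0, 0), 1), path2, 1, pPrint), 1)
  # single-node path: distance term only
  expect_equal(costShape(matrix(c(1.5, 0, 0), 1),
                         matrix(c(0, 0, 0), 1), 1, p), 1.0)
})

test_that("redetection cost walls off already-localized electrodes", {
  path <- rbind(c(0, 0, 0), c(1.9, 0, 0))
  a12 <- 2 / 3 * 1.9
  near <- matrix(c(0.5, 0, 0), 1)       # 0.5 mm from a node
  far <- matrix(c(1.9, 1.5, 0), 1)      # 1.5 mm from every node
  expect_identical(costRedetect(near, path, a12), Inf)
  expect_identical(costRedetect(far, path, a12), 0)
  # boundary: diff_min exactly alpha12 is still infinite (strict >)
  atA12 <- matrix(c(0, a12, 0), 1)
  expect_identical(costRedetect(atA12, path, a12), Inf)
})

test_that("the spacing window is strict and excludes path nodes", {
  cs <- toyCandidates(rbind(c(0.4, 0, 0),    # 0.4 * d: below lower bound
                            c(0.6, 0, 0),    # inside
                            c(2.0, 0, 0),    # exactly 2 d: excluded
                            c(1.0, 0, 0),    # inside
                            c(0.5, 0, 0)))   # exactly d / 2: excluded
  path <- matrix(c(0, 0, 0), 1)
  idx <- expandChildren(cs, path, 1)
  expect_identical(idx, c(2L, 4L))
  # a candidate coinciding with an existing node is excluded
  path2 <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1.0, 0, 0))
  idx2 <- expandChildren(cs, path2, 1)
  expect_false(4L %in% idx2)
})

test_that("a unique feasible chain is recovered exactly", {
  pts <- cbind(seq_len(5), 0, 0)
  cs <- toyCandidates(pts[-1, , drop = FALSE])
  spec <- toySpec(5, 1.0)
  res <- findPath(cs, pts[1, ], spec, costParams(costVariant = "baseline"),
                  imax = 2000)
  expect_true(isComplete(res))
  expect_equal(pathNodes(res), pts, ignore_attr = TRUE)
  # all shape terms vanish on the ideal chain (equal bright intensities)
  expect_equal(res@steps$costS, rep(0, 4), tolerance = 1e-12)
  expect_equal(pathCost(res), 0, tolerance = 1e-12)
})

test_that("beam search is deterministic and ignores non-path candidates", {
  set.seed(31)
  pts <- matrix(runif(30, 0, 4), 10, 3)
  cs <- toyCandidates(pts, runif(10, 800, 2000))
  spec <- toySpec(4, c(1.1, 0.9, 1.3))
  seedPt <- pts[1, ] + c(0.9, 0.4, 0)
  p <- costParams(beamWidth = 10^6)
  r1 <- findPath(cs, seedPt, spec, p)
  r2 <- findPath(cs, seedPt, spec, p)
  expect_identical(pathNodes(r1), pathNodes(r2))
  expect_identical(pathCost(r1), pathCost(r2))
  # removing a candidate that is not on the returned path changes nothing
  used <- apply(pathNodes(r1), 1, function(nd)
    which(colSums((t(pts) - nd)^2) == 0))
  used <- unlist(used)
  drop1 <- setdiff(seq_len(10), used)[1]
  cs2 <- toyCandidates(pts[-drop1, , drop = FALSE],
                       intensities(cs)[-drop1])
  r3 <- findPath(cs2, seedPt, spec, p)
  expect_equal(pathNodes(r3), pathNodes(r1))
  expect_equal(pathCost(r3), pathCost(r1))
})

test_that("infeasible extensions yield flagged incomplete paths", {
  cs <- toyCandidates(matrix(c(10, 10, 10), 1))
  spec <- toySpec(3, 1.0)
  res <- findPath(cs, c(0, 0, 0), spec)
  expect_false(isComplete(res))
  expect_identical(nrow(pathNodes(res)), 1L)
  # empty candidate set
  resE <- findPath(new("CandidateSet", coords = matrix(numeric(0), 0, 3),
                       intensity = numeric(), alpha1 = NA_real_,
                       cutoff = NA_real_), c(0, 0, 0), spec)
  expect_false(isComplete(resE))
})

test_that("saturating beam equals exhaustive enumeration on random instances", {
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(6:10, 1)
    L <- sample(3:4, 1)
    co <- matrix(runif(n * 3, 0, 4), n, 3)
    I <- runif(n, 500, 2000)
    cs <- toyCandidates(co, I)
    spec <- toySpec(L, runif(L - 1, 0.8, 1.4))
    seedPt <- runif(3, 1, 3)
    for (variant in c("baseline", "advanced")) {
      fp <- findPath(cs, seedPt, spec,
                     costParams(costVariant = variant, beamWidth = 10^6),
                     imax = 2000)
      oracle <- exhaustiveChain(cs, seedPt, spec, variant, imax = 2000)
      if (is.finite(oracle$cost)) {
        expect_true(isComplete(fp), info = paste(trial, variant))
        expect_equal(pathCost(fp), oracle$cost, tolerance = 1e-9,
                     info = paste(trial, variant))
        expect_equal(pathNodes(fp)[-1, , drop = FALSE],
                     co[oracle$chain, , drop = FALSE],
                     ignore_attr = TRUE, info = paste(trial, variant))
      } else {
        expect_false(isComplete(fp), info = paste(trial, variant))
      }
    }
  }
})

test_that("advanced-variant paths keep all nodes apart by the redetection radius", {
  ph <- phantomPreset("confusion", "Flex 24", seed = 4)
  res <- localizeElectrodes(ph$volume, ph$gt, ph$spec,
                            thresholdMode = "sweep",
                            params = costParams(costVariant = "advanced"),
                            refine = FALSE)
  nodes <- pathNodes(res$path)
  expect_gte(nrow(nodes), 2L)
  expect_gt(min(dist(nodes)), 2 / 3 * min(gapDistances(ph$spec)))
})
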