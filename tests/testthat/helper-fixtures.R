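# shared fixtures and independent oracles for the test suite

# minimal array spec for geometric tests
toySpec <- function(L, gaps) {
  if (length(gaps) == 1L) gaps <- rep(gaps, L - 1L)
  new("EASpec", name = "toy", manufacturer = "test",
      nElectrodes = as.integer(L), nMarkers = 0L,
      gapDistances = gaps, markerGap = NA_real_,
      apicalLowIntensity = 0L)
}

toyCandidates <- function(coords, intensity = rep(2000, nrow(coords))) {
  new("CandidateSet", coords = coords, intensity = intensity,
      alpha1 = NA_real_, cutoff = NA_real_)
}

voxelPathFrom <- function(nodes, complete = TRUE) {
  new("ElectrodePath", nodes = nodes, cost = 0,
      steps = data.frame(costI = numeric(), costS = numeric(),
                         costR = numeric(), total = numeric()),
      complete = complete)
}

# build a small volume of Gaussian blobs directly (independent of the
# package's rendering code)
blobVolume <- function(centers, peaks = 2000, sigma = 0.45, spacing = 0.3,
                       margin = 4) {
  centers <- matrix(centers, ncol = 3)
  peaks <- rep(peaks, length.out = nrow(centers))
  lo <- apply(centers, 2L, min) - margin
  hi <- apply(centers, 2L, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  a <- array(0, dims)
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - centers[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(zs - centers[i, 3])^2 / (2 * sigma^2))
    a <- a + peaks[i] * (gx %o% gy %o% gz)
  }
  ctVolume(a, spacing = spacing, origin = lo)
}

# Exhaustive minimum-cost chain enumeration, written independently of the
# beam search: plain recursion over all feasible chains with the cost
# formulas spelled out inline.
exhaustiveChain <- function(cs, seedPt, spec, variant = "baseline",
                            imax = 2000) {
  co <- coords(cs)
  I <- intensities(cs)
  L <- nElectrodes(spec)
  gaps <- rev(gapDistances(spec))  # base-to-apex
  best <- list(cost = Inf, chain = NULL)
  n <- nrow(co)
  rec <- function(chain, cost, k) {
    if (k == L) {
      if (cost < best$cost) best <<- list(cost = cost, chain = chain)
      return(invisible())
    }
    d <- gaps[k]
    pathm <- rbind(seedPt,
                   co[chain, , drop = FALSE])
    last <- pathm[nrow(pathm), ]
    for (ci in seq_len(n)) {
      p <- co[ci, ]
      dd <- sqrt(sum((p - last)^2))
      if (!(dd > d / 2 && dd < 2 * d)) next
      if (any(rowSums(sweep(pathm, 2L, p, `-`)^2) == 0)) next
      if (variant == "advanced" &&
          min(sqrt(rowSums(sweep(pathm, 2L, p, `-`)^2))) <= 2 / 3 * d) next
      fac <- if (k >= 14) 0.1 else 1
      cI <- (imax - I[ci]) / 2000 * fac
      if (k == 1L) {
        cS <- dd - d
      } else {
        prev <- pathm[nrow(pathm) - 1L, ]
        u <- p - last
        w <- last - prev
        cz <- sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))
        x <- if (cz < 0.5) cz else 1
        dst <- dd - d
        cS <- 1.0 * (1 - x) + if (dst < 0) -5.2 * dst else 2.0 * dst
      }
      rec(c(chain, ci), cost + cI + cS, k + 1L)
    }
  }
  rec(integer(), 0, 1L)
  best
}

# Exact minimization of the refinement objective over all grid
# combinations by dynamic programming over consecutive levels (the cost is
# a chain of pairwise terms, so the DP minimum equals the exhaustive
# minimum over all grid combinations).
refineDPOracle <- function(v, nodes, spec, rp = refineParams()) {
  k <- nrow(nodes)
  offs <- as.matrix(expand.grid(x = -rp$gridHalf:rp$gridHalf,
                                y = -rp$gridHalf:rp$gridHalf,
                                z = -rp$gridHalf:rp$gridHalf)) * rp$gridStep
  grids <- lapply(seq_len(k), function(i) sweep(offs, 2L, nodes[i, ], `+`))
  resp <- lapply(grids, function(g) blobResponse(v, g, rp$sigma))
  pen <- function(dist, gap) {
    dst <- dist - gap
    ifelse(dst < 0, -rp$alpha10 * dst, rp$alpha11 * dst)
  }
  cur <- -resp[[1]]
  if (k >= 2L) {
    d1 <- sqrt(colSums((t(grids[[1]]) - nodes[2, ])^2))
    cur <- cur + pen(d1, gapFromBase(spec, 1L))
    for (i in 2:k) {
      D <- sqrt(pmax(outer(rowSums(grids[[i - 1L]]^2),
                           rowSums(grids[[i]]^2), `+`) -
                     2 * grids[[i - 1L]] %*% t(grids[[i]]), 0))
      cur <- apply(cur + pen(D, gapFromBase(spec, i - 1L)), 2, min) -
        resp[[i]]
    }
  }
  min(cur)
}

# sort-based oracle for the top-quantile threshold: number of voxels at or
# above the returned cutoff, never exceeding floor(alpha1% of n)
thresholdCountOracle <- function(x, alpha1) {
  n <- length(x)
  k <- floor(alpha1 / 100 * n)
  s <- sort(x, decreasing = TRUE)
  # walk down the sorted values; stop before a tie block would overflow k
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    if (j > k) break
    cnt <- j
    i <- j + 1L
  }
  cnt
}
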