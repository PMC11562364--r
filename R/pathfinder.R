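#' Cost parameters for the electrode chain beam search
#'
#' Defaults follow the published parametrization of the graph-based
#' localization method: intensity relaxation `alpha3 = 0.1` from path
#' length `alpha4 = 14`, intensity normalization by 2000, shape weights
#' `alpha5 = 1`, `alpha6 = 5.2` (too-short penalty per mm), `alpha7 = 2`
#' (too-long penalty per mm), beam width `P = 10`, and redetection radius
#' `alpha12` of two thirds of the (local) electrode gap.
#'
#' `smoothingVariant` selects the bending term: `"penalize_bends"`
#' (default) charges `alpha5 * (1 - X)` with `X = Cos` when `Cos < 0.5`
#' else `1`, i.e. zero for a gentle continuation and up to `2 * alpha5` for
#' a reversal, honoring the stated contract that sharp bends are expensive;
#' `"as_printed"` evaluates the literal printed formula
#' `alpha5 - (1 - X)`, retained for fidelity experiments.
#'
#' `costVariant = "advanced"` adds the redetection term `C_R` that assigns
#' infinite cost to any candidate closer than `alpha12` to an existing path
#' node, eliminating double detection and apical-basal confusion.
#'
#' @param alpha3 intensity relaxation factor for deep path positions.
#' @param alpha4 path length from which the relaxation applies.
#' @param alpha5,alpha6,alpha7 shape-cost weights (see above).
#' @param alpha12 redetection radius in mm, or `NULL` for
#'   `2/3 * local gap`.
#' @param beamWidth number of partial paths kept per level (P).
#' @param intensityNorm intensity normalization constant.
#' @param smoothingVariant `"penalize_bends"` or `"as_printed"`.
#' @param costVariant `"baseline"` or `"advanced"`.
#' @return A list of class `CostParams`.
#' @export
costParams <- function(alpha3 = 0.1, alpha4 = 14, alpha5 = 1.0,
                       alpha6 = 5.2, alpha7 = 2.0, alpha12 = NULL,
                       beamWidth = 10L, intensityNorm = 2000,
                       smoothingVariant = c("penalize_bends", "as_printed"),
                       costVariant = c("advanced", "baseline")) {
  stopifnot(beamWidth >= 1, intensityNorm > 0, alpha3 >= 0, alpha5 >= 0,
            alpha6 >= 0, alpha7 >= 0, is.null(alpha12) || alpha12 >= 0)
  structure(list(alpha3 = alpha3, alpha4 = alpha4, alpha5 = alpha5,
                 alpha6 = alpha6, alpha7 = alpha7, alpha12 = alpha12,
                 beamWidth = as.integer(beamWidth),
                 intensityNorm = intensityNorm,
                 smoothingVariant = match.arg(smoothingVariant),
                 costVariant = match.arg(costVariant)),
            class = "CostParams")
}

#' Intensity cost of a candidate
#'
#' `C_I = (Imax - I(c)) / intensityNorm`, scaled by `alpha3` once the path
#' has reached length `alpha4` (the intensity demand is relaxed for the
#' apical end of long arrays, whose contacts image dimmer).
#'
#' @param intensity candidate intensity (vectorized).
#' @param pathLen current path length i (before the extension).
#' @param imax maximum intensity of the region of interest.
#' @param params a [costParams()] list.
#' @return Non-negative cost, same length as `intensity`.
#' @export
costIntensity <- function(intensity, pathLen, imax, params = costParams()) {
  fac <- if (pathLen >= params$alpha4) params$alpha3 else 1
  (imax - intensity) / params$intensityNorm * fac
}

#' Initial shape cost (first extension from the seed)
#'
#' Signed deviation of the candidate's distance from the seed from the
#' first inter-electrode gap: `||c - p1|| - d1` (as printed; may be
#' negative).
#'
#' @param cand n x 3 matrix of candidate positions (mm).
#' @param seed numeric(3), the seed node (most basal electrode).
#' @param d1 first gap distance in mm (> 0).
#' @return numeric(n).
#' @export
costShapeInitial <- function(cand, seed, d1) {
  stopifnot(d1 > 0)
  cand <- rbindable(cand)
  sqrt(colSums((t(cand) - as.numeric(seed))^2)) - d1
}

#' Cosine of the turning angle at a path extension
#'
#' `Cos = (c - p_i) . (p_i - p_{i-1}) / (||c - p_i|| ||p_i - p_{i-1}||)`:
#' 1 for a collinear continuation, 0 for a right angle, -1 for a reversal.
#'
#' @param cand n x 3 matrix of candidate positions.
#' @param pLast,pPrev the last two path nodes.
#' @return numeric(n) in `[-1, 1]`.
#' @export
bendCosine <- function(cand, pLast, pPrev) {
  cand <- rbindable(cand)
  pLast <- as.numeric(pLast)
  pPrev <- as.numeric(pPrev)
  u <- sweep(cand, 2L, pLast, `-`)
  w <- pLast - pPrev
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(sum(w^2))
  if (nw == 0 || any(nu == 0))
    stop("zero-length segment in bend computation")
  pmin(pmax(as.numeric(u %*% w) / (nu * nw), -1), 1)
}

#' Shape cost of a path extension
#'
#' Sum of a bending (smoothing) term and a distance term. The distance
#' term charges `-alpha6 * Dst` when the candidate is too close
#' (`Dst = ||c - p_i|| - d_i < 0`) and `alpha7 * Dst` when too far. The
#' bending term follows `params$smoothingVariant` (see [costParams()]) and
#' is skipped when the path has fewer than two nodes.
#'
#' @param cand n x 3 matrix of candidate positions.
#' @param pathNodes k x 3 matrix of current path nodes.
#' @param d_i expected gap to the next electrode in mm.
#' @param params a [costParams()] list.
#' @return numeric(n).
#' @export
costShape <- function(cand, pathNodes, d_i, params = costParams()) {
  cand <- rbindable(cand)
  pathNodes <- rbindable(pathNodes)
  k <- nrow(pathNodes)
  pLast <- pathNodes[k, ]
  dst <- sqrt(colSums((t(cand) - pLast)^2)) - d_i
  cost <- ifelse(dst < 0, -params$alpha6 * dst, params$alpha7 * dst)
  if (k >= 2L) {
    cs <- bendCosine(cand, pLast, pathNodes[k - 1L, ])
    x <- ifelse(cs < 0.5, cs, 1)
    cost <- cost + if (params$smoothingVariant == "penalize_bends")
      params$alpha5 * (1 - x)
    else params$alpha5 - (1 - x)
  }
  cost
}

#' Redetection cost C_R
#'
#' The advanced cost term: the minimum Euclidean distance `diff_min` from
#' the candidate to every node already in the path is compared against the
#' redetection radius `alpha12`; the cost is 0 when `diff_min > alpha12`
#' and infinite otherwise, so the chain can never return to the
#' neighborhood of an electrode it has already localized.
#'
#' @param cand n x 3 matrix of candidate positions.
#' @param pathNodes k x 3 matrix of current path nodes.
#' @param alpha12 redetection radius in mm (typically `2/3` of the local
#'   gap).
#' @return numeric(n) of 0 / `Inf`.
#' @export
costRedetect <- function(cand, pathNodes, alpha12) {
  cand <- rbindable(cand)
  pathNodes <- rbindable(pathNodes)
  diffMin <- rep(Inf, nrow(cand))
  for (j in seq_len(nrow(pathNodes))) {
    dj <- sqrt(colSums((t(cand) - pathNodes[j, ])^2))
    diffMin <- pmin(diffMin, dj)
  }
  ifelse(diffMin > alpha12, 0, Inf)
}

#' Candidates eligible to extend a path
#'
#' The spacing window: candidates strictly inside
#' `(d_i / 2, 2 * d_i)` of the last path node, excluding candidates
#' coinciding exactly with an existing node.
#'
#' @param cs a [CandidateSet-class].
#' @param pathNodes k x 3 matrix of current path nodes.
#' @param d_i expected gap in mm.
#' @return Integer indices into the candidate set.
#' @export
expandChildren <- function(cs, pathNodes, d_i) {
  pathNodes <- rbindable(pathNodes)
  pLast <- pathNodes[nrow(pathNodes), ]
  d <- sqrt(colSums((t(cs@coords) - pLast)^2))
  ok <- d > d_i / 2 & d < 2 * d_i
  if (any(ok)) {
    inPath <- vapply(which(ok), function(i)
      any(rowSums(sweep(pathNodes, 2L, cs@coords[i, ], `-`)^2) == 0),
      logical(1))
    ok[which(ok)[inPath]] <- FALSE
  }
  which(ok)
}

#' Beam-search localization of the electrode chain
#'
#' Builds the L-node electrode chain from the basal seed over a candidate
#' set. The first extension is scored by `C_I + C_S_initial`; subsequent
#' extensions by `C_I + C_S` (baseline) or `C_I + C_S + C_R` (advanced).
#' Costs accumulate additively; after each level only the `P` lowest-cost
#' partial paths survive (stable tie-break by generation order). Candidates
#' with infinite cost are removed before accumulation. If no complete
#' L-node chain exists, the longest achieved path is returned flagged
#' incomplete.
#'
#' @param cs a [CandidateSet-class].
#' @param seed numeric(3) mm, position of the most basal electrode (path
#'   node 1).
#' @param spec an [EASpec-class] providing L and the gap distances.
#' @param params a [costParams()] list.
#' @param imax maximum ROI intensity for the intensity cost; defaults to
#'   the maximum candidate intensity.
#' @return An [ElectrodePath-class].
#' @export
findPath <- function(cs, seed, spec, params = costParams(),
                     imax = if (length(cs@intensity)) max(cs@intensity) else 0) {
  seed <- as.numeric(seed)
  L <- spec@nElectrodes
  P <- params$beamWidth
  emptySteps <- data.frame(costI = numeric(), costS = numeric(),
                           costR = numeric(), total = numeric())
  # beam state: node index sequences (0 = seed), accumulated cost, steps
  beam <- list(list(nodes = matrix(seed, 1L, 3L), cost = 0,
                    steps = emptySteps))
  if (nrow(cs@coords) == 0L)
    return(new("ElectrodePath", nodes = beam[[1]]$nodes, cost = 0,
               steps = emptySteps, complete = (L == 1L)))
  for (k in seq_len(L - 1L)) {
    d_i <- gapFromBase(spec, k)
    a12 <- if (is.null(params$alpha12)) 2 / 3 * d_i else params$alpha12
    ext <- list()
    for (b in seq_along(beam)) {
      pb <- beam[[b]]
      idx <- expandChildren(cs, pb$nodes, d_i)
      if (length(idx) == 0L) next
      cand <- cs@coords[idx, , drop = FALSE]
      cI <- costIntensity(cs@intensity[idx], pathLen = k, imax = imax,
                          params = params)
      cS <- if (k == 1L) costShapeInitial(cand, seed, d_i)
            else costShape(cand, pb$nodes, d_i, params)
      cR <- if (params$costVariant == "advanced")
        costRedetect(cand, pb$nodes, a12) else rep(0, length(idx))
      total <- cI + cS + cR
      keep <- is.finite(total)
      if (!any(keep)) next
      ext[[length(ext) + 1L]] <- data.frame(
        b = b, cand = idx[keep], costI = cI[keep], costS = cS[keep],
        costR = cR[keep], stepTotal = total[keep],
        newCost = pb$cost + total[keep])
    }
    if (length(ext) == 0L) break
    ext <- do.call(rbind, ext)
    if (nrow(ext) > P) {
      ord <- order(ext$newCost, seq_len(nrow(ext)))[seq_len(P)]
      ext <- ext[ord, , drop = FALSE]
    }
    beam <- lapply(seq_len(nrow(ext)), function(r) {
      e <- ext[r, ]
      pb <- beam[[e$b]]
      list(nodes = rbind(pb$nodes, cs@coords[e$cand, ]),
           cost = e$newCost,
           steps = rbind(pb$steps,
                         data.frame(costI = e$costI, costS = e$costS,
                                    costR = e$costR, total = e$stepTotal)))
    })
  }
  best <- beam[[which.min(vapply(beam, `[[`, 0, "cost"))]]
  new("ElectrodePath", nodes = unname(best$nodes), cost = best$cost,
      steps = best$steps, complete = nrow(best$nodes) == L)
}
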