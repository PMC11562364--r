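#' Configuration for a phantom experiment battery
#'
#' @param specNames registered array names to include.
#' @param preset phantom preset per array (recycled): `"clean"`,
#'   `"confusion"` or `"artifacts"`.
#' @param seeds integer seeds; each (spec, seed) pair is one rendered
#'   phantom.
#' @param variants cost variants to run on every phantom.
#' @param thresholdMode `"sweep"` picks the per-array threshold once by
#'   coverage sweep on the first-seed phantom (mirroring per-array
#'   threshold individualization); `"individual"` / `"generalized"` use
#'   registry values.
#' @param refine logical; run sub-voxel refinement.
#' @return A list of class `BatteryConfig`.
#' @export
batteryConfig <- function(specNames = names(eaRegistry()),
                          preset = "clean", seeds = 1:3,
                          variants = c("baseline", "advanced"),
                          thresholdMode = c("sweep", "individual",
                                            "generalized"),
                          refine = TRUE) {
  stopifnot(length(seeds) >= 1L)
  for (nm in specNames) getSpec(nm)  # validates registration
  structure(list(specNames = specNames,
                 preset = rep(preset, length.out = length(specNames)),
                 seeds = as.integer(seeds), variants = variants,
                 thresholdMode = match.arg(thresholdMode),
                 refine = refine),
            class = "BatteryConfig")
}

#' Run a phantom experiment battery
#'
#' For every (array, seed, cost variant) combination: generate the phantom,
#' localize, refine, evaluate. Per-array thresholds are chosen once per
#' array (not per seed) when `thresholdMode = "sweep"`. Failures of
#' individual cases are recorded and the battery continues. Fully
#' deterministic given the config seeds.
#'
#' @param cfg a [batteryConfig()].
#' @return A list: `cases` (one row per case: spec, seed, variant, alpha1,
#'   detection rate, accuracy, conditional accuracy, error-class flags,
#'   min pairwise node distance, completeness, error message if failed)
#'   and `summary` (per spec x variant aggregates).
#' @export
runBattery <- function(cfg) {
  rows <- list()
  for (si in seq_along(cfg$specNames)) {
    specName <- cfg$specNames[si]
    spec <- getSpec(specName)
    preset <- cfg$preset[si]
    alpha1 <- NA_real_
    for (seed in cfg$seeds) {
      ph <- phantomPreset(preset, spec, seed = seed)
      if (is.na(alpha1)) {
        alpha1 <- switch(cfg$thresholdMode,
          sweep = {
            roi <- extractROI(ph$volume, ph$gt$positions)
            parametrizeThreshold(roi, ph$gt$positions)$alpha1
          },
          individual = getThreshold(specName, "individual"),
          generalized = getThreshold(specName, "generalized"))
      }
      for (variant in cfg$variants) {
        res <- tryCatch(
          localizeElectrodes(ph$volume, ph$gt, spec,
                             thresholdMode = "value", alpha1 = alpha1,
                             params = costParams(costVariant = variant),
                             refine = cfg$refine),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            spec = specName, preset = preset, seed = seed,
            variant = variant, alpha1 = alpha1,
            detectionRate = NA_real_, accuracy = NA_real_,
            conditionalAccuracy = NA_real_, complete = NA,
            minPairwise = NA_real_, minPairwiseVoxel = NA_real_,
            doubleDetection = NA,
            abConfusion = NA, artifactDetection = NA,
            errorLabels = NA_character_,
            failure = conditionMessage(res))
          next
        }
        rep <- res$report
        nodes <- res$path@nodes
        minPair <- if (nrow(nodes) >= 2L) min(dist(nodes)) else NA_real_
        vn <- res$voxelPath@nodes
        minPairVox <- if (nrow(vn) >= 2L) min(dist(vn)) else NA_real_
        lbl <- rep@errorLabels
        rows[[length(rows) + 1L]] <- data.frame(
          spec = specName, preset = preset, seed = seed, variant = variant,
          alpha1 = alpha1, detectionRate = rep@detectionRate,
          accuracy = rep@accuracy,
          conditionalAccuracy = rep@conditionalAccuracy,
          complete = res$path@complete, minPairwise = minPair,
          minPairwiseVoxel = minPairVox,
          doubleDetection = "double_detection" %in% lbl,
          abConfusion = any(grepl("^ab_confusion", lbl)),
          artifactDetection = "artifact_detection" %in% lbl,
          errorLabels = paste(lbl, collapse = ";"),
          failure = NA_character_)
      }
    }
  }
  cases <- do.call(rbind, rows)
  ok <- is.na(cases$failure)
  agg <- aggregate(
    cases[ok, c("detectionRate", "accuracy", "doubleDetection",
                "abConfusion", "artifactDetection")],
    by = list(spec = cases$spec[ok], variant = cases$variant[ok]),
    FUN = mean)
  names(agg) <- c("spec", "variant", "meanDetectionRate", "meanAccuracy",
                  "fracDoubleDetection", "fracAbConfusion",
                  "fracArtifactDetection")
  list(cases = cases, summary = agg)
}

#' Paired comparison of cost variants across battery seeds
#'
#' Convenience paired sign test (not the clinical-study statistics) on
#' per-seed detection-rate differences between two variants of the same
#' battery.
#'
#' @param cases the `cases` table from [runBattery()].
#' @param better,worse variant names to compare.
#' @return A list: `diffs` (per spec x seed detection-rate differences),
#'   `nBetter`, `nWorse`, `pValue` (two-sided sign test).
#' @export
compareVariants <- function(cases, better = "advanced",
                            worse = "baseline") {
  a <- cases[cases$variant == better & is.na(cases$failure), ]
  b <- cases[cases$variant == worse & is.na(cases$failure), ]
  key <- function(d) paste(d$spec, d$seed)
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), ]
  b <- b[match(common, key(b)), ]
  diffs <- data.frame(spec = a$spec, seed = a$seed,
                      deltaDetection = a$detectionRate - b$detectionRate,
                      deltaAccuracy = a$accuracy - b$accuracy)
  nB <- sum(diffs$deltaDetection > 0)
  nW <- sum(diffs$deltaDetection < 0)
  p <- if (nB + nW > 0)
    stats::binom.test(nB, nB + nW)$p.value else NA_real_
  list(diffs = diffs, nBetter = nB, nWorse = nW, pValue = p)
}
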