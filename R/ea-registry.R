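#' Registry of commercial electrode-array specifications
#'
#' The package ships a registry of ten commercial cochlear-implant
#' electrode arrays (four manufacturers), together with the per-array
#' cumulative-histogram threshold values used for candidate extraction.
#' Arrays whose published spacing is a range (perimodiolar designs such as
#' Hybrid-L with 0.6--0.8 mm) are expanded to a per-gap list by linear
#' interpolation from the apical extreme to the basal extreme of the
#' printed range, in apex-to-base order; this interpolation is a documented
#' modelling choice, not a manufacturer datum.
#'
#' @param path optional path to a user registry file (tab-separated, same
#'   columns as the shipped `extdata/electrode_arrays.tsv`); the default is
#'   the built-in registry.
#' @return `eaRegistry`: a named list of [EASpec-class] objects.
#' @examples
#' names(eaRegistry())
#' getSpec("Flex 24")
#' @export
eaRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "electrode_arrays.tsv",
                        package = "CIlocate", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  req <- c("name", "manufacturer", "n_electrodes", "n_markers", "gaps_mm",
           "marker_gap_mm", "apical_low_intensity")
  if (!all(req %in% names(df)))
    stop("registry file must have columns ", paste(req, collapse = ", "))
  specs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    L <- as.integer(r$n_electrodes)
    new("EASpec", name = r$name, manufacturer = r$manufacturer,
        nElectrodes = L, nMarkers = as.integer(r$n_markers),
        gapDistances = parseGaps(r$gaps_mm, L),
        markerGap = as.numeric(r$marker_gap_mm),
        apicalLowIntensity = as.integer(r$apical_low_intensity))
  })
  thr <- if ("alpha1_pct" %in% names(df)) as.numeric(df$alpha1_pct)
         else rep(NA_real_, nrow(df))
  attr(specs, "alpha1") <- setNames(thr, df$name)
  setNames(specs, df$name)
}

# "2.1" -> constant gaps; "0.6-0.8" -> linear apex-to-base interpolation;
# "a,b,c" -> explicit per-gap list (length L-1)
parseGaps <- function(s, L) {
  s <- trimws(as.character(s))
  if (grepl(",", s)) {
    g <- as.numeric(strsplit(s, ",")[[1]])
    if (length(g) != L - 1L)
      stop("explicit gap list must have length ", L - 1L)
    return(g)
  }
  if (grepl("^[0-9.]+-[0-9.]+$", s)) {
    ends <- as.numeric(strsplit(s, "-")[[1]])
    return(seq(ends[1], ends[2], length.out = L - 1L))
  }
  rep(as.numeric(s), L - 1L)
}

# package-level cache of the built-in registry
.registryCache <- new.env(parent = emptyenv())

builtinRegistry <- function() {
  if (is.null(.registryCache$reg)) .registryCache$reg <- eaRegistry()
  .registryCache$reg
}

#' Look up one electrode-array specification
#'
#' @param name registered array name (see `names(eaRegistry())`), or a name
#'   present in `registry`.
#' @param registry a registry list from [eaRegistry()]; defaults to the
#'   built-in one.
#' @return An [EASpec-class].
#' @examples
#' getSpec("Hybrid-L")
#' @export
getSpec <- function(name, registry = builtinRegistry()) {
  if (!name %in% names(registry))
    stop("unknown electrode array \"", name, "\"; available: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]
}

#' Cumulative-histogram threshold for an electrode array
#'
#' Returns the candidate-extraction threshold alpha_1 (percent of retained
#' brightest ROI voxels). In `"individual"` mode the per-array value from
#' the registry is returned; in `"generalized"` mode the single value
#' 2.66\% shared across all arrays is returned.
#'
#' @param name registered array name (ignored for the generalized mode
#'   except for validation when provided).
#' @param mode `"individual"` or `"generalized"`.
#' @param registry registry list from [eaRegistry()].
#' @return Threshold in percent.
#' @examples
#' getThreshold("Flex 24", "individual")  # 0.96
#' getThreshold("SlimJ", "generalized")   # 2.66
#' @export
getThreshold <- function(name, mode = c("individual", "generalized"),
                         registry = builtinRegistry()) {
  mode <- match.arg(mode)
  if (mode == "generalized") return(2.66)
  thr <- attr(registry, "alpha1")
  if (is.null(thr) || !name %in% names(thr) || is.na(thr[[name]]))
    stop("no individual threshold registered for \"", name, "\"; available: ",
         paste(names(thr)[!is.na(thr)], collapse = ", "))
  unname(thr[[name]])
}

#' Serialize electrode-array specifications to a registry file
#'
#' Writes specs in the same tab-separated format read by [eaRegistry()],
#' with explicit per-gap lists so that reloading reproduces the specs
#' exactly.
#'
#' @param specs a list of [EASpec-class] objects (or a registry).
#' @param path output file path.
#' @param alpha1 optional named numeric of per-array thresholds; defaults
#'   to the `alpha1` attribute of `specs` when present.
#' @return `path`, invisibly.
#' @export
writeEARegistry <- function(specs, path, alpha1 = attr(specs, "alpha1")) {
  rows <- lapply(specs, function(s) {
    data.frame(name = s@name, manufacturer = s@manufacturer,
      n_electrodes = s@nElectrodes, n_markers = s@nMarkers,
      gaps_mm = paste(format(s@gapDistances, digits = 15, trim = TRUE),
                      collapse = ","),
      marker_gap_mm = s@markerGap,
      apical_low_intensity = s@apicalLowIntensity,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$alpha1_pct <- if (!is.null(alpha1)) as.numeric(alpha1[df$name])
                   else NA_real_
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append the non-stimulating marker contact as an extra basal chain node
#'
#' Some arrays carry a non-stimulating marker contact basal to the active
#' contacts (e.g. 3 mm from the most basal electrode). By default
#' localization covers active contacts only; this helper returns a spec
#' with the marker appended as an additional most-basal node, so the chain
#' search includes it explicitly.
#'
#' @param spec an [EASpec-class] with `nMarkers >= 1` and a finite
#'   `markerGap`.
#' @return An [EASpec-class] with `nElectrodes + 1` contacts and the
#'   marker gap appended at the basal end of the gap list.
#' @export
includeMarker <- function(spec) {
  if (spec@nMarkers < 1L)
    stop("spec \"", spec@name, "\" has no marker contact")
  if (!is.finite(spec@markerGap))
    stop("spec \"", spec@name, "\" has no registered marker gap distance")
  new("EASpec", name = paste0(spec@name, " (+marker)"),
      manufacturer = spec@manufacturer,
      nElectrodes = spec@nElectrodes + 1L, nMarkers = 0L,
      # apex-to-base ordering: the marker gap is the most basal gap
      gapDistances = c(spec@gapDistances, spec@markerGap),
      markerGap = NA_real_,
      apicalLowIntensity = spec@apicalLowIntensity)
}

#' Gap distance used when extending a k-node path
#'
#' Gap distances are stored apex-to-base (`gapDistances(spec)[i]` separates
#' electrodes i and i+1 counted from the apex). Path construction proceeds
#' base to apex, so the gap used when extending a path of length `k` (i.e.
#' between electrodes `k` and `k + 1` counted from the base) is apex-to-base
#' gap index `L - k`.
#'
#' @param spec an [EASpec-class].
#' @param k current path length, `1 <= k <= L - 1`.
#' @return Gap distance in mm.
#' @export
gapFromBase <- function(spec, k) {
  L <- spec@nElectrodes
  stopifnot(k >= 1L, k <= L - 1L)
  spec@gapDistances[L - k]
}
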