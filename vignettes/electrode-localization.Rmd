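---
title: "Graph-based localization of cochlear-implant electrodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based localization of cochlear-implant electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CIlocate)
```

## The problem

A cochlear implant stimulates the auditory nerve through an array of
electrode contacts surgically inserted into the cochlea. Postoperative cone
beam CT (CBCT) shows each metal contact as a bright, roughly blob-shaped
artifact a few voxels across (clinical resolution is typically 0.3 mm
isotropic). Research and fitting applications need the 3D position of every
contact, ordered from the basal end of the array to the apex.

Two properties make this harder than generic blob detection:

* the cochlea is a spiral. For deeply inserted arrays (insertion angle
  beyond 360°) the distance between adjacent *turns* of the spiral is close
  to the distance between adjacent *contacts*, so a chain-building
  algorithm can jump between turns and either re-detect a contact it has
  already localized or walk the array in the wrong direction
  (apical–basal confusion);
* on several common arrays the apical contacts image dimmer than the basal
  ones (single- vs double-contact construction), so brightness alone
  under-detects exactly the contacts that are hardest to reach.

`CIlocate` implements a graph-based localization pipeline for distantly
spaced arrays, its "advanced" anti-redetection cost term, the standard
evaluation metrics, and a synthetic phantom generator that reproduces the
geometric regime in which the confusion failure occurs — so the whole
pipeline can be exercised and regression-tested without clinical scans.

## Pipeline and cost model

Inputs: a volume (NIfTI/NRRD), the array specification (built-in registry
of ten commercial arrays), and ground-truth/seed coordinates (the ROI and
seed come from expert labels; automatic ROI segmentation is out of scope).

1. **ROI extraction** (`extractROI`): axis-aligned crop keeping at least
   3 mm per face around every labeled position. World coordinates are
   preserved exactly; all downstream geometry is in mm, so the pipeline is
   correct at non-0.3 mm resolutions too.
2. **Candidate extraction** (`candidatesFromROI`): the threshold α₁ is a
   *top-quantile* of the ROI intensities — the cutoff is the smallest
   observed intensity such that at most α₁% of ROI voxels lie at or above
   it (ties kept above, so the retained count never exceeds the quota).
   The resulting mask is thinned to a one-voxel-wide centerline skeleton
   and every skeleton voxel becomes a candidate point carrying its raw
   voxel intensity.
3. **Chain search** (`findPath`): beam search from the seed (most basal
   contact), beam width P = 10, one level per electrode. Extensions obey
   the strict spacing window (dᵢ/2, 2dᵢ) and are scored by the intensity
   cost, the shape cost, and — in the advanced variant — the redetection
   cost C_R which is infinite within α₁₂ = ⅔·dᵢ of any existing node.
   Infinite-cost extensions are pruned before accumulation; ties are broken
   stably by generation order, so results are deterministic.
4. **Sub-voxel refinement** (`refinePath`): per-node 7×7×7 offset grids
   (step 0.12 mm), scored by −G_σ (Gaussian blob response, σ = 0.3 mm)
   plus a spacing penalty, accumulated by the same beam search.

### Parameters

| parameter | default | meaning |
|---|---|---|
| α₁ | per-array (0.20–2.66%), generalized 2.66% | top-quantile mask threshold |
| α₃, α₄ | 0.1, 14 | intensity-cost relaxation factor and the chain length from which it applies |
| α₅ | 1.0 | bending-penalty scale (0 for gentle continuation, 2α₅ for reversal) |
| α₆, α₇ | 5.2, 2.0 per mm | spacing deviation weights (too short / too long) |
| P | 10 | beam width |
| α₁₂ | ⅔ · local gap | redetection radius (advanced variant) |
| α₈, α₉ | 0.12 mm, 3 | refinement grid step and half-extent (±0.36 mm window) |
| σ | 0.3 mm | blob-response Gaussian scale |
| α₁₀, α₁₁ | 50, 20 per mm | refinement spacing weights |
| detection radius | 0.9 mm | evaluation tolerance (3 voxels at 0.3 mm) |

Notes on choices the printed formulas left open:

* **Bending term.** The printed smoothing formula assigns *lower* cost to
  sharper bends, contradicting its stated purpose. The default
  (`smoothingVariant = "penalize_bends"`) charges α₅·(1 − X) with X = Cos
  below 0.5 and 1 otherwise — zero for gentle continuation, up to 2α₅ for a
  reversal. The literal formula remains available as `"as_printed"` for
  fidelity experiments.
* **Intensity relaxation.** With α₄ = 14 the relaxation never triggers for
  12-contact arrays even though it is motivated by dim apical contacts;
  it is implemented as specified and α₄ is configurable.
* **α₁₂ for variable-pitch arrays** derives from the *local* gap
  (⅔·dᵢ) rather than one global spacing; for constant-spacing arrays the
  two coincide.
* **Refinement grid.** The grid is the integer lattice −3…3 scaled by
  0.12 mm (a ±0.36 mm window, ±1.2 voxels), matching the original method's
  intent; literal mm-valued lattice coordinates would make the window
  microscopic.
* **Blob response sampling.** G_σ is evaluated as the continuous
  Gaussian-weighted average of voxel intensities centred on the query
  position (normalized over in-volume support). Sampling a *discretely*
  filtered volume trilinearly instead would make the response piecewise
  multilinear, whose maxima sit only at voxel centres — refinement would
  then snap back to the voxel grid and sub-voxel recovery would be
  impossible. At voxel centres the two definitions coincide
  (`gaussianFilterVolume` is provided and cross-checked in the tests).
* **Thresholds with ties.** The cutoff is the smallest *observed* intensity
  meeting the quota; a constant ROI degenerates to "retain everything" with
  a warning.
* **First refined node.** The seed has no predecessor, so its refinement
  distance term is referenced to its (unrefined) successor; for a
  single-node chain the distance term is dropped. C_R is not applied
  during refinement: adjacent-node grids can only overlap within ⅔·gap for
  pathological specs.
* **Incomplete chains.** If no extension is feasible the longest achieved
  chain is returned flagged incomplete rather than raising, so evaluation
  can still count detected electrodes; missing labels are excluded from
  the accuracy mean and counted undetected in the rate.

### The 3D skeletonizer

No installed R package provides 3D topological thinning, so the package
implements it in C++: six directional subiterations per pass, deleting only
*simple points* for (26, 6) connectivity — characterized locally by exactly
one 26-connected foreground component among the 26 neighbours and exactly
one 6-connected background component in the 18-neighbourhood touching a
face neighbour — and never deleting curve endpoints (≤ 1 foreground
neighbour). Deletion is sequential in ascending index with re-testing, so
the skeleton is deterministic, connectivity-preserving, and endpoint
preserving (isolated blobs always retain a candidate). Different published
thinning schemes produce slightly different, equally valid skeletons; the
tests therefore assert structural properties (idempotence, thinness,
point/line/endpoint preservation, centred cores for symmetric solids)
rather than voxel-identity with any particular implementation.

## The phantom generator

`phantomPreset(preset, spec, seed)` builds a logarithmic-spiral trajectory
(radius shrinking geometrically per radian, constant height gain per
radian), places the array's contacts along it so that consecutive
*chord* distances equal the specification gaps exactly (chord stepping —
a rigid array's contact spacing is a straight-line distance, and the chain
search measures Euclidean distances), and renders each contact as an
isotropic Gaussian blob (PSF σ 0.45 mm, peak 2000 so the intensity cost's
/2000 normalization maps to [0, 1]) on a 0.3 mm isotropic grid, plus
optional distractors and seeded Gaussian noise clipped at zero.

Presets:

* `clean` — noise-free-capable gentle spiral (base radius 3 mm, radius
  decay 0.955/rad, pitch 0.55 mm/rad), uniformly bright contacts, no
  distractors: the regime where full recovery is expected.
* `confusion` — base radius 3.2 mm, radius decay 0.9534/rad, pitch
  0.28 mm/rad: for a Flex 24-like array this yields an insertion angle of
  ~471° and an adjacent-turn separation of ~1.95 mm, inside the spacing
  acceptance window (0.95, 3.8) mm — the precondition for apical–basal
  confusion. The five most apical contacts render at half peak (the
  single-contact design) and noise σ is 50 intensity units (2.5% of the
  contact peak), a realistic CBCT noise level.
* `artifacts` — the clean geometry plus a bone slab (peak 300, the upper
  end of cortical bone in CBCT) and a bright wire lead leaving the array
  basally, with noise.

What the phantom does **not** model: beam hardening and streak artifacts,
anisotropic PSFs, partial-volume effects of the electrode carrier, bone
texture, or patient anatomy. Passing tests on phantoms therefore
demonstrate the *algorithmic* properties (correct chain optimization,
threshold semantics, confusion repair, sub-voxel recovery) — not clinical
accuracy figures, which depend on artifact structure absent here.

## Experiment battery

`runBattery(batteryConfig(...))` runs (array × seed × cost-variant) cases:
phantom → threshold (chosen once per array, by coverage sweep, mirroring
per-array threshold individualization) → localization → refinement →
evaluation, and aggregates detection rate, accuracy and error-class
frequencies per array and variant. A paired sign test across seeds
(`compareVariants`) is included as a convenience; it is deliberately not
the clinical study's Friedman analysis.

On the confusion suite the battery reproduces the direction of the
published effect — the advanced variant never trails the baseline's
detection rate on any seed and eliminates double detections entirely —
without claiming the clinical magnitudes, which were measured on 150
patient scans.

## Numerical choices and problem sizes

* Spiral arc length is tabulated by trapezoidal integration of the
  analytic speed on a 20 000-point grid (error ≪ 0.01 mm over two turns);
  contact placement root-solves chord distances to 10⁻⁹ mm.
* The chain search and refinement are exactly reproducible: stable
  tie-breaks, seeded noise, no global RNG state leakage (the renderer
  saves and restores `.Random.seed`).
* Test problem sizes were chosen to exercise every property at desk scale:
  ~45³–70³-voxel phantoms, 20-seed confusion comparisons, a 200-case
  battery, 50 randomized beam-vs-enumeration instances, and exhaustive
  refinement checks for chains up to three nodes (where the chain cost's
  Markov structure lets dynamic programming serve as the exact oracle).

## Known limitations

* **Closely spaced arrays** (gaps ≤ ~1 mm vs the 0.45 mm PSF): individual
  contacts do not resolve — there is no intensity valley between
  neighbouring contacts at any threshold — so the skeleton is a tube
  centerline rather than per-contact blobs, and per-contact recovery is
  intrinsically limited. This mirrors the published behaviour of
  threshold/centerline methods on such arrays (spline-based labeling is
  used clinically instead). The parameter-recovery guarantees in the tests
  are scoped to distantly spaced arrays (spacing ≥ 1.2 mm; the ≤ 0.12 mm
  refinement bound to ≥ 1.3 mm, since at 1.2 mm the *end* contacts' blob
  peaks are displaced ~0.18 mm by the one-sided pull of their single
  neighbour).
* The seed node comes from ground truth (as in the evaluated method);
  automatic seed/ROI detection is out of scope.
* Marker contacts are localized only when explicitly appended
  (`includeMarker`); by default only active contacts form the chain.
* Error-class labels are automated geometric proxies for what was
  originally a manual review; reports should treat them as such.
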