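# CIlocate

Automatic localization of cochlear-implant (CI) electrode contacts in
postoperative cone beam CT (CBCT) volumes.

After cochlear implantation, clinics acquire CBCT scans to verify where the
electrode array sits inside the cochlea, and research studies relate contact
positions to hearing outcomes. Labeling the contacts by hand is slow and
needs anatomical expertise. `CIlocate` implements a graph-based automatic
localization pipeline for arrays with distantly spaced contacts, together
with the pieces needed to study it quantitatively without clinical data: a
registry of commercial array geometries, a synthetic helical phantom
generator with exact ground truth, evaluation metrics, and a scripted
experiment battery.

## Method

Given a volume and the ground-truth/seed coordinates of the array:

1. **ROI** — an axis-aligned region is cropped around the array with a
   3 mm (10 voxel) margin per face.
2. **Candidates** — a cumulative-histogram threshold α₁ (percent of
   brightest ROI voxels retained; per-array values shipped, generalized
   value 2.66%) produces a binary mask, which is thinned to a 3D centerline
   skeleton; skeleton voxels are the candidate electrode locations. α₁ can
   be re-parametrized per array by sweeping 0.01–3% in 0.01% steps and
   choosing the smallest value whose candidates cover every electrode
   within 0.9 mm.
3. **Path search** — starting from the most basal contact (the seed p₁), a
   beam search (width P = 10) grows an L-node chain. A candidate c may
   extend a chain whose last node is pᵢ only if dᵢ/2 < ‖pᵢ − c‖ < 2dᵢ,
   where dᵢ is the inter-electrode gap from the array specification. Each
   extension is scored by

   - intensity cost `C_I = (I_max − I(c)) / 2000`, relaxed by a factor
     α₃ = 0.1 once the chain reaches α₄ = 14 nodes;
   - shape cost `C_S`: a bending penalty (up to 2α₅, α₅ = 1, for a
     reversal; zero for gentle continuation) plus a spacing deviation
     penalty `−α₆·Dst` if `Dst = ‖c − pᵢ‖ − dᵢ < 0` else `α₇·Dst`
     (α₆ = 5.2, α₇ = 2.0);
   - **redetection cost** `C_R` (the advanced variant): infinite whenever c
     lies within α₁₂ = ⅔·dᵢ of *any* node already in the chain, zero
     otherwise.

   `C_R` is the package's central term: on deeply inserted, distantly
   spaced arrays the distance between turns of the cochlear spiral matches
   the inter-electrode spacing, so the plain cost function can walk back
   onto an earlier turn (double detection / apical–basal confusion).
   `C_R` makes such chains unrepresentable.
4. **Refinement** — each chain node is refined on a 7×7×7 grid of 0.12 mm
   offsets, scored by the negative Gaussian blob response (σ = 0.3 mm) plus
   a spacing penalty (weights 50/20 per mm), again by beam search.

Evaluation follows the standard criteria: localization accuracy L_a (mean
same-label Euclidean error), detection rate (% of contacts with error
≤ 0.9 mm, i.e. 3 voxels at 0.3 mm), and automated labels for the three
observed failure modes (artifact detection, double detection, apical–basal
confusion).

## Worked example

A synthetic "confusion" phantom — a Flex 24-like array (12 contacts,
1.9 mm spacing) inserted past 360° so adjacent spiral turns sit ~1.95 mm
apart, with dimmed apical contacts and noise — localized with both cost
variants:

```r
library(CIlocate)

ph <- phantomPreset("confusion", "Flex 24", seed = 1)
base <- localizeElectrodes(ph$volume, ph$gt, ph$spec, thresholdMode = "sweep",
                           params = costParams(costVariant = "baseline"))
adv  <- localizeElectrodes(ph$volume, ph$gt, ph$spec, thresholdMode = "sweep",
                           params = costParams(costVariant = "advanced"))
base$report
#> EvalReport: L_a = 0.256 mm, detection rate = 91.7% (radius 0.9 mm)
#>   conditional accuracy (detected only) = 0.053 mm
#>   error classes: double_detection, ab_confusion_basal_revisit
adv$report
#> EvalReport: L_a = 0.053 mm, detection rate = 100.0% (radius 0.9 mm)
#>   conditional accuracy (detected only) = 0.053 mm
#>   error classes: none
```

The baseline chain tracks the basal contacts correctly, then crosses back
to an earlier turn and re-detects an already-localized contact (the
`double_detection` / `ab_confusion_basal_revisit` labels); the advanced
cost forbids the revisit and recovers all 12 contacts with ~0.05 mm mean
error. `ph$gt` carries the generator's exact contact positions, so every
number above is a true error, not an estimate.

The same pipeline is available from a shell via the thin wrapper
`inst/cli/cilocate` (`simulate`, `localize`, `sweep-threshold`,
`evaluate` subcommands), reading/writing NIfTI or NRRD volumes and
CSV/JSON coordinate lists.

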