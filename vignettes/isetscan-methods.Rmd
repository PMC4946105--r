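---
title: "Methods: semi-automated analysis of filtration-enriched CTCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated analysis of filtration-enriched CTCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isetscan)
```

# The specimen and why it is hard

A 1-mL ISET spot is a membrane with circular 8-µm pores carrying everything
blood filtration retained: 6,000–20,000 leukocyte nuclei, rare tumor cells
whose nuclei can exceed 30 µm, debris and autofluorescence trapped in pores,
all on a surface that is not microscopically flat. Three consequences drive
the whole design:

* **Intensity gating must be background-relative.** The scanner's only
  per-channel intensity control is the exposure time (gain is pinned at its
  8-bit maximum, 255), and absolute counts vary between scans; so every
  intensity rule in this package is expressed against the measured membrane
  background and its spread.
* **Nothing is in focus everywhere.** The focal surface varies by
  micrometres across a spot; acquisition refocuses on DAPI every frame,
  leaving a residual error. For FISH, the thick nucleus itself spreads
  signals over >10 µm of z.
* **Pores lie about cells.** Pore-trapped debris is DAPI-positive;
  background estimation and the simulator both treat pore discs specially.

# The two assays

**Assay 1 (fluorescence + cytomorphology).** `segment_nuclei()` demarcates
DAPI⁺ nuclei; `measure_candidates()` produces the gallery characteristics
(`Avg_Int`, `Avg_Int_Bg`, `Sec/Ter/Quat_Avg_Int`, area);
`select_cd45_negative()` applies the three single-cell criteria (DAPI
intensity, CD45 intensity, area > 55 µm²) and the fourth, cluster criterion
(area > 150 µm² = three pore-equivalents, CD45 ignored);
`classify_candidates()` assigns the eight categories;
`build_gallery()` emits the reviewable records. `register_rounds()` aligns
the brightfield round via the snick fiducial, and `call_epithelial_ctc()` /
`call_markerneg_ctc()` apply the five- and three-criterion CTC definitions.

**Assay 2 (fluorescence + FA-FISH).** `render_zstack()` / `detect_spots()`
find 3D spots per cell, `multi_exposure_fuse()` picks the best of up to
three exposure times per channel, `call_break_apart()` scores
rearranged / native / native-copy-gain, and `spot_count_table()` /
`detection_rate()` compute the per-setting calibration statistic.

# Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| pixel size | 0.5 (spot), 0.2 (FISH) | µm/px | not dictated by the assay; 0.5 resolves leukocyte nuclei, 0.2 approximates a ×63 FISH capture |
| DAPI gate | bg + 5·sd | counts | nuclei must stand clearly off the membrane |
| CD45 gate | bg + 3·sd | counts | "CD45-negative" = indistinguishable from background; no absolute cutoff exists because calibration is exposure-based |
| area gates | 55 / 150 | µm² | one pore ≈ 50 µm²; 55 excludes pore-sized objects, 150 = three pore-equivalents for clusters; both strictly greater-than |
| marker positivity | bg + 3·sd | counts | same background-relative logic as CD45 |
| two-pore split | 16 | µm | marker-negative size split; strictly greater-than in the category rule, inclusive (≥) in the marker-negative CTC rule — the two rules state their boundaries differently and both are honored verbatim |
| epithelial-CTC size | > 12 | µm | 1.5 pore diameters, strict |
| n_stacks | 30 (max) | – | scanner ceiling; calibration optimum |
| step | 0.6 | µm | interior optimum of the step sweep |
| exposures | ≤3 per channel, 5–100 | ms | the multi-exposure protocol; 3 channels × 3 exposures gives the theoretical 27 settings (9 with red+green only); both cardinalities are accepted since the third varying channel is not pinned down |
| irregularity | 1 − solidity, min 0.05 | – | "nuclear irregularity" named but not quantified; solidity is the standard operationalization |
| N/C ratio | min 2.0 | – | "high nuclear-to-cytoplasmic ratio" unquantified; 2 is a conservative cytology convention |
| d_fuse / d_split | 1 / 2 signal diameters | µm | standard break-apart scoring convention; separations in between are ambiguous, never split |

# Segmentation choices

The scanner's own algorithm is proprietary; ours mirrors its calibration
semantics. A global offset (automatic: background + 0.15 of the bright
range, never below 4 noise-sd) demarcates generous foreground; a
distance-transform watershed always splits touching nuclei; each nucleus is
then re-demarcated at its own half-maximum above background. The half-max
reference is an upper quantile (p90) of the object rather than its maximum,
so a small bright overlap — pore debris under a cell, a brighter neighbour's
rim — cannot drag the threshold above the object's own plateau and erase
it. On noiseless synthetic nuclei this pipeline recovers counts exactly and
areas within ±7 %. The cluster pass reuses the same per-nucleus masks and
merges touching ones, so cluster areas are sums of honestly-sized nuclei.
One global threshold *without* the per-object refinement mismeasures areas
by up to +25 % across a realistic brightness range — that failure mode is
why the refinement exists.

Candidates selected by the cluster rule are resolved into constituents by
re-segmentation within the merged mask; a "cluster" resolving to a single
nucleus falls through to single-cell classification (it is typically a
large CTC whose CD45 measurement was contaminated by an adjacent
leukocyte — exactly the case the CD45-blind cluster rule exists for).
Clusters of exactly two CD45⁻ cells sit in a definitional gap between
single cells and the three-cell microcluster; they are reported as
`uncategorized-pair`, never silently binned.

# FISH detection choices

Per plane, spots are found as local-maximum clusters of a
difference-of-Gaussians response (σ = 0.4 µm, ratio 1.6), with footprint
statistics taken at the response half-maximum so they do not inflate with
exposure. Detections in consecutive planes within 0.6 µm laterally link
into one 3D spot. A detection whose single maximum has a wide (> 2.2 µm) or
elongated (axis ratio > 1.6) footprint is flagged `merged` — a signal that
may hide two — and excluded from the *countable* tally. Multi-exposure
fusion maximizes countable spots and breaks ties toward the lowest exposure
(least bloom); this single objective subsumes the "don't trust thick
signals" rule, because an exposure that fuses a resolvable pair counts one
where another counts two. A stack saturated over ≥ 60 % of its pixels is
non-interpretable (the tables' "n.i."), as is a cell with no signal in
either channel.

The assay itself does not define a spot-counting operator across planes;
the linking rule above is this package's design decision, stated as such.

# What the simulator states (and what it does not)

The generator's defaults are the stated world: 6,000–20,000 leukocytes per
spot with nuclear areas below the 55-µm² gate (mean 42 µm²), rare CTCs of
60–750 µm² with an epithelial/mesenchymal phenotype mix (40/30/20/10 % for
E⁺/M⁻, E⁺/M⁺, E⁻/M⁺, E⁻/M⁻), debris only inside pores, touching clusters
of 4–6 nuclei with ~25 % CD45⁻ members, a smooth focal surface with 10-µm
peak-to-peak and 0.5-µm refocus residual, FISH spots as 3D Gaussians
(lateral σ 0.4 µm, axial σ 0.8 µm) uniform through a 14-µm nucleus.
Detector: linear 8-bit response, dark level 8 counts, read noise 1.5
counts, approximate shot noise.

Deliberate idealizations, hence what a green test does *not* establish:

* A full spot is ~28 mm²; the simulator packs the stated population into a
  ~1.5-mm field (denser than reality). Absolute densities are not
  validated, only counts, rules and rates.
* Isolated single cells never overlap in projection; projected overlap is
  modelled only by the deliberate cluster groups, and one pore seats one
  cell. Real filters will occasionally stack a cell on debris-filled pores
  in ways the watershed cannot untangle; the CD45-blind cluster gate is the
  systemic mitigation, not a guarantee.
* An optical section captures a spot only within ±0.3 µm (strictly) of the
  plane. This hard support is what creates the measured trade-off —
  a 0.5-µm step's comb is too short for a 17-µm spot range while 0.7–0.8-µm
  steps leave inter-plane dead zones, making 0.6 µm the interior optimum —
  but it is a model statement, not measured optics.
* Saturation blooming is modelled by clipping only; real glare spreads
  light laterally. The merged-pair flag therefore fires on footprint
  geometry, not on a physical bloom model, and genuinely sub-resolution
  pairs (≲ 0.4 µm) are one spot to any detector and are simply counted once.

# Numerical conventions

Lengths in µm, areas in µm², exposures in ms everywhere; pixels never cross
module boundaries. Centroids sit at pixel centres; gallery crops are
half-open windows. Equivalent-circle diameter `2·sqrt(area/π)` is the only
area→length conversion. Detection rates round to the nearest integer
percent (base-R `round`), matching the calibration tables' precision; a
row's maximum ignores n.i. entries and ties count toward every tying
setting; fully non-interpretable rows are dropped with a warning.
Registration resamples fiducial outlines by arc length and fits by
SVD (Kabsch) over both traversal directions, refusing degenerate
(collinear) or ambiguous (near-symmetric) fiducials. All randomness flows
from explicit integer seeds; identical seeds give bit-identical images,
tables and calls.

# Known limitations

* Cytoplasm segmentation from brightfield is a single dark-threshold flood
  from the nucleus; stain-specific colour deconvolution (Mayer-Hemalun vs
  Diff-Quik) is treated as metadata only.
* "Nucleus intact" is operationalized as mask contiguity plus no crop-border
  truncation — a stated heuristic for an expert judgement.
* The TIFF codec covers exactly the subset the package writes (8-bit
  grayscale, uncompressed, little-endian, one strip per page); vendor
  pyramid/WSI formats are out of scope.
* Review (`set_review_status()`) is a data operation with a CLI; there is no
  GUI, as interactive review belongs to the scanner console.
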