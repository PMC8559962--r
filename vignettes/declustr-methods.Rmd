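---
title: "Models and methods behind declustr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind declustr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declustr)
```

## The biological system and what the pipeline measures

During *Drosophila* spermatocyte maturation, pericentromeric
heterochromatin of all chromosomes is initially coalesced into one or few
chromocenter clusters. As chromosome territories form (stages S2b–S4),
these clusters resolve stepwise: live imaging of a centromeric marker
(Cenp-A/Cid fused to a fluorescent protein) shows a progression from one
merged dot up to eight dots, one per homolog's unresolved sister-centromere
pair. The order of the splitting events, the relative dot intensities, the
durations of the *k*-dot stages, dot motility, the radial positions of
satellite loci, and the pole ratios of centromeres at anaphase I are the
quantitative readouts this package computes from two-channel 4D movies —
one diffuse nuclear channel (a His2Av-type chromatin signal) and one
punctate marker channel.

Because no raw movies are publicly deposited for this system, the package
pairs every estimator with a synthetic-movie generator that emits complete
ground truth. All parameter-recovery claims in the test suite are claims
about these simulations, not about real microscope data; the section on
the generator below states exactly which features of real data it does and
does not emulate.

## The karyotype model

The male *D. melanogaster* karyotype (2n = 8: chr2, chr3, chr4, X, Y) is
the source of every analytic expectation. Each chromatid contributes one
centromere unit of relative intensity 1.0; the Y centromere carries weight
2.0, reflecting its consistently twofold brighter Cid signal. Whether the
twofold factor is an exact biological constant or an empirical average is
not established; it is therefore a parameter
(`karyotype_male(y_centromere_weight = )`) with default 2.0.

From this model derive, rather than being hard-coded:

* cluster intensities — e.g. in G2 a large-autosome bivalent cluster holds
  2 homologs × 2 chromatids × 1.0 = 4 units, the XY bivalent cluster
  2 + 4 = 6 units, hence the 1.5-fold expected ratio at a naive
  one-cluster-per-bivalent four-dot stage;
* dot counts for any partition of centromere units (1, 3, 8 for the named
  stages), with partition validation;
* entity counts at meiosis I onset (4 intact bivalents; 7 when the three
  autosomal conjunctions are lost; 8 univalents);
* telomere dot counts (16 in G1, 32 in G2, fewer under clustering);
* the random-segregation null: for *n* independent univalents the
  unordered pole ratio a:b has probability `choose(n, a) / 2^n`, doubled
  when a ≠ b. Analytic mode enumerates the 2^n assignment space exactly
  (guarded at n ≤ 30); Monte-Carlo mode draws seeded cohorts. For n = 8
  the 5:3 class has probability 112/256 = 43.75%.

```{r karyotype}
k <- karyotype_male("G2")
p4 <- canonical_partition(k, "four_dot_bivalent")
cluster_intensity_ratio(p4$XY, p4$Aa, k)
random_segregation_null(8)
```

## The synthetic-movie generator

`simulate_movie()` renders a single nucleus per movie: channel 1 is a
sphere with a plateau interior and a sigmoidal edge; channel 2 renders each
dot as a voxel-integrated anisotropic Gaussian whose total integral equals
the dot's true intensity (window ±5σ, truncation < 0.01%). Voxel values
are integer photon counts; Poisson shot noise, Gaussian read noise and
exponential per-frame bleaching are applied from a dedicated RNG
substream, so toggling noise does not perturb the motion sample.

Key modelling choices, all deliberate and fixed:

* **Acquisition presets.** `"fine"`: 46 z-planes at 500 nm, 45 s frame
  interval; `"coarse"`: 29 planes at 800 nm, 10 min intervals — the two
  acquisition regimes used for this system. Tests use smaller grids
  (typically 64×64×16 voxels, 10–40 frames) so the suite completes in
  minutes on one CPU; the geometry per voxel is unchanged.
* **Motion.** Anchored confined diffusion: per frame an isotropic Gaussian
  step with expected length `mean_speed × frame_interval`, projected back
  onto a confinement sphere around the dot's anchor. This reproduces the
  ~0.03 µm/s speed regime without claiming a mechanistic model. Transient
  faster phases are available through an optional two-state speed switch;
  its parameters are free choices, not literature-derived. After a split,
  the children's anchors separate by `child_anchor_separation` (default
  1.6 µm), emulating partitioning into distinct territories.
* **Nuclear edge.** The sigmoid scale is 0.12 µm (10–90% width ≈ 0.5 µm),
  i.e. a PSF-limited boundary; soft-focus edges much wider than the PSF
  would make small nuclei unsizeable by any global threshold and do not
  correspond to chromatin-channel images of this system.
* **Event grammar.** `simulate_decluster_schedule()` emits the canonical
  split order (Aa release, Ab release, Aa → Aa1+Aa2, Ab → Ab1+Ab2, Y
  release, X/chr4 separation, final chr4 split) or one of the two variants
  in which the first release from the most intense XY4 cluster happens
  before the Ab split (four-dot variant) or before the Aa split (three-dot
  variant). True partition fractions come from the karyotype model (e.g.
  0.4 for the Y release from the 10-unit XY4 cluster in G2).
* **Condensin II mutant mode** suppresses splits and renders stretch
  episodes: the dot's mass is laid out along a line segment with 30% at
  each endpoint and 40% distributed along the bridge, total intensity
  conserved; elongation follows a triangular profile up to
  `max_separation` (default 2 µm, the typical observed elongation;
  occasional episodes up to 4.8 µm are configurable).
* **Anaphase mode** moves entities to two poles: intact bivalents send
  their homologs to opposite poles deterministically; univalents draw
  independent fair coins under the null.

What the generator does **not** emulate: optical sectioning physics and
depth-dependent aberrations, nucleoli and Y-loops, multi-nucleus cysts,
cell growth during the movie, autofluorescent background structure, and
stage drift other than rigid translation. Estimator performance on real
data can therefore be worse than the recovery numbers in the test suite,
particularly for crowded dot configurations and low-contrast nuclei.

## Spot detection

Detection is a band-pass (Laplacian-of-Gaussian) blob detector
parameterized by the expected spot diameter, mirroring the
diameter-parameterized detector used in the original analyses (500 nm for
centromere dots, 400 nm for telomeres, 1 µm for satellite dots). The
scale relation is σ = diameter / (2√2) per axis, with an axial diameter
defaulting to twice the lateral one. Background subtraction removes a
coarse Gaussian blur (4σ) before filtering. Local maxima
(26-connectivity, plateau ties broken toward the lowest (z, y, x) index)
are refined by per-axis quadratic interpolation, clamped to ±0.5 voxel.

The default quality threshold is auto-calibrated per frame as
mean + k·SD of the band-pass response over background voxels (below the
99.5th percentile). Because the smoothed response is spatially
correlated, the nominal Gaussian tail underestimates the maxima rate; on
noise-only simulations k = 5 still yielded ≈3 false maxima per frame,
while k = 7 achieves the intended < 1 false positive per frame. The
default is therefore k = 7. The detector's `quality` score is the
band-pass response at the maximum; it is not claimed to match any
commercial package's proprietary score.

Integrated intensity sums voxels in an **ellipsoid** centred on the
subpixel position (lateral semi-axis = diameter, axial semi-axis = axial
diameter), minus the median of a surrounding shell times the voxel count.
A sphere with radius of order the lateral diameter aliases badly against
500–800 nm z-sampling: identical dots could differ by tens of percent
depending on their subvoxel z-position, which would defeat the twofold
intensity discriminability the classification relies on. When several
detections' regions overlap, contested voxels are assigned to the nearest
spot, so intensity partitions rather than double-counts across fresh
splits.

## Nuclear segmentation and geometry

The diffuse channel is Gaussian-smoothed (default σ = 0.4 µm), thresholded
automatically, and the largest 6-connected component is kept with interior
holes filled. The automatic threshold starts from Otsu's method and is
refined by a robust isodata iteration on class *medians*: on these images
the background mode dominates the histogram and the edge ramp dilutes the
foreground mean, so plain Otsu (and mean-based isodata) settles well below
the half-height of the soft-edged nucleus and inflates the equivalent
diameter; the median-based fixed point sits at the half-height and
recovers rendered sphere diameters to within 3% across radii 3–7 µm under
both acquisition geometries. The threshold actually used is logged in the
returned model.

Distance-to-periphery uses an exact Euclidean distance transform on the
anisotropic voxel grid (separable lower-envelope recursion with per-axis
spacing, implemented in the package because no installed package provides
a 3D anisotropic EDT); a brute-force nearest-boundary-voxel search serves
as its independent oracle in the tests. Points outside the mask return a
negative distance. The nuclear diameter doubles as a developmental-stage
proxy: d < 9 µm → S1/S2, 9–12 µm → S3/S4, larger → later stages; exactly
9 µm is assigned to the upper bin, since the source staging rule is
ambiguous at the boundary. Radial position is reported both as a raw
distance and as the normalized fraction (radius − distance)/radius — 0 at
the center, 1 at the periphery — because published "radial position" plots
do not state a normalization.

## Tracking and event calling

Linking is frame-to-frame optimal bipartite assignment
(`clue::solve_LSAP`) on Euclidean costs between predicted positions and
candidates, gated at `max_step` per elapsed frame, with birth/death costs
equal to the gate. The prediction is
`position + motion_memory × previous displacement`, a first-order
autoregressive (constant-velocity) prior with `motion_memory = 0.8` by
default; equivalence with the commercial autoregressive tracker is claimed
only at the level of ground-truth recovery. Candidates are sorted
deterministically within each frame, making linking invariant to input row
order. Gaps up to `max_gap` frames are bridged. Manual curation is
supported only as a deterministic batch-edits table (delete / relabel /
cut / join).

Drift correction subtracts the per-frame displacement of the segmented
nucleus centroid relative to frame 0; missing centroids are interpolated
with a warning. Speeds are `|Δposition| / Δt` over consecutive observed
frames, pooled over dots, time points and cells for summaries.

A split is called when a new track begins within `association_radius` of
an existing track — measured against both the candidate parent's last
pre-event and first post-event positions, since fresh split products
scatter around the precursor — whose intensity drops commensurately with
the new track's intensity (within a factor of 3). When several spatial
candidates pass the intensity test the event is flagged ambiguous rather
than assigned; fusions are the time-reverse. The partition fraction is
the continuing child's share of the summed intensities at the first
post-split frame.

## Per-cell metrics

Dot-count stage intervals are maximal constant-count runs after a
debounce: count dips shorter than 2 frames flanked by equal counts — the
signature of a transient fusion — are bridged; the debounce length is
configurable and recorded, since the original analyses do not state how
transient fusions were handled. Runs touching the observation window are
flagged censored ("minimal durations"); a single run spanning the whole
window is flagged `both_censored`. Durations tile the window exactly.

Pair separations encode the reported zero convention: 0 means exactly one
of the two signals was detected (a merged spot); frames with both signals
absent are missing values and are never imputed as zeros. Stretch episodes
are maximal runs with separation ≥ `min_separation` (default 1 µm, the
two-spot detection scale at a 1 µm estimated diameter) lasting
≥ `min_duration` frames (default 3); an episode ends in `definitive_split`
if the separation never returns to zero before the observation ends.
Group comparisons use the classical pooled-variance two-tailed t test
(Welch by flag) with stars at 0.05/0.01/0.001.

## Classification

The de-clustering program classifier takes a lineage rooted at the
three-dot stage {Aa, Ab, XY4}. The most intense initial track is XY4.
Splits of the other two roots must partition ≈1:1 (ratio within
[0.67, 1.5]); the released product of the first XY4-lineage split must be
≈2× an Aa1-class dot (within [1.6, 2.4]) — brackets chosen around the
reliably detectable twofold differences. The timing of the first XY4
release relative to the two autosomal splits selects canonical /
variant_four_dot / variant_three_dot; violations yield `other`, never a
guess. Intensities entering these rules are medians over a short window
(3 frames) after the event: the median rejects the transient
cross-contamination of freshly separated dots, and the short window guards
against intensity steps from later, possibly uncalled, splits. Splits of
tracks whose own origin event was not called are dropped from program
inference (they are late-stage descendants) and noted in the call.

Segregation calls project final-frame unit positions on their principal
axis and run deterministic 1D 2-means initialized at the extremes; explicit
pole anchors override. Units equidistant within a localization tolerance
are excluded with a warning; ratios are unordered. Goodness of fit against
the null combines the Pearson chi-square statistic with a seeded
Monte-Carlo exact multinomial p value (probability of a table at most as
likely as the observed one).

## Numerical and reproducibility choices

* All randomness flows from one master seed through named substreams
  (placement, motion, drift, noise, anaphase), so re-simulation is
  bit-identical and components can be toggled independently.
* Movies are integer photon counts ≤ 65535 and are written as 16-bit
  OME-TIFF (XYZCT plane order, LZW) with the calibration in an OME-XML
  sidecar; reading de-interleaves any supported DimensionOrder and
  round-trips bit-identically. Positions are micrometers with voxel
  centers at (index + 0.5) × spacing, voxel indices 0-based externally.
* CSV outputs have fixed column order, unit-bearing comment headers and a
  configuration hash (which excludes the machine-local output path), so
  identical configurations reproduce byte-identical tables.
* Problem sizes in the tests — movies of 48–96 px laterally, 12–24
  z-planes, 10–40 frames; 200 Monte-Carlo cohorts of 44 cells; 10^5-cell
  null samples — were chosen so each module exercises its full code path
  at desk scale; they are the package's own test conditions, not
  recommendations for real data.

## Known limitations

* The detector merges dots closer than roughly the axial resolution;
  stretch episodes whose axis is mostly axial are detected only near
  maximal elongation (the ground-truth-based episode count is exact; the
  detector-based count is conservative).
* Freshly split dots can exchange identity for a frame or two before
  their territories separate; program classification absorbs this through
  the median-window rule, but per-frame identity is not guaranteed at
  split instants.
* The intensity scale for the ≈2× release test comes from the observed
  Aa1/Aa2 products; movies in which no autosomal split is observed cannot
  check the bracket and rely on event timing alone.
* Stage-duration estimates are quantized to the frame interval; censored
  intervals are reported as lower bounds and no survival-analysis
  treatment is attempted.
* The pipeline assumes one nucleus per movie; fields with several nuclei
  keep only the largest segmented component.
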