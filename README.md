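# declustr

Quantitative 4D image analysis of **centromere de-clustering and
chromosome territory formation in *Drosophila* spermatocytes**, built as a
tested, reusable R pipeline with a ground-truthed synthetic-movie
generator.

During spermatocyte maturation the merged pericentromeric chromocenter
resolves stepwise into up to eight centromere dots (one per homolog's
sister-centromere pair), following a characteristic program of splitting
events. Researchers studying this system score, from two-channel 4D
fluorescence movies (a diffuse nuclear channel and a punctate marker
channel): dot counts and *k*-dot stage durations, dot intensities and
their ratios, dot motility, radial positions, satellite-locus separations
and stretch episodes, and centromere pole ratios at anaphase I. This
package implements that entire workflow:

* **Karyotype model** (`karyotype_male()`): the male 2n = 8 karyotype with
  per-chromatid centromere units (chrY twofold), from which all analytic
  expectations derive — cluster intensities, dot/entity/telomere counts,
  and the random-segregation null. For *n* univalents segregating
  independently, the unordered pole ratio a:b (a ≥ b, a + b = n) has
  probability

  P(a:b) = C(n, a) / 2ⁿ · (2 − [a = b]),

  so for n = 8: P(4:4) = 70/256, P(5:3) = 112/256 = 43.75%, …
* **Synthetic movies** (`simulate_movie()`, `simulate_anaphase()`):
  voxel-integrated Gaussian dots with karyotype-derived intensities inside
  a soft-edged nucleus; anchored confined diffusion, whole-nucleus drift,
  Poisson + Gaussian noise, bleaching; wild-type split schedules,
  condensin-II-mutant stretch episodes, and anaphase segregation — all
  with complete ground truth.
* **Spot detection** (`detect_spots()`): diameter-parameterized 3D
  Laplacian-of-Gaussian detector with subpixel localization and
  background-corrected integrated intensities.
* **Nuclear segmentation** (`segment_nucleus()`,
  `distance_to_periphery()`, `stage_from_diameter()`): automatic
  thresholding, equivalent diameter (a developmental-stage proxy), and an
  exact anisotropic Euclidean distance transform.
* **Tracking** (`link_tracks()`, `correct_drift()`,
  `detect_splits_fusions()`): optimal bipartite linking under a
  constant-velocity prior, drift correction from the nucleus centroid,
  velocities, and split/fusion calls with intensity partitions.
* **Metrics** (`dot_stage_intervals()`, `pair_separation()`,
  `stretch_episodes()`, `radial_summary()`, `compare_groups()`).
* **Classification** (`classify_decluster_program()`,
  `classify_segregation()`, `null_comparison()`): canonical vs variant
  de-clustering programs, anaphase pole ratios, and goodness of fit
  against the random-segregation null.
* **I/O and pipeline** (`read_movie()`/`write_movie()` for OME-TIFF,
  `run_pipeline()`, plus a thin `declustr` command-line wrapper in
  `exec/`).

## Worked example

Analytic expectations from the karyotype model:

```r
library(declustr)
k <- karyotype_male("G2")
p4 <- canonical_partition(k, "four_dot_bivalent")
cluster_intensity_ratio(p4$XY, p4$Aa, k)
#> [1] 1.5
random_segregation_null(8)
#>   class a b probability
#> 1   4:4 4 4   0.2734375
#> 2   5:3 5 3   0.4375000
#> 3   6:2 6 2   0.2187500
#> 4   7:1 7 1   0.0625000
#> 5   8:0 8 0   0.0078125
```

The 1.5 is the expected intensity ratio of the sex-chromosome bivalent's
centromere cluster (X + twofold Y, 6 units in G2) to a large-autosome
bivalent cluster (4 units) — the naive expectation against which observed
four-dot-stage intensities are compared. The table is the exact null for
eight univalents segregating at random.

A full simulated-movie run through the pipeline (6 h of a canonical
de-clustering program at 10-min sampling, 64×64×16 voxels):

```r
d <- tempfile("demo")
cfg <- run_config(out_dir = d, seed = 42,
  simulate = list(
    program = "canonical",
    acquisition = list(preset = "custom", n_frames = 36L, ny = 64L,
                       nx = 64L, z_planes = 16L, frame_interval = 600),
    motion = list(mean_speed = 0.0003, confinement_radius = 0.3),
    nucleus_radius = 3.2),
  track = list(max_step = 0.9))
run_pipeline(cfg)
read_table_csv(file.path(d, "stage_intervals.csv"))
#>   count start_frame end_frame duration      censoring
#> 1     1           0         5     3600  left_censored
#> 2     2           6        11     3600       complete
#> 3     3          12        26     9000       complete
#> 4     4          27        33     4200       complete
#> 5     3          34        34      600       complete
#> 6     5          35        35      600 right_censored
```

Each row is a maximal run of constant dot count: the four-dot stage here
lasted 4200 s (7 frames × 600 s); the first and last runs touch the
observation window and are therefore censored — their durations are lower
bounds. The one-frame dip to 3 at frame 34 is a detection dropout at the
moment of the Ab split. The classify stage writes the program call:

```r
cat(readLines(file.path(d, "classification.json")), sep = "\n")
#> {
#>   "program": "canonical",
#>   "identities": {
#>     "3": "XY4",
#>     "1": "Aa1",
#>     "4": "Aa2",
#>     "2": "Ab1",
#>     "5": "Ab2"
#>   },
#>   ...
#> }
```

The most intense track is identified as the XY4 cluster and the two
approximate-1:1 autosomal splits yield the Aa1/Aa2 and Ab1/Ab2 sister-pair
dots, matching the simulated schedule.

See `vignette("declustr-methods")` for the models, parameter defaults and
design decisions.

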