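# isletmorph

Quantitative image analysis of pancreatic islet morphogenesis in zebrafish
larvae.

During secondary islet formation, endocrine progenitors delaminate from the
pancreatic duct, extend fine actin-rich filopodia, migrate, and coalesce
into compact islets. `isletmorph` implements the measurements needed to
quantify this process from volumetric fluorescence microscopy, for
developmental biologists comparing treatment cohorts (e.g. PI3K or GPCR
inhibition) against controls:

- **Secondary islet segmentation** — automated delineation of the exocrine
  pancreas from the red (mCherry) channel after a single manual head/tail
  boundary, then 3D segmentation of endocrine (GFP) islet objects with
  smoothing (σ = 0.5 µm), local background subtraction, thresholding,
  26-connected labeling and a minimum object size of 100 µm³; volumes are
  reported in µm³ from physical voxel sizes, with batch CSV tables and QC
  montages.
- **Clustering statistic** — cells are tracked by global minimum-cost
  (Hungarian) frame-to-frame assignment and coalescence is quantified as
  the volume of the convex 3D polytope enclosing the tracked cell centers,

  V(t) = vol conv{ x₁(t), …, xₙ(t) } (µm³),

  which decreases as cells come into closer proximity.
- **Single-cell morphometry** — per-frame area A, perimeter P, circularity
  4πA/P² (capped at 1) and solidity A/A_hull (1 for a round cell,
  decreasing with protrusion formation), plus a membrane-motility analysis
  that opens the mask with a 2 µm disk to separate the cell body from
  fine protrusions.
- **Filopodia kinetics** — backbone tracing of thin (< 2 µm) protrusions by
  skeletonization, instantaneous extension/retraction rates ΔL/Δt from
  consecutive frames, maximal lengths, and cohort length distributions.
- **Statistics** — unpaired t-tests computable directly from printed
  mean ± sd summaries (pooled and Welch), Mann–Whitney, Kruskal–Wallis with
  Dunn's post-hoc, one-way ANOVA with Dunnett's post-test, and figure-style
  box-whisker panels.
- **Synthetic scenes** — a seeded generator for ground-truthed two-channel
  stacks (ellipsoidal pancreas + spherical endocrine cells, Gaussian PSF,
  Poisson + Gaussian noise), attraction-plus-noise motion, protrusion-bearing
  cell masks and piecewise-linear filopodium length programs, so the whole
  pipeline is testable without microscope data.

Conventions: physical units are µm everywhere; arrays are ordered
(z, y, x); voxel centers sit at `(index − 0.5) · voxel_size`; anisotropic
stacks (z-step > xy pixel) are handled by doing all computations in
physical space.

## Worked example

Simulate five coalescing cells imaged every 18 min and quantify clustering:

```r
library(isletmorph)

set.seed(1)
x0 <- matrix(runif(15, 5, 30), 5, 3)           # initial centers, um
tr <- simulate_motion(motion_spec(n_frames = 6, seed = 1), x0)
cs <- clustering_series(tracks_from_trajectories(tr))
cs[, c("frame", "time_min", "n_points", "hull_volume_um3", "degenerate")]
#>   frame time_min n_points hull_volume_um3 degenerate
#> 1     1        0        5           515.6      FALSE
#> 2     2       18        5           498.5      FALSE
#> 3     3       36        5           368.5      FALSE
#> 4     4       54        5           272.1      FALSE
#> 5     5       72        5           228.8      FALSE
#> 6     6       90        5           230.5      FALSE
```

The hull volume falls from ~516 µm³ to ~230 µm³ over 90 min: the attraction
term dominates the diffusion noise and the group contracts. Frames with
fewer than 4 cells (or coplanar centers) would be flagged `degenerate` and
reported with 2D-area and maximum-extent fallbacks instead.

Group comparison straight from published-style summaries (beta-cell counts,
control 17 ± 4, n = 16, versus treated 5 ± 2, n = 14):

```r
t_test_from_summary(group_summary("CTL", 16, 17, 4),
                    group_summary("LY", 14, 5, 2))
#>         test statistic df   p_value sidedness comparison
#> 1 t (pooled)     10.15 28 6.863e-11 two.sided  CTL vs LY
```

p ≪ 0.0001: the treated group has significantly fewer beta cells.

A command-line wrapper for batch segmentation lives in
`inst/scripts/isletmorph`:

```sh
isletmorph segment --red red.tif --green green.tif --roi roi.json --min-volume 100
isletmorph stats --summary summaries.csv
```

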