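---
title: "Methods: quantifying islet morphogenesis with isletmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying islet morphogenesis with isletmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmorph)
```

# The measurement problem

Secondary islets in the zebrafish pancreas assemble when endocrine
progenitors leave the duct, probe their surroundings with thin actin-rich
filopodia, and coalesce into compact clusters. Comparing this process
between treatment cohorts requires turning 4D microscopy into a handful of
per-sample numbers: islet volumes, a scalar "how clustered are these cells"
statistic over time, per-frame cell-shape descriptors, and filopodium
kinetics. This vignette describes the models and numerical choices behind
each measurement, what the synthetic-data generator does and does not
emulate, and the known limitations.

Units and coordinates are fixed once, package-wide: physical µm, array
axis order (z, y, x), voxel centers at `(index − 0.5) · voxel_size`.
Confocal stacks are usually anisotropic (z-step of ~1 µm against xy pixels
of ~0.2–0.5 µm), so every kernel width, structuring element and volume is
specified in µm and converted per axis; nothing is computed in raw voxel
units.

# Islet segmentation

The automated pipeline needs one manual input per sample: a polyline in the
xy plane separating the pancreatic head (which contains the large principal
islet) from the tail, with a sign convention naming the tail side. After
that:

1. **Pancreas delineation** (red/exocrine channel): Gaussian smoothing
   (σ = 0.5 µm default — the standard smoothing used for islet surface
   extraction), local background subtraction, thresholding, restriction to
   the tail half-plane, then the largest 26-connected 3D component. A stack
   with no suprathreshold signal yields an *empty mask plus a flag*, not an
   error, so batch runs continue.
2. **Islet segmentation** (green/endocrine channel): the same chain inside
   the pancreas mask, then 3D connected components and a minimum object
   size of 100 µm³ (the conventional cutoff for secondary-islet
   quantitation; configurable). Volumes are voxel counts times the voxel
   volume.

Choices a practitioner should know:

- **Threshold.** Otsu's method on the in-mask intensity histogram by
  default, with a fixed-value override for the "same settings applied to
  every image of an experiment" workflow. Published pipelines rarely state
  their threshold; exposing both modes makes the choice explicit.
- **Background subtraction** is a grayscale box top-hat (separable running
  min then max), radius 10 µm by default — larger than an islet cell so
  cells survive, smaller than tissue-scale background. The radius is a free
  parameter; no standard value exists.
- **Connectivity** is 26-neighborhood in 3D (8 in 2D). This is stated
  because it changes object counts for touching-corner voxel pairs.
- **Anisotropy warning.** If the z-step exceeds the scale of the objects,
  the pipeline warns but proceeds; no axial interpolation is attempted.
- **Spot counting** (endocrine nuclei) is Laplacian-of-Gaussian detection
  at the blob-matched scale σ = d/(2√2) for the configured spot diameter
  (default 5 µm, the conventional nucleus spot size), with local maxima
  separated by at least d/2 and a center-intensity filter. This reproduces
  "spot diameter" semantics without any proprietary implementation.

# The clustering statistic

Clustering is quantified as the volume of the convex 3D polytope enclosing
the tracked cell centers, evaluated per frame. The hull is computed by
incremental insertion (quickhull-style) with outward-oriented facets and a
divergence-theorem volume; the implementation is validated in the test
suite against brute-force supporting-plane enumeration (small n) and
Monte-Carlo membership integration (50-point clouds), and against closed
forms (unit cube, regular tetrahedron) to 1e-9 relative.

Fewer than 4 cells, or coplanar/collinear centers, have no 3D volume. What
to plot then is genuinely open; the package reports volume 0 with an
explicit `degenerate` flag **plus** the 2D hull area of the best-fit-plane
projection and the maximum pairwise distance, so low-n series remain
informative rather than silently zero.

Tracking is frame-to-frame global minimum-cost assignment (Hungarian
algorithm on Euclidean distance) with links longer than `max_displacement`
(default 10 µm per frame) forbidden; unmatched detections open new tracks.
Gaps are never interpolated — the statistic is computed over the cells
observed in each frame and the frame is flagged as incomplete — because
inventing positions would bias the hull volume downward or upward
unpredictably. Frame times come from metadata and need not be uniform
(intervals from ~18 min to hours are typical for clustering series;
12–20 s for filopodia).

With zero diffusion the motion generator contracts every center toward the
centroid by a factor (1 − k·Δt) per step, so the hull series obeys
V(t+1)/V(t) = (1 − k·Δt)³ exactly; the pipeline reproduces this to
~1e-12 relative, which is the sharpest end-to-end correctness check of
tracking + hull evaluation.

# Cell morphometry

Per frame and cell: area A (pixel count × pixel area), perimeter P,
circularity 4πA/P² capped at 1 (the ImageJ convention, chosen because
manual analyses in this field are ImageJ-based), and solidity A/A_hull.

The **perimeter estimator** matters: raw pixel-edge ("staircase") lengths
overestimate smooth boundaries by up to ~27%, biasing circularity low. The
package traces the 0.5-level marching-squares contour — which runs along
the physical mask outline — and applies a circular moving average (window
5 vertices) before summing segment lengths. The window is a compromise
validated against closed forms in the tests: a rasterized disk (r = 25 px)
measures circularity ≈ 0.998 and a filled square ≈ 0.798 against the exact
π/4 ≈ 0.785. Axis-aligned straight edges are nearly length-neutral under
the smoothing, while staircase arcs contract toward their true length;
corner rounding costs a fixed few pixels per corner, so large fixtures are
used where closed forms are asserted.

**Convex hull area** is measured on the same pixel grid as the mask area
(pixels whose centers fall inside the hull of the foreground pixel
centers), so solidity is consistently ≤ 1 by construction and a round cell
measures 1 within rasterization tolerance.

**Pooling.** Group statistics pool all frames of all cells per treatment
group, matching how variable-length single-cell series are conventionally
combined; because frames of one cell are not independent, per-cell means
are also attached to every morphology table rather than silently replacing
the pooled analysis.

**Membrane motility.** Opening the mask with a disk of 2 µm diameter — the
upper bound of filopodium thickness — removes fine protrusions and leaves
the cell body. Expansion and retraction are the per-frame-pair area gained
and lost by the body; both the raw areas and the index normalized by mean
body area are reported, since either normalization is defensible.

# Filopodia kinetics

A filopodium is a traced backbone with a time-varying length. Two entry
paths are supported and labeled in the output, because published tracking
procedures are usually manual or semi-automatic: (a) *automatic* — each
frame's protrusion mask (a maximum-intensity projection; 3D path tracing is
out of scope) is thinned to a skeleton (Zhang–Suen), and the backbone is
the geodesic from the base anchor to the farthest connected skeleton pixel;
(b) *annotated* — manual tip points override tracing.

Numerical details of the automatic path: geodesic length is measured over
4-pixel chords of the ordered path rather than unit steps, suppressing
8-connectivity metrication bias; thinning erodes roughly half the
protrusion width at each end, so the base connector is added back exactly
and the tip is extended to the mask margin along the terminal direction.
On fixtures this recovers a straight 6 µm protrusion to ±0.05 µm and a
quarter-circle arc (true length 2π µm) to ~1%, correctly exceeding the
base-to-tip chord. Branches are followed to the longest endpoint and
counted in a log attribute.

"Instantaneous" rates are consecutive-frame ΔL/Δt with no smoothing — at
12–20 s sampling this is a near-derivative, and any smoothing would mix
extension and retraction phases. Classification into
extension/retraction/pause uses a ±0.1 µm dead-band per frame pair to
suppress segmentation jitter (set it to 0 for noiseless or simulated
data; the exact-recovery tests do). Mean extension and retraction rates
average only their own phase, as positive magnitudes. Cohort summaries
report each filopodium's maximal length, the fraction below 9 µm and the
count above 15 µm, the two headline descriptors of filopodial reach in
this system.

# Statistics

- **t-test from summaries.** Published comparisons often provide only
  mean ± sd and n; the closed-form unpaired t (pooled and Welch) is exact
  for such inputs, and the tests verify it matches `t.test` on raw data
  constructed to the same summaries to 1e-12. Which variant a given paper
  used is often unknowable from rounded summaries, so both are always
  available and reported side by side.
- **Rank tests.** Mann–Whitney U uses the exact small-sample distribution
  when possible (verified against full enumeration: {1,2,3} vs {4,5,6}
  one-tailed gives p = 1/20) and the tie-corrected normal approximation
  otherwise. One-tailed directions must be declared explicitly — a silent
  default direction is a classic source of irreproducible p-values.
  Kruskal–Wallis is followed by Dunn's z comparisons with Bonferroni
  adjustment over the tested pairs, the common reading of "Dunn's multiple
  comparison test".
- **ANOVA + Dunnett.** One-way F, then many-to-one comparisons against the
  named control via multivariate-t critical values. All-constant groups
  (zero within-group variance) are flagged rather than reported as
  infinite F.
- Box-whisker panels follow the field's two conventions: 10–90% whiskers
  for rate/length cohorts and 5–95% for islet-volume cohorts, box 25–75%,
  median line, mean marked "+".

# The synthetic-data generator

The generator produces the study conditions every test runs under:

- **Scenes**: an ellipsoidal "pancreas" (red) containing non-overlapping
  spherical "endocrine cells" (green) on grids of ~40×96×96 voxels at
  (1, 0.5, 0.5) µm — a realistic confocal anisotropy — blurred by an
  anisotropic Gaussian PSF approximation and corrupted by Poisson shot
  noise on the signal plus additive Gaussian read noise, the standard
  fluorescence noise model. Channel intensities are free parameters; no
  published intensity statistics exist to match.
- **Motion**: Euler updates x ← x + k(centroid − x)Δt + noise. Defaults
  (k = 0.004/min, Δt = 18 min, diffusion 0.3 µm/√min) contract a ~500 µm³
  hull by roughly half over ~90 min against visible noise, the timescale of
  observed coalescence.
- **Cells and filopodia**: disk-bodied cells with thin radial arms;
  piecewise-linear filopodium length programs (segment rates in µm/min,
  diameter constrained < 2 µm). Synthetic treated cohorts use fewer,
  shorter protrusions and a slightly smaller body than controls — the
  compact phenotype — so direction tests are forced by construction.
- Identical spec + seed is bit-identical everywhere; the seed is recorded
  in ground-truth output.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: optical aberrations beyond a Gaussian
PSF, tissue autofluorescence structure, registration drift (assumed
corrected upstream), touching or dividing cells (endocrine differentiation
is associated with cell-cycle exit, so divisions are out of scope by
design), filopodia that leave the projection plane, and photobleaching.
Tests on synthetic scenes establish *numerical* correctness of the
measurements, not segmentation robustness on arbitrary tissue.

# Problem sizes and numerical tolerances

The test suite and the acceptance script use: scenes up to 48×96×96
voxels; 20 Monte-Carlo hull cross-checks at 4×10⁵ samples each (hull vs
integration agree within 1%, typical error ~0.3%); 1000-replicate null
simulations for test size; 15×80-step stochastic rate recoveries. Closed
forms are held to 1e-9 relative (hull), 1e-6 (contraction law), 0.02
absolute (rasterization-limited shape measures). These sizes make the
suite complete in a few minutes while leaving every stochastic check
several standard errors of headroom.

# Known limitations

- The hull statistic is sensitive to a single outlier cell; the
  `subset` argument of `clustering_series()` supports restricting to a
  tracked subset, but outlier handling is the analyst's decision.
- Otsu thresholding assumes a bimodal in-mask histogram; very sparse
  signal can push the threshold into the noise. The fixed-threshold mode
  is the remedy.
- Dunn's Bonferroni adjustment is conservative relative to some software's
  exact adjustment; adjusted p-values may differ slightly from other
  implementations.
- Filopodium lengths are projected 2D lengths when traced from projected
  masks; true 3D lengths are longer for out-of-plane protrusions.
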