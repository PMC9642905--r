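---
title: "Methods: endosomal microdomain quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endosomal microdomain quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodomain)
```

# The measurement problem

Coelomocytes are *C. elegans* scavenger cells with endosomes large enough
(1–5 µm) that coat-protein microdomains on the limiting membrane —
recycling patches (RME-8, SNX-1) segregated from degradative patches
(ESCRT-0/HRS) — can be resolved as arcs on a ring in a conventional
widefield image. The biological questions are quantitative: how much of
an endosome's circumference does a microdomain occupy, how enriched is a
marker on endosomal membrane relative to cytoplasm, does a marker
redistribute between the cell's interior and its periphery, do two
markers overlap, and how mobile is a marker in FRAP. These measurements
are usually made interactively in acquisition software and are hard to
reproduce. This package reimplements them as tested, scriptable
functions, and validates each one against synthetic images whose ground
truth is known exactly.

# Geometry conventions

Pixel coordinates are 0-based and pixel-centered; the row index is the y
axis, increasing downward; column is x. Angles are degrees
counter-clockwise from the +x image axis (so with y pointing down, a
point at angle θ lies at `x = cx + r cos θ, y = cy − r sin θ`). ROIs carry
physical radii (µm) and are evaluated against pixel centers at the
image's `pixel_size_um`. All "above threshold" comparisons are strict
(`>`); the convention is arbitrary but must be fixed, and it is applied
identically in the generator's oracles and the metrics.

# The synthetic scene generator

`scene_spec()` / `generate_coelomocyte()` emulate the stereotyped
coelomocyte layout: a bright cytoplasm disc on dim background, a dark
nucleus, and ring-shaped early endosomes placed peripherally, each
carrying one angular arc per channel representing a microdomain. The
rendering is deliberately idealized:

- **Piecewise-constant rendering, no anti-aliasing.** A ring pixel
  belongs to the arc iff its angle from the endosome center lies in
  `[arc_center − 180·coverage, arc_center + 180·coverage)`. This keeps
  the analytic prediction of every downstream metric exact in the
  noise-free case, which is the point of the generator: testability over
  realism.
- **Additive Gaussian noise, clipped at zero**, one standard deviation
  for the whole frame. This is the simplest model that exercises
  thresholding; photon (Poisson) statistics, detector gain structure and
  deconvolution artifacts are intentionally out of scope.
- **Single 2D plane.** Real acquisitions are deconvolved z-series
  projections; whether projection artifacts bias the metrics is untested
  here, so a green recovery test establishes correctness of the
  *computation*, not robustness to 3D optics.
- **Seeding.** One top-level seed per spec; channel noise is drawn in
  channel order from that seed, so identical spec + seed is bit-identical.
  Generators save and restore the caller's RNG state.

Default intensity levels (background 10, cytoplasm 100, ring 150,
arc 400 AU, noise 0–15 AU) were chosen once to mimic a well-exposed
12-bit widefield acquisition with strong microdomain contrast
(arc:ring ≈ 2.7:1) and are not tuned to any test outcome; the
recovery tolerances below come from the angular pixelation of the
rendering, not from the intensity scale. Default geometry (cell radius
10–12 µm, nucleus 3 µm, endosomes of radius 1.2–1.8 µm at 0.1 µm/px) is a
typical coelomocyte at a typical camera sampling.

The FRAP generator renders a bleach disc, an unbleached reference disc
and camera background, with the bleach-region fluorescence following
`floor + (prebleach − floor) · m · (1 − e^{−t/τ})` after the bleach and a
whole-frame multiplicative fade `(1 − ρ)^{frame}` modeling acquisition
photobleaching. Because the fade multiplies fluorescence above background
in both the bleach and reference regions, double normalization cancels it
exactly — this identity is asserted to 1e−9 in the tests.

Sequence fixtures plant non-overlapping IWN 4-mers at recorded positions
in otherwise random sequences; hit-table fixtures plant an exact count of
rows passing the coverage/e-value screen, including exact boundary rows
(coverage = 40.0, e-value = 1e-3) that must be *excluded* by the strict
filter.

# The metrics and their numerical choices

**Spread.** `circle_profile()` samples the image at the ring's nominal
radius by bilinear interpolation — a single-pixel-width scan, because the
width of the original interactive line scans is not standardized; a
width-averaged variant (mean of 5 radial taps across the ring width) is
available via `width_average = TRUE`. The default sampling density is one
sample per circumference pixel (`ceiling(2πr_px)`), which makes
`1/n_samples` the natural angular pixelation scale: noise-free recovery
of arc coverage is exact to within that scale, and that is the tolerance
the acceptance suite enforces. The spread of one cell is the mean over
its endosomes (≥3 in the standard design), matching the
one-value-per-animal aggregation used for plotting.

**Membrane/cytoplasm ratio.** Three 3-µm-diameter discs on endosomes,
three on non-endosomal cytoplasm; ratio of the pooled per-disc means.
`place_measurement_discs()` automates off-disc placement by seeded
rejection sampling constrained to the cell disc and away from every
endosome ring; a bounded retry budget converts impossible geometry into
an informative error rather than a hang.

**Interior/peripheral ratio.** The equal-area split puts the interior
radius at `R/√2`; masks use half-open annulus inclusion so the two
regions partition the cell's pixel set exactly. The numerator and
denominator are *integrated* above-threshold intensity (sums); a
mean-based variant exists behind `statistic = "mean"`. A region with zero
above-threshold intensity raises an error — no epsilon fudge — because a
silent ±Inf on the log2 scale would corrupt downstream summaries.

**Thresholded Pearson.** The correlation is computed over pixels above
threshold in *either* channel by default. The union rule was chosen over
the intersection rule because conditioning on both channels being bright
biases r upward; both, plus an unthresholded variant, are exposed via
`include =`. Degenerate inputs (fewer than two pixels, zero variance)
raise errors.

**Otsu.** Default threshold source when none is given, since published
interactive thresholds are unrecorded. 256-bin histogram over the region;
ties in between-class variance (plateaus across empty bins in well
separated histograms) resolve to the mean of the maximizing split
positions, which is deterministic and symmetric.

**Fiber length.** No procedure for fiber-length measurement on
microdomain masks is standardized, so the package declares one: per
8-connected component, Zhang–Suen thinning to a one-pixel skeleton, then
the sum of minimum-spanning-tree edge weights over the skeleton's
8-neighbor pixel graph (1 for orthogonal, √2 for diagonal steps) scaled
by pixel size. The MST avoids double-counting the orthogonal+diagonal
triangles that raw pairwise adjacency would count twice; on a clean
1-pixel path it reduces to the exact path sum (11 collinear pixels at
0.1 µm/px → 1.0 µm; the 45° diagonal → √2 µm).

**FRAP fitting.** `F(t) = F₀ + (plateau − F₀)(1 − e^{−t/τ})` with `F₀`
fixed to the first post-bleach value, fitted to the post-bleach samples.
The amplitude enters linearly and is profiled out analytically, reducing
the fit to a 1-D search over τ (coarse log-spaced bracket, then Brent
refinement). This avoids the classic `nls()` failure on zero-residual
synthetic data and reaches the 1e−6 noise-free round-trip tolerance. A
flat curve (zero amplitude) is reported as mobile fraction 0 with τ
flagged unidentifiable rather than an error; mobile fractions outside
[0, 1.5] or τ at the search boundary clear the `converged` flag.
Initialization details (bracket limits) are derived from the sampled time
span, not from the data values, so the fit is scale invariant.

**IWN curation.** The motif is `[ILV] W ζ ζ` with
ζ = {S, T, N, Q, D, E, K, R, H} — the standard polar + charged set,
histidine included; the set is a function argument so curators can widen
it (e.g., add Y or C) since the boundary of "hydrophilic" is a judgment
call. `X` never matches. Overlapping windows are all reported (regex
lookahead in the implementation; the tests check it against exhaustive
window enumeration). The screen keeps hits with coverage strictly > 40 %
and e-value strictly < 1e-3, and a candidate needs ≥ 3 repeats — both
thresholds taken as written, with the strictness of the inequalities
exercised by boundary-value tests.

# What a green test establishes, and what it does not

Every metric is validated by parameter recovery on the generator's output
and/or by agreement with an independent brute-force oracle (loop-based
masked means, textbook correlation sums, exhaustive motif enumeration,
closed-form recovery curves). That establishes the computations are
correct on images with the generator's statistical structure: flat-field,
Gaussian-noise, single-plane, perfectly circular geometry. It does not
establish robustness to the features of real micrographs the generator
omits — out-of-focus haze, intensity gradients, non-circular endosomes,
projection artifacts, chromatic misregistration. The published mutant
comparisons themselves (plotted distributions from undeposited
micrographs) are not reproducible from the paper at desk scale, so the
acceptance surface is the metric's documented worked examples (the
±1.0/0.0 log2 semantics) plus the recovery criteria.

# Interfaces

In-memory types are plain S3 lists (`pixel_image`, `disc_roi`,
`ring_roi`, `angular_profile`, spec objects) with validating constructors
and print methods. On disk: a lossless plain-text image format (header +
`%.17g` values; no TIFF dependency exists in the supported offline
stack), ROI CSV (`kind, center_x_px, center_y_px, radius_um, width_um`),
FASTA via Biostrings, tab-separated hit tables (with a column-map hook
for `qcovs`-style headers), YAML/JSON configuration validated against a
closed key set, and a results CSV in which every row carries a
configuration hash for traceability. The CLI
(`inst/cli/endodomain.R`) binds generation, measurement, FRAP fitting and
motif curation into `simulate | measure | frap | iwn` subcommands.

# Known limitations

- Automatic endosome detection is not provided; ROIs come from ground
  truth or user CSV, mirroring manual region selection in the original
  workflow.
- The FRAP model is a single-exponential reaction-dominant
  approximation; diffusion-coupled models (Soumpasis) and two-component
  fits are out of scope, and on real data τ from this model is an
  effective, not mechanistic, constant.
- Fiber length on thick or branched structures depends on the thinning
  topology; branch points contribute their MST path, which slightly
  undercounts total branched length relative to per-branch summation.
- The equal-area split assumes a circular cell; strongly non-circular
  coelomocytes would need a segmented-mask variant.
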