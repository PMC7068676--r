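---
title: "Methods: moment-based fiber orientation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moment-based fiber orientation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibermoments)
```

## The measurement problem

Differentiating muscle cells in the embryonic limb elongate and align into
clusters of parallel fibers. The input to this package is the standard
manual quantification of that process: on every optical section of a
confocal z-stack, a line is drawn over the long axis of each elongated
myogenin/myosin-positive cell, yielding one binary trace image per
section. The package converts such a stack into per-fiber axial
orientations, orientation-binned color projections, and summary statistics
of orientational order.

The unit of analysis is the *fiber segment* — one connected trace — and
all orientations are *axial*: a fiber pointing at θ and at θ + 180° is the
same orientation, so every statistic operates on angles modulo 180°.

## Pipeline and model

### 1. Branch-point removal

Where drawn fibers cross or touch, their traces share pixels; a moment
computed over such a merged component would average two different
orientations. We therefore remove *branch points* before labeling: any
foreground pixel with three or more foreground neighbors under the chosen
connectivity. Interior pixels of a 1-pixel-wide line have exactly two
neighbors, so isolated fibers are untouched while crossings and junctions
are disconnected.

Exactly **one** removal pass is applied. Iterating to a fixpoint seems
attractive but can erode genuine fibers: after removing a junction, pixels
on a staircase diagonal may transiently qualify and a fixpoint iteration
eats its way down the fiber. One pass is sufficient to disconnect
junctions of 1-pixel traces, which is the input modality here.

### 2. Segment extraction

The pruned plane is labeled into connected components (default
8-connectivity, because hand-drawn diagonal strokes are 8-connected
chains; 4-connectivity is available). Components shorter than
`min_segment_length` pixels are discarded and tallied — these are mostly
junction debris left between removed branch pixels. The default of 5 px
suppresses that debris while retaining short myocyte traces; the threshold
is configurable and all drops are reported. Segment ids follow the
raster-scan order of each component's first pixel, then plane order, so a
decomposition is deterministic and reproducible.

Input traces are assumed ≈ 1 pixel wide. Thicker input is accepted, and an
optional Zhang–Suen thinning pre-step (`thin = TRUE`, off by default)
reduces outline- or blob-style input to centerlines first.

### 3. Orientation from second-order central moments

For a segment with pixels (x_i, y_i) and centroid (x̄, ȳ), the unweighted
second-order central moments are

μ20 = Σ(x−x̄)², μ02 = Σ(y−ȳ)², μ11 = Σ(x−x̄)(y−ȳ),

and the axial orientation is the principal axis of this 2×2 tensor,

θ = ½ · atan2(2 μ11, μ20 − μ02) (mod 180°).

The atan2 form is algebraically identical to the leading eigenvector of
the pixel covariance but branch-free at μ20 = μ02. Moments are unweighted
(each pixel counts once) because drawn traces carry no meaningful
intensity.

**Coordinate frame.** x is the column index increasing rightward, y the
row index increasing downward, both 0-based; θ is measured from +x toward
+y. Since y points down, θ increases clockwise on screen. Nothing
downstream depends on the handedness — what matters is internal
consistency between moments, histograms and rendering — and the rendered
images are written with the y-axis as stored (any display flip is a viewer
concern).

**Degeneracy.** A segment with fewer than two pixels, or an isotropic
tensor (|μ20 − μ02| and |μ11| both < 1e−9 × pixel count), has no preferred
axis. Such segments are retained but flagged, excluded from histograms and
order statistics, and painted a reserved neutral gray in renderings. The
tolerance avoids assigning a noise-driven arbitrary axis to symmetric
remnants.

### 4. Binning and hue coding

Angles are reduced modulo 180° into [0°, 180°) and assigned to
`n_bins = 32` equal half-open bins of width 5.625°,
bin = ⌊θ / (180/n_bins)⌋; an angle of exactly 180° wraps to bin 0, which
is forced by the axial topology. The hue LUT sweeps HSV hue 0° (red) to
300° (magenta) across the bins at full saturation and value: a monotone
"rainbow ruler" whose endpoints remain visually distinct even though the
angle axis wraps. Endpoints are configurable.

Where segments from different planes overlap in a projection, the topmost
plane (largest section index) wins — any deterministic rule would do; this
one is simple and stable under re-runs.

### 5. Order statistics

With doubled angles φ = 2θ, the nematic order parameter and mean axis are

S = |Σ w e^{iφ}| / Σ w, mean axis = ½ arg(Σ w e^{iφ}) ∈ [0°, 180°).

S = 1 for perfectly parallel fibers; S = 0 for an isotropic field (and for
an exactly orthogonal equal-weight pair, where doubled angles cancel — a
useful reminder that a *global* S near 0 does not mean "disordered" when
the histogram is multimodal). Default weighting is one count per segment,
matching the figure convention of coloring whole vectors; per-pixel
weighting (w = pixel count) is available when longer fibers should count
more. `compare_conditions()` reports ΔS between two maps descriptively;
no p-value is attached because a permutation test over specimens, not
segments, would be the honest unit and single maps do not support it.

## Stack geometry

Physical calibration travels in a key-value sidecar file
(`n_sections`, `z_spacing_um`, optional `pixel_size_um`, `label`), never
parsed from TIFF tags — tag dialects are unreliable, and when a resolution
tag conflicts with the sidecar a warning is raised and the sidecar wins.
The total imaged depth is reported as n_sections × z_spacing (to 0.01 µm),
the convention under which a 46-section series at 1.51 µm spans 69.46 µm.
Published legends occasionally print depths rounded from a rounded
spacing; the package reports the exact product.

## The synthetic generator

`generate_field()` emulates the statistical structure of traced myocyte
fields: spatial clusters of short 1-pixel-wide line segments, each cluster
with a mean axis and an angular dispersion, from isotropic to tightly
aligned.

* **Angular noise** is von Mises on the doubled angle: 2θ ~ vM(2·mean, κ),
  the standard axial-data construction. κ = 0 gives uniform axial angles;
  κ ≥ 1e8 is treated as the zero-dispersion point mass and returns the
  mean exactly. Sampling uses the Best–Fisher rejection algorithm.
* **Placement** is uniform within rectangular cluster regions, sections
  chosen uniformly; compaction is modeled only through region size.
* **Rasterization** draws the digital line of the *exact* real-valued
  endpoints: one pixel per integer step of the driving axis with the
  companion coordinate interpolated on the true line. This keeps every
  chain 8-connected with exactly two neighbors per interior pixel (so
  branch removal never bites into a lone fiber) and avoids the angle bias
  that rounding endpoints before rasterizing introduces in short fibers.
  Residual quantization still limits single-fiber angle accuracy: for the
  default 10–40 px lengths the recovered angle of an individual fiber can
  deviate by a few degrees (the shortest fibers dominate the tail), while
  cluster *mean* axes, which average over many fibers, recover to well
  under a degree in the test suite.
* **Non-crossing mode** (default) re-draws any fiber that would touch or
  cross an existing fiber in its plane, up to 100 attempts, then drops it
  with a count; a drop rate above 50% aborts with advice to enlarge the
  region. In non-crossing fields every fiber is exactly one recovered
  segment, which is what makes fiber-level ground-truth matching exact.
* **Determinism**: identical spec + seed give bit-identical stacks, and
  each cluster draws from its own deterministic sub-stream of the seed so
  one cluster's fibers are stable when another cluster is added.
* **Defaults** (512×512 px, 10 sections, lengths 10–40 px, tens to
  hundreds of fibers per cluster) are stated as plausible fixtures for
  traced fields at these densities, not as biological measurements —
  fiber length and density statistics for the source tissue are not
  available.

What the generator deliberately does **not** model: fluorescence imaging
physics (PSF, noise), the manual tracing error process, curved or branched
fibers, and temporal dynamics. Passing recovery tests therefore shows the
*computational* pipeline is correct on its stated input modality (clean
1-px line traces); it does not validate tracing quality on real images.

## Numerical and testing choices

* Orientation is cross-checked against an independent brute-force oracle:
  scan candidate axes at 0.001° spacing for maximal projected variance,
  then refine by the vertex of the parabola through the three best
  samples. The moment axis agrees with this oracle to < 1e−6° over
  thousands of random real-coordinate segments.
* Hand-enumerable crossing fixtures pin the decomposition exactly. A
  plus-sign is checked under 4-connectivity — under that definition only
  the center pixel is a junction and the four 2-px arms survive as
  separate segments; under 8-connectivity the flanking pixels are
  junctions too and the arms would merge diagonally, so the 4-connected
  enumeration is the discriminating one. The X-cross is checked under
  8-connectivity, where removing the single crossing pixel leaves four
  2-px diagonal arms.
* Test problem sizes are kept at a few hundred fibers on stacks of a few
  hundred pixels square — large enough that stochastic assertions (KS
  distance of uniform sampling, S of isotropic fields, monotonicity of S
  in κ at 500 fibers per level) have comfortable margins at fixed seeds,
  and small enough that the whole suite runs in well under a minute.
* All RNG flows through R's global generator, seeded explicitly by every
  test and by the acceptance script's `--seed`.

## Known limitations

* No gap closing or re-joining of fibers across removed junctions: a
  fiber crossed by another is reported as two (or more) shorter segments.
  Counts from crossing-rich fields are therefore segment counts, not
  fiber counts, though orientation histograms remain faithful (verified
  by the crossing stress tests).
* No 3-D linking of traces across sections; each plane is analyzed
  independently, as the tracing protocol implies.
* Spatial cluster discovery (assigning segments to anatomical muscle
  groups) is out of scope; regions of interest are the user's
  responsibility via `z_range` and cropping.
* The moment axis is the maximum-variance axis; for strongly curved
  traces it summarises the chord direction, not local tangents.
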