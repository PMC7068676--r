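# fibermoments

Quantifying muscle-fiber orientation from binary trace z-stacks.

During limb development, differentiating muscle cells (myocytes) elongate
and progressively align into clusters of parallel fibers. A standard way to
measure this is to draw a line over the long axis of each elongated cell on
every optical section of a confocal z-stack, producing a stack of binary
trace images. `fibermoments` turns such stacks into quantitative
orientation maps:

1. **Decomposition** — each binary plane is split into individual fiber
   segments: junction pixels (foreground pixels with ≥ 3 foreground
   neighbors, where fibers cross or touch) are removed in one pass, the
   remaining pixels are labeled into connected components, and components
   below a length threshold are discarded.
2. **Orientation** — each segment's axial orientation is the principal
   axis of its pixel set, computed from the second-order central moments
   μ20 = Σ(x−x̄)², μ02 = Σ(y−ȳ)², μ11 = Σ(x−x̄)(y−ȳ) as

   θ = ½ · atan2(2 μ11, μ20 − μ02),  θ ∈ [0°, 180°).

3. **Binning and rendering** — angles are normalised to 0–180° in 32
   equal half-open bins and hue-coded with a monotone rainbow LUT;
   binary and color-coded z-projections reproduce the standard
   "vector projection" figures.
4. **Order statistics** — orientational order is summarised by the
   nematic order parameter S = |Σ w·e^{2iθ}| / Σ w (1 = perfectly
   parallel, 0 = isotropic) and the mean axis ½·arg(Σ w·e^{2iθ}),
   computed on doubled angles because fiber orientation is axial
   (θ and θ + 180° are the same fiber).

Because manually traced confocal data are rarely deposited, the package
includes a fully seeded synthetic fiber-field generator (clusters of
1-pixel-wide digital lines with von Mises angular dispersion and complete
per-fiber ground truth) so the whole pipeline can be validated end to end.

## Worked example

Two clusters of 80 fibers each, mean axes 30° and 120°, concentration
κ = 100, on a 400×400 px stack of 6 sections:

```r
library(fibermoments)

spec <- synthetic_field_spec(
  width = 400, height = 400, n_sections = 6, z_spacing = 1.51,
  clusters = list(cluster_spec(30, 100, 80, c(25, 25, 185, 375)),
                  cluster_spec(120, 100, 80, c(215, 25, 375, 375))),
  seed = 42)
field <- generate_field(spec)

map <- orientation_map(field$stack)   # decompose + orient + bin
summary(map)
#> Fiber orientation map 'synthetic seed 42'
#>   400 x 400 px, 6 sections; 160 segments (0 degenerate), 32 bins over 0-180 deg
#>   discarded: 0 sub-threshold components (0 px), 0 branch pixels removed
#>   nematic order parameter S = 0.0021, mean axis = 172.83 deg (segment weighting)
#>   occupied bins (6 of 32): 4 5 6 20 21 22
```

The two clusters are nearly orthogonal, so the *global* order parameter is
≈ 0 (orthogonal axes cancel in doubled-angle space) while the histogram is
sharply bimodal around bins 5 (30°/5.625°) and 21 (120°/5.625°). Against
the generator's ground truth:

```r
recovery_report(field$truth, map)
#> Recovery: matched 160 / 160 fibers (rate 1.000); angle error mean 0.286 deg, max 1.983 deg
#>  cluster mean_axis_true_deg mean_axis_recovered_deg    err_deg  n
#>        1                 30                30.09389 0.09388986 80
#>        2                120               120.21252 0.21251606 80
```

Rendering and export:

```r
plot(map)                                             # hue-coded projection + ruler
write_projection_png(render_colored_projection(map), "vectors_hue.png")
write_projection_tiff(project_binary(map), "vectors_binary.tif")
write_segment_table(map, "segments.tsv")
```

Real data enter through `load_trace_stack()` (multi-page TIFF of binary
traces, any nonzero sample = foreground) with the physical calibration in
a small key-value sidecar read by `read_geometry()`. Depth bookkeeping
follows the sections × spacing convention, e.g.
`total_depth(46, 1.51)` → `69.46` µm.

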