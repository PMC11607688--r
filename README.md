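# gastroquant

Quantitative image and single-cell analysis of anteroposterior (AP) symmetry
breaking in gastruloids — stem-cell aggregates that self-organize a body axis
by polarizing T (brachyury) expression toward the prospective posterior.
The package is for developmental biologists and image analysts who need the
full quantification chain behind such experiments as reusable, tested R
functions:

* **Segmentation** of the aggregate from brightfield: a ~340-feature
  multi-scale bank (difference of Gaussians, Gaussian gradients, Laplacians
  of Gaussian, DAISY-style orientation descriptors) feeding a three-class
  multinomial logistic-regression pixel classifier
  (background / inside / edge), a seeded watershed on the edge-probability
  landscape as the preferred alternative mask, an automated selection policy
  with classifier fallback and manual override, and morphological smoothing.
* **Morphometrics**: area and sub-pixel perimeter; the midline (AP axis) as
  the ridge of the interior distance transform with local width; computational
  straightening; and the second-moment eccentricity
  `e = sqrt(1 - (b/a)^2)`, where `a` and `b` are the major and minor axis
  lengths of the ellipse with the same second moments as the straightened
  mask.
* **AP profiles**: mean intensity orthogonal to the midline at every arc
  position, oriented so the highest-T pole is posterior (position 1),
  rescaled to [0, 1], normalized globally / per group / per channel-maximum;
  replicate mean ± s.d. bands, time-lapse kymographs with orientation locked
  on the final frame, and multichannel (HCR-style) profiles along a
  T-defined axis.
* **Tissue flow**: rigid pre-registration (phase correlation + rotation
  search), pyramidal Lucas–Kanade optical flow (3 levels, 20 px window, one
  measurement every 10 px), and sliding 16-frame temporal averages emitted
  every 4 frames.
* **Single-cell utilities**: the printed per-dataset QC filter presets
  (strict inequalities on unique feature count, mitochondrial %, total RNA
  count), log-normalization, T/Sox2 marker gating (> 1.5 / ≤ 0.05 and
  > 1.0 / ≤ 0.05), nearest-neighbour label transfer in 50-dimensional PC
  space, the three transfer-quality statistics (mean k-NN distance,
  agreement score, unique-mapping fraction; k = 30), cluster-correlation
  matrices over averaged PC components, and ±1 cluster-average differential
  expression with top-10 reporting.
* **Synthetic data with exact ground truth** — silhouettes with polarized
  reporters, advected time-lapses, QC cell tables, paired query/reference
  embeddings with a controllable mixing parameter — so every stage is
  benchmarked end to end without external data.

Results are tibbles that chain with the pipe; result types have
`autoplot()` methods (profiles with s.d. ribbons, kymographs, quiver plots,
correlation heatmaps) and the fitted classifier and transfer-QC objects have
broom-style `tidy()` / `glance()` methods.

## Worked example

Generate a bent, polarized synthetic gastruloid, measure its shape, and
extract the oriented AP profile:

```r
library(gastroquant)

sp <- shape_spec(length_px = 150, width_px = 50,
                 bend_curvature = 1/150, orientation_deg = 20)
ch <- list(polarization_spec("T", function(s) 6000 * s, noise_sd = 300))
s  <- make_gastruloid_image(sp, ch, seed = 7)
s
#> <synthetic_sample> axis 150 px, width 50 px, curvature 0.006667 1/px, seed 7
#> <image_sample 'synthetic'> 256 x 256 px, channels: BF, T

measure_shape(s$true_mask, sample_id = "demo")
#>   sample_id area perimeter midline_length mean_width eccentricity degenerate_axis
#> 1      demo 6958       359          148.5      49.61       0.9401           FALSE

ml <- extract_midline(s$true_mask)
pr <- ap_profile(s$image, s$true_mask, ml, sample_id = "demo")
on <- orient_and_normalize(pr, reference_channel = "T",
                           intensity_norm = "per_channel_max")
head(on[, c("channel", "position", "intensity", "flipped")], 3)
#>   channel position intensity flipped
#> 1       T   0.0000    0.0667    TRUE
#> 2       T   0.0101    0.0623    TRUE
#> 3       T   0.0202    0.0570    TRUE
```

The shape row says the 150 × 50 px capsule was measured at 148.5 px axis
length and 49.6 px mean width with straightened eccentricity 0.94 (strongly
elongated). The profile rows are the normalized T intensity on the common
[0, 1] AP grid: near-zero at the anterior (position 0), rising toward the
posterior where it peaks at 1 by construction of the per-channel-maximum
normalization; `flipped = TRUE` records that the raw midline happened to run
posterior-to-anterior and was reoriented by the highest-T-pole rule.

`autoplot(on)` draws the mean ± s.d. profile; `segment_sample()`,
`klt_flow()`, `transfer_qc()` etc. follow the same pattern. A thin command
line over the same functions is installed at
`system.file("cli", "gastroquant.R", package = "gastroquant")` with
subcommands `simulate`, `segment`, `profile`, `flow` and `scqc`.

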