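---
title: "mitoHCS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoHCS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and its readouts

mitoHCS implements single-cell image analysis for a plate-based
high-content assay of mitochondrial health in cultured cells, built
around three fluorescent dyes imaged per field:

* a **nuclear stain** (Hoechst 33342) marking every nucleus, live or
  dead;
* a **cytoplasmic viability stain** (Calcein-AM) retained only by live
  cells, which therefore also delineates the cell soma;
* a **potential-dependent mitochondrial stain** (TMRM in non-quench
  mode), whose per-cell fluorescence is a proxy for mitochondrial
  membrane potential: depolarized mitochondria are dimmer.

From one field the pipeline produces, per cell: whole-cell and
mitochondrial mean TMRM intensity (measured on the *original* image,
never the enhanced one), four mitochondrial morphology statistics
(mean object area, total mitochondrial area divided by cell area,
aspect ratio, major-axis length), and a live/dead call. Per-cell
values are averaged per image, because the image — not the cell — is
the unit of statistical analysis; image means are then normalized to
the control-basal group of the same experiment and compared with
nonparametric tests.

# Pipeline stages

**Nuclei.** Otsu's threshold computed on a 65,536-bin histogram of the
raw 16-bit counts (no rescaling, so the threshold lives on the count
scale and is shift-equivariant for integer offsets; ties across the
flat optimum are resolved to the midpoint). The binary mask is
hole-filled, objects below `nucleusMinAreaPx` are removed, clumped
nuclei are optionally split by a distance-transform watershed whose
peak-suppression radius derives from the minimum area, and components
are labeled with 8-connectivity. Nuclei touching the border are kept
by default (`borderPolicy`).

**Soma.** The cytoplasm channel is thresholded by Otsu; the foreground
mask, united with the nucleus pixels, is partitioned by seeded
propagation: every foreground pixel joins the nucleus reachable at
minimal accumulated cost, where a step to an 8-neighbor costs its
length (1 or sqrt(2)) plus `lambda` times the absolute intensity
difference (default `lambda` 0.05 per count). Ties go to the lower
seed label, which makes the result order-independent and
deterministic. The relaxation is run to its fixed point, so the
assignment is the exact minimum-cost one — the package carries a
brute-force shortest-path oracle in its test suite to pin this down.

**Viability.** A cell is dead iff its soma area does not exceed its
nucleus area: a Calcein-negative cell gains no pixels by propagation,
so its soma collapses onto its nucleus. The same area rule, applied to
a soma propagated on an immunostain channel, yields marker positivity
(percent of nuclei with corresponding cytoplasmic staining). An
optional minimum mean-Calcein intensity cut exists but is off by
default, since the area rule alone is the documented behavior.

**Mitochondria.** The TMRM image is enhanced with a white top-hat
(input minus its grayscale opening by a flat disc, radius
`tophatRadiusPx`, default 3 px), which removes diffuse and out-of-focus
background while preserving punctate and elongated bright objects. A
*fixed* threshold — not a per-image one — segments the enhanced image,
so that intensity differences between conditions express themselves as
segmented-area differences rather than being normalized away. The
default (120 counts) is calibrated on the synthetic noise model as
roughly five times the total per-pixel noise sd inside a
basal-condition soma; it is a mandatory, logged configuration entry for
real data. Objects are assigned to the live soma containing their
centroid (majority-pixel overlap is available behind a flag), trimmed
to that soma, and — for morphology only — touching objects within one
cell are merged into single objects (transitive closure; objects in
different cells never merge).

**Morphology.** Each merged object is summarized by its
moment-equivalent ellipse. Pixels are treated as unit squares
(covariance of pixel centers plus 1/12 on the diagonal), and axis
lengths follow the 4*sqrt(eigenvalue) convention, so a rasterized disc
of diameter d measures about d on both axes, a single pixel has aspect
ratio exactly 1, and a one-pixel-wide bar has a small but strictly
positive aspect ratio. This keeps the aspect ratio inside (0, 1],
where higher values mean rounder, i.e. more fragmented, mitochondria.
With point moments (no 1/12 term) thin bars would degenerate to aspect
0; the unit-square convention was chosen to avoid that degeneracy and
is cross-checked against EBImage's moment features on thick objects,
where the correction is negligible.

# Statistics

Per-image summaries are unweighted means over live cells (fields with
fewer than `min_cells_per_image` live cells, default 5, are dropped).
Normalization divides each readout by the **median** of the
control-basal images of the same plate/experiment — median rather than
mean because downstream reporting is median-and-interquartile-range
based; the mean is available as an option. Normalization is never
pooled across experiments and is idempotent.

Group comparisons use the Kruskal-Wallis rank test (tie-corrected H,
chi-squared approximation), with Dunn's z post-hoc comparisons on the
joint ranks under Holm adjustment — the post-hoc procedure is a package
choice, made because pairwise p-value ranges are commonly reported
without naming one. Distribution shifts use the two-sample
Kolmogorov-Smirnov test (asymptotic p). Coefficient-of-variation
diagnostics compare cell-to-cell with well-to-well variability (per-well
means first). One-way ANOVA and t-test wrappers are provided as plain
comparison utilities (used e.g. for viability changes); they contain
nothing bespoke.

# The synthetic plate generator

Because the assay's raw patient imaging data cannot ship with a
package, every stage is validated against synthetic plates with exact
ground truth. A field is rendered as:

* nuclei: discs (radius ~N(9, 1) px) at centers placed by rejection
  sampling with a minimum separation (default: the soma radius);
* soma: larger discs (radius ~N(20, 2) px) drawn **only for live
  cells** on the cytoplasm channel;
* mitochondria: filled rotated ellipses (length ~N(7, 2) px, width
  2 px, ~Poisson(8) per live cell) placed uniformly in the soma annulus
  outside the nucleus, plus a faint diffuse cytosolic TMRM component
  (10% of the mitochondrial amplitude); both scale multiplicatively
  with the per-cell membrane-potential factor `tmrmScale` (1 = control
  basal);
* degradation: Gaussian optical blur (sigma 0.8 px), Poisson shot noise
  on signal + background (background 50 counts), additive Gaussian read
  noise (sd 10 counts), clipping to the 16-bit range.

The geometry corresponds to neurons imaged with a 40x objective at
roughly 0.3 um/px (soma diameter ~12 um); amplitudes (12000 / 3000 /
4000 counts for the three stains) put signals well inside the 16-bit
range at realistic signal-to-background ratios. Per-cell brightness is
log-normal (sdlog 0.25) — a conventional choice for fluorescence
heterogeneity; the distribution shape is configurable. Dead cells get
no cytoplasmic and no mitochondrial signal, and dead fraction, cell
count (fixed or Poisson) and a marker-positive fraction are all
parameters. Per-field seeds are a deterministic hash of (master seed,
well, field), so plates regenerate byte-identically in any order.

What the generator does **not** emulate: neurites and realistic neuron
morphology, optical PSFs, multi-z acquisition, uneven illumination,
inter-plate batch effects. Passing recovery tests therefore shows the
pipeline correctly inverts this generative model at realistic noise
levels — not that it is robust to every artifact of real microscopy.

# Verification designs and problem sizes

The test suite and `scripts/acceptance.R` use fixed standard designs:

* operator checks against brute-force oracles on images up to 40x40
  and samples up to 20 values (exact or 1e-9);
* segmentation recovery on 8 wells x 5 fields of 512x512 px with ~50
  non-overlapping cells each (minimum center separation = twice the
  soma radius), scored by one-to-one centroid-in-disc matching;
* membrane-potential recovery with control `tmrmScale` 1.0 vs patient
  0.7 on 104 images per group (256x256 px, ~12 cells each); the
  expected normalized whole-cell intensity is slightly above 0.7
  because background and additive offsets do not scale with potential;
* a CCCP-like condition at `tmrmScale` 0.25, inside the 19-32%-of-basal
  range typical for full depolarization;
* fragmentation as twice as many, half as long ellipses at equal
  expected total area;
* dead fractions {0, 0.2, 0.5} (about 1000 cells per fraction) and an
  oxidative-stress-like contrast 0.1 vs 0.4, both on non-overlapping
  plates -- when somas overlap, a dead nucleus lying inside a live
  cell's Calcein disc captures nearby foreground by propagation and
  reads as live, so dead-cell recovery is only well-posed without
  overlap (see Known limitations);
* null calibration of the Kruskal-Wallis and KS tests with 1000
  replicates at n = 1000 per group. The size of the KS test at
  screen-typical sample sizes (tens to hundreds of images) is ~0.035
  - 0.04 — conservative, because the supremum statistic is discrete —
  and only approaches the nominal 0.05 at large n, so the calibration
  check is run where the asymptotic reference is accurate.

# Numerical and design notes

* All label maps are integer matrices, 0 = background, 8-connectivity
  throughout; coordinates are 0-based (row, col), pixel-center
  convention.
* Images are 16-bit unsigned on disk (single-page grayscale TIFF, one
  file per channel, `<plate>_<well>_f<field>_<channel>.tif`); internal
  arithmetic is double precision. Tables are CSV with numerics at 17
  significant digits, so write-read round-trips are lossless.
* Morphology fields are missing exactly when a cell has zero
  mitochondria; fields with zero nuclei yield missing percent-dead.
* Pixel size is optional metadata; all measurements are reported in
  pixels.
* Whole-cell intensity means include the nucleus pixels (the soma
  contains its nucleus by construction); this is documented behavior,
  not an accident of segmentation.
* A constant (zero-variance) channel yields an empty segmentation with
  a warning rather than an error.

# Known limitations

* The mitochondrial mask depends on the potential-dependent stain, so
  morphology describes only functioning mitochondria; a
  potential-independent mitochondrial marker channel is out of scope.
* Heavily overlapping cells are split by propagation geometry, not by
  morphology-aware declumping; the recovery guarantees quoted above are
  for plates with bounded overlap. In particular, a dead (Calcein
  negative) nucleus lying inside a neighboring live cell's cytoplasmic
  footprint acquires foreground pixels by propagation and is
  misclassified live, so percent-dead estimates carry a downward bias
  that grows with cell crowding; symmetrically, marker positivity is
  biased upward when negative nuclei sit inside positive cells'
  footprints. The recovery designs therefore use non-overlapping
  plates.
* The Otsu-based soma mask assumes each field contains some live cells;
  a field that is entirely dead degrades to nucleus-only somas (all
  cells classified dead) only when the Calcein channel is truly blank.
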