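---
title: "Quantifying X-chromosome compaction, radial position and derepression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying X-chromosome compaction, radial position and derepression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xquant)
```

# Scope and model

In XX *C. elegans* hermaphrodites the dosage compensation complex (a
condensin I variant distinguished by the SMC subunit DPY-27) halves
transcription chromosome-wide on both X chromosomes, compacts them into a
smaller nuclear volume than their DNA content predicts, and anchors them
near the nuclear periphery. Perturbing the complex therefore has three
measurable signatures, and `xquant` implements the quantitative readout for
each:

1. **Compaction** — the fraction of the nuclear volume occupied by the X
   territory, from two-channel 3D image stacks (a DNA stain and an
   X-paint FISH or IF signal): `v = |X mask ∩ nucleus mask| / |nucleus
   mask|`, counted in voxels.
2. **Radial position** — the three-zone assay: a single in-focus mid-slice
   of the nucleus is partitioned into three concentric, equal-area
   elliptical zones, and the fraction of the thresholded signal in the
   central / intermediate / peripheral zone is reported.
3. **Derepression** — on a per-gene log2 fold-change table,
   `d = median(log2FC, X-linked) − median(log2FC, autosomal)`, with a
   two-sided Wilcoxon rank-sum comparison of the two gene sets and the
   fold-change equivalent `2^d`.

Supporting metrics are the line-scan enrichment ratio `E` (peak / minimum
interpolated intensity along a line through the enriched region, for
stains such as H4K20me1 that concentrate on the X), the normalized mean
nuclear intensity `I` (mean in-nucleus intensity over mean background
intensity), and contingency statistics for progeny-viability assays
(Fisher's exact test on pooled dead/live counts, chi-square for
on/off-auxin survival, brood viability ratios).

Because raw micrographs and sequencing runs are rarely available to a
method's consumers, every pipeline stage is paired with a synthetic-data
generator whose ground truth is known exactly; the test suite and the
acceptance script are built entirely on that loop.

# Image pipeline

`quantify_nucleus()` composes the stages in the order a microscopist
would: rolling-ball background subtraction on both channels → nucleus
segmentation on the DNA channel → signal segmentation inside the nucleus →
volume fraction; then mid-slice selection → ellipse fit with an
ellipticity gate → zones → zone fractions; and finally the line scan and
intensity ratio, which read the *raw* signal channel, since those two
metrics are defined on unprocessed intensities and the background level is
part of `I`'s definition.

**Rolling ball.** The background surface of each z-plane is the grayscale
opening with a paraboloid structuring function
`b(dx, dy) = −(dx² + dy²)/(2r)` on a square support of half-width `r`
(default 50 px, matching common practice for ~10 µm nuclei at ~0.1 µm
pixels). The additive separability of `b` lets the 2D opening factorize
exactly into four 1D passes, which is also what makes the brute-force 2D
opening an equality oracle in the tests rather than an approximation. The
radius must exceed the half-width of any feature that should survive;
radii smaller than the nucleus flatten the nucleus itself.

**Segmentation.** Otsu's criterion on the pooled stack histogram (the
threshold method is a parameter), then the largest 26-connected 3D
component with per-plane hole filling — dissected-nucleus fields contain
one nucleus by construction. The signal threshold is computed only from
voxels inside the nucleus mask and the resulting mask is intersected with
the nucleus, so non-specific staining outside it never contributes; no
largest-component filter is applied because a decondensed territory may
fragment. A signal channel that is constant inside the nucleus cannot be
thresholded: it yields the whole nucleus when uniformly bright and an
empty, flagged mask when uniformly zero.

**Zones.** The zone boundaries are the concentric ellipses with semi-axes
scaled by `√(1/3)` and `√(2/3)` — the contours enclosing one and two
thirds of the fitted ellipse's area. On the pixel grid, pixels inside the
outer ellipse are ranked by their squared elliptical radius and cut into
three equal-count groups (deterministic lexicographic tie-break), so the
discrete zone areas agree to within one pixel at any nucleus size; a pure
center-point rasterization of the two scaled ellipses leaves 2–3%
area imbalance for semi-axes near 20 px. The ellipse itself comes from
second-order image moments (with the 1/12 pixel-variance term), rescaled
to match the mask area. Nuclei whose mask-vs-ellipse Jaccard overlap falls
below 0.90 fail the ellipticity gate — the automated counterpart of
restricting the assay to smoothly elliptical nuclei — and keep `v`, `E`,
`I` but not zone fractions.

**Line scan.** The line runs through the nucleus centroid toward the
intensity-weighted signal centroid; when there is no signal (or the
centroids coincide) it falls back to the nucleus major axis, a
deterministic stand-in for drawing an arbitrary line when no enrichment is
visible. Samples are taken at unit-pixel steps with bilinear
interpolation whose weights are restricted to nucleus pixels, so samples
at the clipped endpoints never blend in extranuclear background — without
this, boundary samples mix in up to half an outside pixel and inflate `E`
by tens of percent. A 3-point moving average (edges replicated) suppresses
single-pixel noise before the peak/minimum ratio; intensities are floored
at `1e-6 ×` the maximum.

**Mid-slice.** Among the middle third of nucleus-containing planes, the
plane maximizing the normalized variance (variance/mean²) of the raw
signal within the nucleus is selected, ties toward lower z. Raw rather
than background-subtracted intensities are used because the subtraction
dome under a large nucleus adds spurious plane-to-plane variance.

# Synthetic data

`generate_nucleus_stack()` renders a solid ellipsoidal nucleus and a
single spherical territory in physical micrometer coordinates onto an
anisotropic grid (voxel membership by center-point test), with intensities
`base` in the nucleus, `k_true × base` in the territory, `bg` outside, an
optional linear gradient, and noise `N(0, noise_scale·√(intensity+1))` —
a Gaussian read-noise plus Poisson-variance scaling approximation.
Defaults: 72×72×32 voxels at 0.1/0.1/0.2 µm, semi-axes (3.2, 3.2, 2.4) µm
(≈ 51,000 nucleus voxels — small enough that a full two-preset batch of 40
nuclei quantifies in a couple of minutes, large enough that the realized
volume fraction lands within ±0.01 of the requested one), base intensity
100, background 20, enrichment 4, noise scale 1. The territory sphere
holds fraction `f_true` of the nuclear volume and is centered `r_true` of
the way toward the boundary along a seeded random direction in the xy
mid-plane, constrained inside the nucleus via the conservative inner
ellipsoid (semi-axes reduced by the sphere radius); placements that cannot
fit raise an error naming the constraint. Presets `"wt-like"`
(f = 0.125, r = 0.6) and `"decondensed-like"` (f = 0.20, r = 0.3) mirror
the reported ranges of compact versus decondensed X territories —
conveniences, not claims. An `irregular` mode perturbs the sphere boundary
with smoothed noise for robustness checks; it trades exact volume control
for shape realism.

What the generator does *not* emulate: optics (no PSF, no photobleaching),
multi-nucleus fields, chromatin texture, or germline/soma differences.
Passing tests therefore demonstrate correctness of the measurement
pipeline on well-posed inputs, not robustness to every real-world imaging
artifact.

`generate_count_matrix()` draws per-gene baseline means from a log-normal
(meanlog = log 100, sdlog = 1), applies a uniform multiplicative shift
`2^d_true` to X-linked genes in the treatment group, and samples
negative-binomial counts (dispersion 0.05; Poisson when 0) scaled by
per-sample library factors (log-uniform in [0.7, 1.4] by default — enough
to exercise normalization without dominating it). The default design is
20,000 genes (2,800 on X, 14%) by 3 + 3 replicates.
`generate_viability_table()` draws per-stage binomial deaths so that
`laid = dead embryos + dead larvae + adults` holds by construction.

# Expression statistics

The real-data entry point is a log2 fold-change table from any upstream
differential-expression tool (`read_dge_table()`); the synthetic path
closes the loop with a deliberately minimal estimator: median-of-ratios
size factors and `log2((mean_trt + 1)/(mean_ctrl + 1))` on normalized
means. Two properties of that loop are worth knowing. First, a
chromosome-wide shift on 14% of genes inflates median-of-ratios factors
for the shifted samples by a few percent, depressing all log2FCs — the
derepression statistic is immune because a common shift cancels in the
X − A contrast (an argument for difference statistics generally). Second,
the pseudocount shrinks low-expression genes toward zero; medians over
thousands of genes are hardly moved, but per-bin means of coordinate
profiles are, which is why `chromosome_profile()` is tested with true
library factors and wide bins.

The Wilcoxon rank-sum test uses mid-ranks, exact enumeration for combined
sizes ≤ 12 without ties, and otherwise a normal approximation with tie
correction, continuity correction, and a one-term Edgeworth correction
using the exact excess kurtosis of the null rank-sum distribution,
`γ₂ = −6/5 · (m² + n² + mn + m + n) / (mn(N+1))` (verified against full
enumeration). The plain normal approximation errs by up to 0.022 against
exact enumeration at N = 12; the Edgeworth term brings every case with
both groups ≥ 3 under 0.02. For groups of one or two the exact two-sided
p-value takes only a handful of coarse values (e.g. 0.5 and 1 at 1 vs 3)
that no continuous approximation can reproduce — those sizes always take
the exact path. Two-sided p-values throughout; the derepression medians
use the mean-of-central-pair convention for even n, and genes on
chromosomes outside I–V/X are dropped with a message rather than an error.
An optional `min_base_mean` filter restricts the statistic to expressed
genes; the default uses all genes with finite log2FC.

# Viability statistics

Dead embryos and dead larvae are pooled into one "dead" category against
surviving adults; replicate rows are summed before testing, matching the
pooled-count reporting convention of egg-laying assays. Fisher's exact
test is two-sided by the point-probability rule (summing hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed the observed one, with a `1 + 1e-7` relative tolerance on
that comparison to absorb floating-point ties); it agrees with
`stats::fisher.test` to ~1e-15 over every 2×2 table with total ≤ 40. The
chi-square comparison delegates to `stats::chisq.test` without continuity
correction — the variant is not standardized across publications, so a
`correct` flag enables Yates' correction. Survival ratios
(on-auxin / off-auxin survivors) and brood metrics (hatched/laid,
adults/hatched) are simple ratios with explicit flags for undefined cases.

# Numerical conventions

* Axis order is `(z, y, x)` everywhere; geometry is computed in µm and
  voxelized by center-point test; all 2D work is in pixel units.
* The volume fraction counts voxels, not µm³ — grid anisotropy biases
  numerator and denominator identically, so the ratio is spacing-free.
* TIFF stacks are written as 32-bit float pages in units of 1/65535 (TIFF
  float storage is defined on [0, 1]); masks as 8-bit. Integer microscope
  TIFFs are read as raw counts.
* All generators are bit-reproducible given `(params, seed)`, restoring
  the caller's RNG state afterwards.
* Problem sizes used by the validation suite: 20 nuclei per preset for
  volume recovery, 8 seeds per radial position for the zone monotonicity,
  10 simulation seeds per effect size and 100 under the null for the
  derepression statistics.

# Known limitations

Segmentation is global-threshold based and assumes one nucleus per field
with clear foreground/background separation; dim or touching nuclei need
upstream cropping. The enrichment ratio depends on line placement when
enrichment is weak; the deterministic fallback removes run-to-run
variance but not that sensitivity. The internal fold-change estimator is
for synthetic data only and does not replace a dispersion-modelling DE
tool on real counts. The three-zone assay reads a single slice, as in the
original protocol; a fully volumetric radial profile is out of scope.
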