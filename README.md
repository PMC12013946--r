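# xquant

Quantitative analysis of X-chromosome dosage compensation phenotypes in
*C. elegans*: chromosome-territory compaction and radial nuclear position
from single-nucleus 3D image stacks, the X-vs-autosome derepression
statistic on differential-expression tables, and contingency-based
progeny-viability statistics — plus a synthetic-data generator with exact
ground truth so the whole pipeline is testable without microscopy or
sequencing data.

## Who this is for

Labs measuring the three signatures of a perturbed dosage compensation
complex (condensin I^DC):

* **Compaction.** From a two-channel stack (DNA stain + X-paint FISH or
  IF), the territory volume fraction
  `v = |X mask ∩ nucleus mask| / |nucleus mask|` counted in voxels, after
  rolling-ball background subtraction and Otsu segmentation. Compact
  wild-type X territories sit near v ≈ 0.12, decondensed ones near 0.20.
* **Radial position.** The three-zone assay: the in-focus mid-slice is
  partitioned into three concentric equal-area elliptical zones and the
  fraction of the signal in each zone is reported
  (central, intermediate, peripheral).
* **Derepression.** On a per-gene log2 fold-change table,
  `d = median(log2FC_X) − median(log2FC_autosome)`, its fold equivalent
  `2^d`, and a two-sided Wilcoxon rank-sum test of X vs autosomal log2FC
  sets (exact by enumeration for tiny samples, Edgeworth-corrected normal
  approximation otherwise).
* **Viability.** Fisher's exact test (point-probability rule) on pooled
  dead/live counts, chi-square for on/off-auxin survival ratios, and
  brood viability metrics.

Auxiliary metrics: line-scan enrichment ratio `E` (peak ÷ minimum along a
line through the enriched region) and normalized mean nuclear intensity
`I` (nuclear mean ÷ background mean).

## Worked example

Simulate an mRNA-seq experiment in which every X-linked gene is shifted up
by 2^0.435 in the treatment group, estimate fold changes, and compute the
derepression statistic:

```r
library(xquant)

sim <- generate_count_matrix(count_sim_params(d_true = 0.435, seed = 7))
tab <- log2_fold_changes(sim$counts, sim$groups, genes = sim$genes)
derepression(tab)
#> X derepression d = 0.4331 (1.35-fold), median X = 0.3748, median A = -0.0583
#> Wilcoxon rank-sum: W = 4.465e+07, two-sided p = 0 (n_X = 2800, n_A = 17200)
```

The estimate recovers the simulated shift (0.433 vs 0.435); `1.35-fold`
is its fold-change equivalent `2^d`. The medians are both offset by about
−0.06 — a normalization artifact of a chromosome-wide shift — which
cancels in the X − A contrast; that invariance is the point of the
statistic.

Simulate and quantify one wild-type-like nucleus (f_true = 0.125):

```r
s <- generate_nucleus_stack(image_sim_preset("wt-like", seed = 1))
quantify_nucleus(s$dapi, s$signal, nucleus_id = "wt_like_seed1")
#> <QuantResult 'wt_like_seed1'> v=0.1249  zones=(0.757, 0.243, 0.000)  E=4.401  I=6.875  slice=15  qc=pass
```

`v = 0.1249` recovers the simulated volume fraction; the zone fractions
say three quarters of the territory's mid-slice falls in the central
zone; `E` reflects the simulated 4× stain enrichment (plus noise);
`I = 6.875` equals the nuclear mean (137.5) over the background level
(20) exactly.

Viability comparison of a simulated mutant against wild type:

```r
tabv <- generate_viability_table(viability_sim_params(
  c("N2", "mut"), 600, p_embryonic = c(0.02, 0.5),
  p_larval = c(0.02, 0.1), seed = 1))
ct <- dead_live_table(as.list(tabv[2, ]), as.list(tabv[1, ]))
ct
#>     dead live
#> mut  327  273
#> N2    26  574
fisher_exact(ct)
#> [1] 4.392104e-91
```

A command-line wrapper over the same functions is in
`inst/scripts/xquant-cli.R` (subcommands `simulate-image`,
`simulate-counts`, `simulate-viability`, `quantify`, `derepress`,
`profile`, `viability`).

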