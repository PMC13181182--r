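# methblocks

Data-driven segmentation of whole-genome bisulfite sequencing (WGBS) data
into methylation blocks shared across a cohort of samples.

DNA methylation at CpG sites is spatially correlated and functions in
blocks — CpG islands, promoter and enhancer domains, repeats — yet most
segment-level analyses start from fixed windows or predefined annotations.
methblocks derives the blocks from the counts themselves: it finds a single
set of segment boundaries for the whole cohort while letting every sample
keep its own methylation level inside each segment, then labels segments
whose CpGs share one level per sample as *coherently methylated*. The output
is a natural unit for downstream work (differential methylation, variability
and entropy analyses, annotation enrichment).

## Method in brief

Methylated counts are binomial, $X_{ij} \sim \mathrm{Bin}(t_{ij}+c_{ij}, p_{ij})$,
with per-set pooled MLEs $\hat p_{S,j} = \sum_S c_{ij} / \sum_S (t_{ij}+c_{ij})$.
Adjacent clusters $A$, $B$ on a chromosome are merged agglomeratively by the
smallest

$$d(A,B) = \underbrace{-\log \hat L_{A\cup B} + \log \hat L_A + \log \hat L_B}_{\mathrm{nLLR}\;\ge\;0}
\;+\; \underbrace{-\log T\!\big(\delta(A,B)/100;\,1\big)}_{\text{Cauchy distance penalty}},$$

with $d = \infty$ across chromosomes ($T(x;1)$: Student-$t_1$ density,
$\delta$: genomic gap in bp). Cutting the per-chromosome merge tree at the
BIC-minimizing resolution ($-2\log\hat L + kn\log N_{\mathrm{obs}}$) yields
the segmentation; a likelihood-ratio test of "one rate per sample for the
whole segment" against per-site rates, referred to $\chi^2_{r-1}$, flags
coherent segments ($p > 0.05$). A synthetic-data module (piecewise-constant
rates, binomial sampling, graded mixture noise $p' = (1-w)p + w\varepsilon$,
$w = \eta/100$) plus breakpoint-recovery metrics with bootstrap CIs and a
Fisher/BH enrichment harness make the whole system testable end to end. See
`vignettes/methylation-segmentation.Rmd` for assumptions, parameter choices
and limitations.

## Worked example

```r
library(methblocks)

sim <- simulate_methylation(n_sites = 500, n_segments = 4, n_samples = 3, seed = 11)
seg <- segment_methylation(sim$data) |>
  test_coherence(sim$data, df_mode = "per_sample")
seg
#> <meth_segmentation> 4 segments over 500 CpG sites (1 chromosome(s))
#>   resolution: bic; total BIC 19777.03
#>   coherent segments: 4 of 4
tidy(seg)
#> # A tibble: 4 × 11
#>   segment_id chrom start   end length_bp n_cpgs first_site last_site
#> 1 seg_00001  chr1      1  2637      2637     34          1        34
#> 2 seg_00002  chr1   2696 17384     14689    150         35       184
#> 3 seg_00003  chr1  17431 25698      8268     66        185       250
#> 4 seg_00004  chr1  25816 49663     23848    250        251       500
#> # ℹ 3 more variables: mean_methylation, coherent, coherence_pvalue
```

The BIC cut recovers the four simulated blocks exactly (`first_site` /
`last_site` match the true boundaries at sites 34, 184 and 250), and all
four are coherent: within each block every sample's CpGs share one rate.
Robustness to noise:

```r
rob <- evaluate_noise_robustness(sim$data, sim$truth, eta_grid = c(20, 100),
                                 n_replicates = 5, master_seed = 11)
tidy(rob)[, c("eta", "sensitivity", "precision", "f1", "prop_gained")]
#>     eta sensitivity precision     f1 prop_gained
#> 1    20       1       0.79    0.871        0.25
#> 2   100       0.667   0.00565 0.0112       0.992
```

At 20% noise the true boundaries are still found (sensitivity 1); at 100%
noise every cell's rate is independent uniform noise, so the segmentation
shatters — 99% of predicted breakpoints are spurious. `autoplot()` methods
exist for segmentations, robustness curves and enrichment tables;
`write_segments_bed()` / `write_segment_summary()` / `write_segment_matrix()`
produce the standard file outputs.

A command-line wrapper ships in `exec/`:

```sh
methblocks segment --cov a.cov,b.cov --out run1      # BED + summary + matrix
methblocks simulate --out sim --eta 20,60,100 --replicates 10 --seed 7
methblocks evaluate --sim-dir sim --out sim/eval
methblocks enrich --summary run1.summary.tsv --bed promoters=prom.bed --out enr.tsv
```

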