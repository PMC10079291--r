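# crmkit

Post-alignment analysis of HDAC ChIP-seq experiments in early vertebrate
embryos: classification of bound cis-regulatory modules (CRMs) by
histone-mark context, spike-in (ChIP-Rx) normalized quantification of
pan-H3K acetylation changes between germ layers and HDAC-inhibited
conditions, and mapping of CRMs to temporally and spatially categorized
gene classes — with a synthetic-data generator providing known ground
truth in place of sequencing archives.

## Who this is for

Epigenomics groups analyzing deacetylase or acetylation ChIP-seq around
zygotic genome activation (ZGA), and anyone who needs the building blocks:
interval Venn partitions, nearest-gene assignment with deterministic
tie-breaks, spike-in scaling factors, strictly-zygotic expression filters,
germ-layer gene categorization, and the matching inferential toolkit.

## The model in brief

- **CRM partition.** With H3K27ac peak set $A$ and H3K27me3 peak set $M$,
  each CRM is labeled I ($\cap A, \cap M$), II (only $M$), III (only $A$)
  or IV (neither). Labels always partition the input.
- **Spike-in scaling.** With $n_i$ the spike-in reads of sample $i$ inside
  spike-in peaks and $n_\mathrm{ref} = \min_i n_i$, the factor
  $f_i = n_\mathrm{ref} / n_i$ multiplies raw coverage. Treatment effects
  are $\mathrm{FC}_r = \log_2\frac{t_r + c}{u_r + c}$ per region and
  $\bar\Delta = \mathrm{mean}_r\,\mathrm{FC}_r$ per CRM cluster.
- **Spatial categories.** AC CRM if AC signal $\ge 2\times$ VG signal,
  VG symmetrically, ubiquitous otherwise.
- **Gene classes.** Nearest gene within 10 kb per CRM; Class 1
  $= G(I) \cup (G(II) \cap G(III))$, Class 2 $= G(II) \setminus$ Class 1,
  Class 3 $= G(III) \setminus$ Class 1.
- **Filters.** Strictly zygotic: TPM $\le 1$ through 2 hpf and $\ge 1$ by
  23 hpf. Germ-layer category: NE if all collapsed layers $< 1$ TPM, NL if
  CV $< 0.1$ over (AC, mean-mesoderm, VG), else arg-max layer. DE cutoffs:
  $|\log_2 \mathrm{FC}| > 1$, FDR $< 0.05$, strict.
- **Statistics.** Welch t (two-sided), Cohen's d (pooled SD, $x - y$
  sign), one-sided Fisher exact for categorical enrichment, qPCR percent
  input $= 100 \cdot 2^{\mathrm{Ct}_\mathrm{input} - \log_2 D -
  \mathrm{Ct}_\mathrm{IP}}$ with quadrature error propagation.

## Worked example

```r
library(crmkit)

res <- run_pipeline(sim_config(seed = 1))
res
#> <crm_pipeline>
#>   2000 CRMs; 400 genes; 232 strictly zygotic
#>   clusters: I=300 II=120 III=1170 IV=410
#>   premature class-2 activation: 0.911

res$delta
#> # A tibble: 5 x 3
#>   group           n delta_bar
#>   <chr>       <int>     <dbl>
#> 1 cluster_I     300     1.67
#> 2 cluster_II    120     2.14
#> 3 cluster_III  1170     1.07
#> 4 cluster_IV    410     1.61
#> 5 random       2000    -0.722

score_simulation(res)
#> # A tibble: 6 x 4
#>   metric                         value     n pass
#> 1 crm_cluster_recovery           1      2000 TRUE
#> 2 crm_localization_recovery      1      2000 TRUE
#> 3 crm_spatial_recovery           0.985  1470 TRUE
#> 4 zygotic_set_recovery           1       400 TRUE
#> 5 gene_category_recovery         1       400 TRUE
#> 6 premature_activation_fraction  0.911    45 NA
```

Reading the numbers: every CRM recovered its planted histone-mark cluster
and localization label; 98.5% of the 1470 acetylated CRMs recovered their
planted AC/VG/ubiquitous category under 4-fold separation with lognormal
noise; the strictly zygotic gene set and germ-layer gene categories are
exact; and 91% of the 45 class-2 genes (planted activation probability
0.9) are called prematurely activated under HDAC inhibition. `delta_bar`
shows the spike-in normalized acetylation gain per cluster — repressive
CRMs (cluster II) gain the most, active CRMs (cluster III) the least —
with randomized regions far below every cluster.

Per-result plots: `plot_localization()`, `plot_class_trend()`,
`plot_fold_change()`, `plot_metagene()`, and `autoplot()` on summit
matrices; `tidy()`/`glance()` give broom-style accessors on pipeline
results.

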