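# stpheno

Spatiotemporal projection of bulk transcriptomes onto embryo reference
atlases, with a phenotypic difference index for comparing conditions.

## What problem this solves

In vitro differentiation experiments (for example, mouse embryonic stem
cells driven toward neuromesodermal progenitors and their spinal-cord /
presomitic-mesoderm derivatives) produce bulk RNA-seq samples whose
developmental identity is hard to state precisely. Given a spatially
resolved embryo reference atlas — position-indexed expression profiles such
as Geo-seq "corn plots" of the gastrula — stpheno answers two questions
quantitatively:

1. **Where and when in the embryo does each sample fit best?** Each bulk
   sample is correlated against every atlas position over a spatially
   informative feature gene set, using the Pearson correlation coefficient

   `PCC(X, Y) = Cov(X, Y) / (σX · σY)`

   on `log2(TPM + 1)` expression; the top-ranked positions are the inferred
   embryonic locations.

2. **How does a perturbation move that fit?** For a case/control pair
   (knockout vs wild type, treatment vs vehicle), the per-position
   **phenotypic difference index**

   `PDI = PCC_case − PCC_control  ∈ [−2, 2]`

   is computed within matched timepoints: 0 means no change in association
   strength with that position, positive values an enhanced resemblance in
   the case group, negative an attenuation.

The package also includes TPM normalization with exon-union gene lengths
derived from a GTF, a pseudo-bulk + top-50-marker Spearman module for
staging against single-cell references, corn-plot rendering of PCC/PDI
maps, a YAML-configured pipeline with a thin CLI (`exec/stpheno`), and a
ground-truthed synthetic atlas/bulk generator so everything is testable
without downloading a real atlas.

## Worked example

A synthetic six-domain study: wild-type replicates drawn from their origin
signatures, knockout replicates drifting halfway toward the adjacent
domain.

```r
library(stpheno)

study <- simulate_fate_shift_study(n_positions = 6, n_genes = 600,
                                   markers_per_position = 25, seed = 42)
pcc <- map_samples(study$bulk, study$atlas, study$features)
pcc
#> <pcc_map> 36 samples x 6 positions, 150 feature genes used (provenance: synthetic position markers)

head(rank_positions(pcc, k = 1), 3)
#> # A tibble: 3 × 4
#>   sample_id         rank position_id   pcc
#>   <chr>            <int> <chr>       <dbl>
#> 1 WT_T01_S1_P01_r1     1 S1_P01      0.937
#> 2 WT_T01_S1_P01_r2     1 S1_P01      0.944
#> 3 WT_T01_S1_P01_r3     1 S1_P01      0.930

pdi <- compute_pdi(pcc, study$groups, study$pairs)
round(pdi$pdi[, "KO_T01_vs_WT_T01"], 3)
#> S1_P01 S1_P02 S1_P03 S1_P04 S1_P05 S1_P06
#> -0.123  0.256  0.046  0.030  0.030  0.068

recovery_report(pcc, study$truth, pdi)
#> # A tibble: 1 × 4
#>   origin_recovery n_samples_scored sign_agreement n_comparisons_scored
#>             <dbl>            <int>          <dbl>                <int>
#> 1               1               18              1                    6
```

Reading the output: every wild-type replicate ranks its true origin first
(PCC ≈ 0.94 against its own domain, `origin_recovery = 1`), and in the T01
comparison the index is most positive at `S1_P02` — exactly the domain the
knockout population was simulated to drift toward — while the abandoned
origin `S1_P01` shows the attenuation (−0.123). `autoplot(pdi, study$atlas)`
draws the corresponding corn plot with a diverging palette centred at 0.

Real data enter the same way: `read_expression_table()` +
`counts_to_tpm()` + `log_transform()` for the bulk counts (gene lengths via
`gene_lengths_from_gtf()`), `read_atlas()` for the reference, and
`load_feature_set()` for the spatial-DEG list, or `run_pipeline()` with a
YAML configuration to do all of it and write TSVs, plots and a run log.

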