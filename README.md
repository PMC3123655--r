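# mirgrb

Genome-wide identification of microRNA loci under long-range developmental
regulation.

Developmental master genes sit inside *genomic regulatory blocks* (GRBs):
synteny-preserved regions where arrays of highly conserved non-coding
elements (HCNEs) act as long-range enhancers on one target gene. GRB target
genes carry recognizable hallmarks — a dense local HCNE field, large CpG
islands, and "bivalent" (H3K4me3 + H3K27me3) promoters in embryonic cell
types. `mirgrb` screens miRNA loci for the same hallmarks: it derives the
set of *self-transcribed* (ST) miRNAs that plausibly own a promoter,
measures enhancer density around them against matched random controls, maps
bivalent chromatin onto their promoter windows, and calls a locus a
putative GRB target when it is

* HCNE-enriched — top half of the density split, density being the percent
  of bases in HCNEs within a 300 kb window centered on the locus — in at
  least one lineage comparison, **and**
* associated (≥ 1 bp overlap) with a bivalent domain in its gene-truncated
  50 kb upstream promoter window in at least one developmental cell type.

Enrichment against controls is tested with a two-sided bootstrapped
two-sample Kolmogorov–Smirnov test (pooled resampling, tie-robust,
`p = #{D* ≥ D_obs}/nboot`); bivalent association rates between
enriched and poor loci with a one-sided Fisher exact test; CpG-to-gene
ratios with a one-sided Wilcoxon rank-sum test. Orthologs between miRNA
catalogs are called by reciprocal best hits under exact Smith–Waterman
local alignment with the field's precursor (≥ 56% aligned, ≤ 10 gap
columns) and mature (≥ 80% aligned, ≤ 3 mismatches, seed positions 2–8
conserved) filters.

The package is written for audit and reuse: every stage is an exported
function over plain interval tables (BED/GFF3/FASTA in, TSV out), every
stochastic step takes an explicit seed, and a synthetic-genome generator
plants ground-truth targets so the whole chain is testable offline.

## Worked example

```r
library(mirgrb)

bundle <- generate_bundle(simulation_config(seed = 101))
res <- run_pipeline(bundle, seed = 101)

res$enrichment[["human:mouse"]]
#> <enrichment_result> D = 0.1745, p_boot = 0.004 (nboot = 1000, n = 115 vs 11500)

res$contingency$table
#>          bivalent not_bivalent
#> enriched       15           40
#> poor            7           48

head(subset(res$predictions, predicted,
            c(locus_id, location_class, bivalent_cell_types, cgi_count)), 4)
#>      locus_id location_class bivalent_cell_types cgi_count
#> 1 hsa-mir-004     intergenic             hES,mES         2
#> 2 hsa-mir-005     intergenic                 mES         1
#> 3 hsa-mir-010     intergenic             hES,mES         1
#> 7 hsa-mir-018     intergenic             hES,mES         2

res$performance[c("precision", "recall")]
#> $precision
#> [1] 0.9411765
#> $recall
#> [1] 0.8
```

Reading: the ST miRNA loci sit in windows with significantly higher HCNE
density than length/context/gene-density-matched random regions (bootstrap
p = 0.004 against 100 pooled control sets); bivalent promoters concentrate
in the enriched half of the split (15/55 vs 7/55); and the predicted set
recovers most of the generator's 20 planted targets with few false calls.
(Numbers are from this exact seed; other seeds vary within the tested
precision/recall ≥ 0.7 envelope.)

The `analysis/` directory holds the same workflow as numbered narrative
scripts — `01_simulate.R` through `06_predict.R` — each a thin driver over
the package that prints what it found and writes its tables under
`results/`.

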