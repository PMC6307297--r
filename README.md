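# heartlnc

Identification and genomic-context classification of heart-expressed spliced
lncRNAs, with the statistics used to test whether cardiac genes carrying a
bidirectional (divergent-promoter) lncRNA are enriched among haploinsufficient
genes.

Dosage-sensitive cardiac transcription factors are frequently accompanied by a
long non-coding RNA transcribed head-to-head from the same promoter region.
This package reimplements that screen as a reproducible workflow: filter
assembled transcript models down to spliced, non-coding, heart-expressed,
tissue-selective candidates; classify each candidate as bidirectional
(divergent TSS within 3 kb), antisense (opposite-strand gene overlap), both, or
intergenic; compare TSS-to-nearest-gene distances and divergent-pair expression
correlation across development; and test the haploinsufficiency enrichment with
a housekeeping-gene confounder control. Because the original raw RNA-seq is not
deposited, the workflow runs on a planted-truth synthetic genome at the study's
scale, and all statistics are validated against independent oracles.

## Worked example

Generate a synthetic study (200 coding genes; 20 bidirectional, 20 antisense,
20 intergenic lncRNAs; 40 heart-selective) and run the full screen:

```r
library(heartlnc)

cfg <- simulation_config(seed = 1)
bundle <- simulate_bundle(cfg, "data/synthetic")
report <- run_pipeline(run_config(
  annotation_gtf = "data/synthetic/annotation.gtf",
  expression_tsv = "data/synthetic/expression.tsv",
  gene_labels_tsv = "data/synthetic/gene_labels.tsv",
  out_dir = "results"))
#> filter stages: input=270, spliced=260, non_coding=60, expressed=60, selective=40

report$class_counts
#> bidirectional     antisense          both    intergenic
#>            20            20             0            20

unlist(report$orientation)
#> opposite     same n_within
#>       40        0       40

report$distances$summary
#>                    group   n median_distance
#> 1                   mRNA 200         40599.5
#> 2             lncRNA_all  60          1338.5
#> 3 lncRNA_heart_selective  40          1469.0

report$distances$tests
#>                 comparison    U            p
#> 1       lncRNA_all_vs_mRNA 3999 9.002897e-05
#> 2 lncRNA_selective_vs_mRNA 2599 4.757848e-04

report$enrichment
#> hypergeometric enrichment: k=5 of n=25 vs K=20 of N=200; P(X>=k)=0.08398, OR=2.67
```

All 60 candidates are the planted lncRNAs with class labels and selectivity
flags recovered exactly; lncRNA TSSs sit far closer to coding genes than mRNAs
do, and all 40 proximal candidates run opposite to their neighbor. The
enrichment on this 200-gene toy genome is directionally right but underpowered;
at the study scale it is decisive:

```r
g <- simulate_enrichment_study(n_genes = 2000, hi_bidirectional_odds = 3, seed = 5001)
bidirectional_hi_enrichment(g)
#> hypergeometric enrichment: k=68 of n=205 vs K=300 of N=2000; P(X>=k)=2.979e-12, OR=3.34
```

The numbered drivers under `analysis/` (`01_simulate.R` … `06_assembly_qc.R`)
narrate the same study step by step and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_identify.R
# ...
```

Methods, parameter rationale, and the design of the synthetic generator are
documented in `vignettes/heart-lncrna-screen.Rmd`.

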