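#!/usr/bin/env Rscript
# Step 3 — genomic-context classification and distance statistics.
#
# Classifies each candidate relative to protein-coding genes: bidirectional
# (opposite-strand divergent TSS within 3 kb), antisense (opposite-strand
# gene-span overlap), both, or intergenic; tallies the 10 kb orientation
# census (opposite- vs same-strand neighbors); and compares TSS-to-nearest-
# expressed-coding-gene distances of lncRNA candidates against mRNAs by
# two-sided Mann-Whitney tests. Prints the tables written by step 2.

library(heartlnc)

report <- run_pipeline(run_config(
  annotation_gtf = "data/synthetic/annotation.gtf",
  expression_tsv = "data/synthetic/expression.tsv",
  gene_labels_tsv = "data/synthetic/gene_labels.tsv"))

cat("genomic-context classes:\n")
print(report$class_counts)
cat("\norientation census within 10 kb (opposite vs same strand):\n")
print(unlist(report$orientation))
cat("\nmedian TSS-to-nearest-coding-gene distances (bp):\n")
print(report$distances$summary)
cat("\nMann-Whitney distance comparisons:\n")
print(report$distances$tests)
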