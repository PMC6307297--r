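#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# The published screen was run on raw RNA-seq that is not deposited, so the
# workflow operates on a planted-truth synthetic genome at the study's scale:
# 200 protein-coding genes on two chromosomes and 60 spliced lncRNAs planted as
# 20 bidirectional (divergent TSS within 3 kb of a coding gene), 20 antisense
# (opposite-strand overlap of a coding gene) and 20 intergenic (>= 15 kb from
# any coding gene), with 40 of the 60 heart-selective. Writes
# data/synthetic/{annotation.gtf, expression.tsv, gene_labels.tsv, truth.json}.

library(heartlnc)

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
cfg <- simulation_config(seed = seed)
bundle <- simulate_bundle(cfg, "data/synthetic")
cat("wrote synthetic bundle (seed", seed, ") to data/synthetic:\n")
print(bundle$annotation)
cat("planted classes:\n")
print(table(bundle$truth$lnc$class))
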