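---
title: "Methods: screening and classifying heart-expressed lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and classifying heart-expressed lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartlnc)
```

## Scientific question

Developmental cardiac transcription factors are dosage-sensitive: losing one
functional copy is often enough to cause disease. One proposed layer of dosage
control is transcription of long non-coding RNAs (lncRNAs) from the same
promoter region in the opposite direction — *bidirectional* (divergent)
lncRNAs. This package reimplements, as a reproducible workflow, a screen of
that hypothesis: identify spliced, heart-expressed, tissue-selective lncRNA
candidates from assembled transcript models; classify each candidate's genomic
context relative to protein-coding genes; correlate divergent pairs across
developmental stages; and test whether genes carrying a bidirectional lncRNA
are over-represented among haploinsufficient genes.

The original raw sequencing data are not deposited, so the numeric results of
the published screen cannot be recomputed. The workflow therefore ships a
synthetic-data module that plants known truth at the study's scale, and every
statistical routine is validated against that planted truth and against
independent oracles. The `analysis/` directory contains numbered drivers
(`01_simulate.R` … `06_assembly_qc.R`) that narrate the full study; the
workflow is organized as these thin R drivers over the package API rather than
as a shell CLI, because every consumer of the pipeline here is an R session.

## Candidate identification

`run_pipeline()` applies the screen's filtering flowchart to a transcript GTF
and an fpkm matrix:

1. **Spliced** — keep transcripts with ≥ 2 exons (`min_exons = 2`). Single-exon
   models are the least reliable products of short-read assembly.
2. **Non-coding** — drop known mRNAs and functional RNAs by biotype, and drop
   any transcript whose annotated CDS exceeds one third of its length
   (`cds_fraction_max = 1/3`, strictly greater removes). The 1/3 rule is the
   screen's operational proxy for coding potential.
3. **Expressed** — require fpkm ≥ 1 (`min_fpkm = 1`, inclusive) in at least one
   heart-ventricle stage.
4. **Heart-selective** — additionally require fpkm < 1 in *every* brain sample.
   Kidney and liver expression is tallied as a census but does not filter.

Internally all coordinates are 0-based half-open; the GTF boundary converts
from/to 1-based inclusive. A transcript's TSS is its span start on `+` and its
span end on `-`.

## Genomic-context classification

Each candidate is classified against protein-coding genes
(`classify_genomic_context()`):

- **bidirectional** — some coding TSS lies within 3,000 bp
  (`bidirectional_window`) of the candidate TSS on the opposite strand, with
  the two transcripts diverging (head-to-head). Same-strand or convergent
  proximity never qualifies; a `same_strand_proximal` flag records the former
  for diagnostics.
- **antisense** — the candidate's span overlaps a coding gene's span (not
  exon-level) on the opposite strand by ≥ 1 bp, so intron-contained antisense
  transcripts qualify.
- **both** — a candidate meeting both definitions (e.g. divergent from one
  gene while overlapping another).
- **intergenic** — neither.

Distances from each candidate TSS to its nearest coding gene exclude the
candidate's own gene and, by default, restrict the neighbor pool to
ventricle-expressed genes (`expressed_neighbors_only = TRUE`), mirroring the
screen. Distance is 0 inside a gene span and otherwise the gap to the nearest
contained base. An open methodological question in the source analysis is
whether distances were measured to gene bodies or TSS-to-TSS;
`context_config(distance_mode = "tss")` switches to the alternative reading,
with `"gene_body"` as the default used everywhere in this package. A 10,000 bp
(`proximity_window`) orientation census counts candidates transcribed opposite
vs same strand relative to their nearest gene.

## Statistics

- **Distance comparisons** — two-sided Mann-Whitney tests of lncRNA vs mRNA
  TSS-to-nearest-gene distances (`mann_whitney()`); exact null for combined
  n ≤ 16 without ties, normal approximation with tie and continuity correction
  otherwise.
- **Divergent-pair correlation** — Pearson r of `log2(fpkm + 1)` across the
  three heart stages (`pair_correlation()`). The pseudocount of 1 keeps zeros
  finite while compressing sub-fpkm noise; replicates are averaged per stage
  and partner genes summed over isoforms first. With only three stages, r is a
  coarse but sign-faithful coupling measure.
- **Haploinsufficiency enrichment** — upper-tail hypergeometric probability
  (`bidirectional_hi_enrichment()`): population = all coding genes, successes =
  genes with a bidirectional lncRNA, sample = haploinsufficient genes. A
  two-sided Fisher test on housekeeping labels (`proportion_control()`) guards
  against the confounder that bidirectional promoters mark broadly expressed
  genes in general.
- **Gene-set enrichment** — per-term hypergeometric tails with
  Benjamini-Hochberg q-values (`gene_set_enrichment()`).
- **Localization** — `log10((intact + 0.01) / (nuclear + 0.01))`; the 0.01
  pseudocount bounds ratios for dropout measurements at ±4 orders of magnitude.

### Calibration of discrete p-values

Exact tests on discrete data have sub-uniform p-values under the null: the
p-value carries point masses, so its mean exceeds 0.5 and a
Kolmogorov–Smirnov test against Uniform(0,1) rejects a *correct*
implementation at well above the nominal rate. The package therefore exposes
the point-mass-smoothed probability integral transform
(`hypergeom_tail_pit()`, `fisher_two_sided_pit()`):
`P(p < p_obs) + U · P(p = p_obs)` with `U ~ Uniform(0,1)`, which is exactly
Uniform(0,1) if and only if the implementation's null distribution is correct.
`calibrate_null_enrichment()` runs repeated studies with planted independence
and returns raw p-values alongside their PITs; correctness is asserted as
(i) KS uniformity of the PITs and (ii) raw rejection rates at α = 0.05 within
binomial error. Raw p-values remain what the pipeline reports.

## Synthetic-data design

`simulate_annotation()` lays out coding genes on a fixed slot grid (50 kb
slots, genes 6–12 kb with 4–12 exons, CDS ≈ 70% of length) and plants each
lncRNA class with a *safety margin* from every decision boundary:

- bidirectional offsets are drawn from 100–2,700 bp. The window is 3,000 bp, so
  every planted TSS gap keeps ≥ 10% clearance from the boundary; that margin
  requirement is also why the upper offset stays at 2,700 rather than nearer
  the window.
- antisense lncRNAs sit inside their host span at the end away from the host
  TSS, keeping their own TSS ≥ 3,300 bp from any coding TSS so they can never
  leak into the bidirectional class.
- intergenic lncRNAs keep ≥ 15 kb from every coding gene (5× the window, and
  beyond the 10 kb census).

Expression keeps ≥ 50% margins around the fpkm = 1 threshold (selective
candidates: heart peak 1.5–8, brain 0.05–0.5). Coupled partners track the
lncRNA's log2 heart profile with strength 0.9 and lognormal noise (SD 0.2 in
log2). Haploinsufficiency labels multiply the odds of bidirectional-bearing
genes by `hi_bidirectional_odds` while solving the baseline numerically so the
marginal fraction is preserved; housekeeping labels are independent. Three
derived RNG sub-streams (placement / expression / labels, `derive_seeds()`)
make each layer reproducible in isolation. `simulate_truncated_assembly()`
generates the QC ground truth: exon losses Poisson-distributed with mean
`a · exp(-b · fpkm)`.

## Assembly-fidelity QC

`exon_fidelity_qc()` compares per-gene exon counts (maximum over alternative
transcripts) between an assembled and a reference annotation for genes with
≤ 12 reference exons, and fits `diff = a · exp(-b · fpkm)` by
Levenberg–Marquardt least squares. The single-exponential form is the simplest
monotone decay with an interpretable "intact above x fpkm" threshold
(`log(a/0.5)/b`); it is a summary curve, not a mechanistic model.

## Problem sizes and limitations

The reference study conditions (200 coding genes, 60 lncRNAs, 8 samples) run
in seconds; nearest-gene queries are index-backed (GenomicRanges) and validated
against exhaustive scans up to 10⁴ genes. Known limitations: coding potential
is taken from annotation (`cds_length`), not recomputed from sequence; the
three-stage correlation cannot distinguish co-regulation from shared trends;
the toy genome is underpowered for the enrichment contrast (power is
demonstrated on 2,000-gene label studies instead); and the synthetic margins
mean the recovery criteria certify correct thresholds and geometry, not
robustness to boundary-straddling real data.
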