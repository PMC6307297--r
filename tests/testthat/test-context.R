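# helper: candidate rows = transcript-table rows of the lnc gene
lnc_rows <- function(ann) {
  ann$transcripts[ann$transcripts$biotype == "lncRNA_candidate", , drop = FALSE]
}

test_that("bidirectional calls respect the 3000 bp divergent-TSS rule", {
  # coding gene [8000,12000) '+': TSS 8000. lnc '-' ending at 7500: TSS 7500,
  # gap 500, head-to-head -> bidirectional
  ann <- toy_annotation(lnc_exons = data.frame(start = c(6000, 7000),
                                               end = c(6500, 7500)),
                        lnc_strand = "-")
  out <- classify_genomic_context(lnc_rows(ann), ann)
  expect_equal(out$context, "bidirectional")
  expect_equal(out$bidirectional_partners, "pc1")

  # same geometry but lnc on '+': TSS 6000, gap 2000, but convergent -> not
  # bidirectional; flagged same-strand proximal
  ann2 <- toy_annotation(lnc_exons = data.frame(start = c(6000, 7000),
                                                end = c(6500, 7500)),
                         lnc_strand = "+")
  out2 <- classify_genomic_context(lnc_rows(ann2), ann2)
  expect_equal(out2$context, "intergenic")
  expect_true(out2$same_strand_proximal)

  # gap boundary: lnc '-' TSS at 5000 (gap exactly 3000) in, 4999 (3001) out
  ann3 <- toy_annotation(lnc_exons = data.frame(start = c(3000, 4500),
                                                end = c(3400, 5000)))
  expect_equal(classify_genomic_context(lnc_rows(ann3), ann3)$context,
               "bidirectional")
  ann4 <- toy_annotation(lnc_exons = data.frame(start = c(3000, 4500),
                                                end = c(3400, 4999)))
  expect_equal(classify_genomic_context(lnc_rows(ann4), ann4)$context,
               "intergenic")
})

test_that("antisense = opposite-strand gene-span overlap, even intron-only", {
  # coding gene exons [8000,9500) and [10000,12000) '+'; lnc entirely inside
  # the intron on '-', TSS 9990 (gap to gene TSS 1990 but convergent)
  ann <- toy_annotation(lnc_exons = data.frame(start = c(9550, 9800),
                                               end = c(9700, 9990)),
                        lnc_strand = "-")
  out <- classify_genomic_context(lnc_rows(ann), ann)
  expect_equal(out$context, "antisense")
  expect_equal(out$antisense_partners, "pc1")
  # same-strand overlap is NOT antisense
  ann2 <- toy_annotation(lnc_exons = data.frame(start = c(9550, 9800),
                                                end = c(9700, 9990)),
                         lnc_strand = "+")
  expect_equal(classify_genomic_context(lnc_rows(ann2), ann2)$context,
               "intergenic")
})

test_that("a divergent lncRNA overlapping another gene is labeled 'both'", {
  # two coding genes: pc1 [8000,12000)+ as before; pcB [2000,4800) on '+'.
  # lnc '-' spans [3000,5000): overlaps pcB (opposite strand) and its TSS 5000
  # is divergent to pc1's TSS 8000 at the default window.
  base <- toy_annotation()  # lnc [3000,5000) '-'
  tx <- rbind(base$transcripts[, c("transcript_id", "gene_id", "biotype",
                                   "cds_length")],
              data.frame(transcript_id = "pcB.t1", gene_id = "pcB",
                         biotype = "protein_coding", cds_length = 1000L))
  ex <- rbind(base$exons,
              data.frame(transcript_id = "pcB.t1", chrom = "chr1",
                         start = 2000L, end = 4800L, strand = "+"))
  ann <- genome_annotation(tx, ex)
  out <- classify_genomic_context(lnc_rows(ann), ann)
  expect_true(out$is_bidirectional)
  expect_true(out$is_antisense)
  expect_equal(out$context, "both")
  expect_equal(out$bidirectional_partners, "pc1")
  expect_equal(out$antisense_partners, "pcB")
})

test_that("planted genomic-context classes are recovered exactly", {
  cfg <- simulation_config(seed = 21)
  sim <- simulate_annotation(cfg)
  cand <- lnc_rows(sim$annotation)
  out <- classify_genomic_context(cand, sim$annotation)
  truth <- sim$truth$lnc
  m <- match(out$transcript_id, truth$transcript_id)
  expect_equal(out$context, truth$class[m])
  # bidirectional partner gene matches the planted partner
  bid <- out$is_bidirectional
  expect_equal(out$bidirectional_partners[bid],
               truth$partner_gene_id[m][bid])
})

test_that("widening the window only adds bidirectional calls", {
  cfg <- simulation_config(seed = 22)
  sim <- simulate_annotation(cfg)
  cand <- lnc_rows(sim$annotation)
  small <- classify_genomic_context(cand, sim$annotation,
                                    context_config(bidirectional_window = 1000))
  big <- classify_genomic_context(cand, sim$annotation,
                                  context_config(bidirectional_window = 5000))
  expect_true(all(small$is_bidirectional <= big$is_bidirectional))
})

test_that("classification is invariant under mirror reflection of the genome", {
  cfg <- simulation_config(seed = 23)
  sim <- simulate_annotation(cfg)
  out <- classify_genomic_context(lnc_rows(sim$annotation), sim$annotation)
  mirrored <- mirror_annotation(sim$annotation)
  out_m <- classify_genomic_context(lnc_rows(mirrored), mirrored)
  m <- match(out$transcript_id, out_m$transcript_id)
  expect_equal(out$context, out_m$context[m])
})

test_that("orientation census applies the 10 kb window with strand tallies", {
  # opposite-strand lnc with 500 bp gap counts as opposite
  ann <- toy_annotation(lnc_exons = data.frame(start = c(6000, 7000),
                                               end = c(6500, 7500)),
                        lnc_strand = "-")
  cen <- orientation_census(lnc_rows(ann), ann)
  expect_equal(cen$n_within, 1L)
  expect_equal(cen$opposite, 1L)
  expect_equal(cen$same, 0L)
  # a lnc 15 kb away is outside the window
  ann2 <- toy_annotation(lnc_exons = data.frame(start = c(25000, 26000),
                                                end = c(25500, 27000)),
                         lnc_strand = "-")
  cen2 <- orientation_census(lnc_rows(ann2), ann2)
  expect_equal(cen2$n_within, 0L)
  # census tallies agree with a direct per-candidate oracle on simulated data
  cfg <- simulation_config(seed = 24)
  sim <- simulate_annotation(cfg)
  cand <- lnc_rows(sim$annotation)
  cen3 <- orientation_census(cand, sim$annotation)
  opp <- 0L; same <- 0L
  for (i in seq_len(nrow(cand))) {
    o <- oracle_nearest(sim$annotation, cand$chrom[i], cand$tss[i],
                        exclude_gene = cand$gene_id[i])
    if (is.na(o$distance) || o$distance > 10000) next
    gs <- sim$annotation$genes$strand[sim$annotation$genes$gene_id == o$gene_id]
    if (gs != cand$strand[i]) opp <- opp + 1L else same <- same + 1L
  }
  expect_equal(cen3$opposite, opp)
  expect_equal(cen3$same, same)
})

test_that("unexpressed neighbors are skipped when the pool is expression-gated", {
  # expressed gene [8000,12000), unexpressed gene [5500,6000); query TSS 5000
  base <- toy_annotation()
  tx <- rbind(base$transcripts[, c("transcript_id", "gene_id", "biotype",
                                   "cds_length")],
              data.frame(transcript_id = "pcU.t1", gene_id = "pcU",
                         biotype = "protein_coding", cds_length = 300L))
  ex <- rbind(base$exons,
              data.frame(transcript_id = "pcU.t1", chrom = "chr1",
                         start = 5500L, end = 6000L, strand = "+"))
  ann <- genome_annotation(tx, ex)
  mat <- toy_matrix(c("pc1.t1", "pcU.t1", "lnc1.t1"),
                    heart = list(c(9, 9, 9), c(0.2, 0.2, 0.2), c(4, 4, 4)))
  cand <- lnc_rows(ann)
  cand$tss <- 5000L  # place the query TSS between the two genes
  d <- compute_nearest_distances(cand, ann, mat,
                                 context_config(expressed_neighbors_only = TRUE))
  expect_equal(d$nearest_gene, "pc1")
  expect_equal(d$nearest_distance, 3000)
  d2 <- compute_nearest_distances(cand, ann, mat,
                                  context_config(expressed_neighbors_only = FALSE))
  expect_equal(d2$nearest_gene, "pcU")
  expect_equal(d2$nearest_distance, 500)
})

test_that("genes_with_bidirectional reduces candidate calls to gene level", {
  cfg <- simulation_config(seed = 25)
  sim <- simulate_annotation(cfg)
  out <- classify_genomic_context(lnc_rows(sim$annotation), sim$annotation)
  gb <- genes_with_bidirectional(out, sim$annotation)
  truth_genes <- sim$truth$genes
  m <- match(gb$gene_id, truth_genes$gene_id)
  expect_equal(gb$has_bidirectional, truth_genes$has_bidirectional[m])
})
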