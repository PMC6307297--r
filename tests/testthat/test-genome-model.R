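test_that("GTF I/O converts 1-based inclusive to 0-based half-open and back", {
  gtf <- c(
    "##format: gtf",
    paste("chr1", "src", "transcript", "101", "200", ".", "+", ".",
          'gene_id "gA"; transcript_id "tA"; transcript_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "src", "exon", "101", "140", ".", "+", ".",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"),
    paste("chr1", "src", "exon", "161", "200", ".", "+", ".",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"),
    paste("chr1", "src", "CDS", "111", "130", ".", "+", ".",
          'gene_id "gA"; transcript_id "tA";', sep = "\t"))
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  ann <- read_gtf(path)
  tx <- ann$transcripts
  expect_equal(tx$start, 100L)        # internal 0-based start
  expect_equal(tx$end, 200L)          # internal half-open end
  expect_equal(tx$n_exons, 2L)
  expect_equal(tx$tx_length, 80L)
  expect_equal(tx$cds_length, 20L)    # CDS lengths sum across blocks
  expect_equal(tx$tss, 100L)          # '+' strand: TSS = span start
  # write back out: 1-based inclusive coordinates restored
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  fields <- strsplit(grep("\texon\t", readLines(out), value = TRUE), "\t")
  starts <- sort(as.integer(vapply(fields, `[[`, "", 4)))
  ends <- sort(as.integer(vapply(fields, `[[`, "", 5)))
  expect_equal(starts, c(101L, 161L))
  expect_equal(ends, c(140L, 200L))
})

test_that("TSS convention follows strand", {
  plus <- toy_annotation(lnc_strand = "+")
  minus <- toy_annotation(lnc_strand = "-")
  # lnc span is [3000, 5000)
  expect_equal(plus$transcripts$tss[plus$transcripts$gene_id == "lnc1"], 3000L)
  expect_equal(minus$transcripts$tss[minus$transcripts$gene_id == "lnc1"], 5000L)
})

test_that("malformed GTF lines are rejected with the line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("##format: gtf",
               "chr1\tsrc\texon\t1\t100\t.\t+\t.",  # 8 fields only
               ""), path)
  expect_error(read_gtf(path), "malformed GTF line 2")

  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", "1", "100", ".", "?", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), path2)
  expect_error(read_gtf(path2), "unknown strand symbol")
  expect_error(read_gtf(path2), "GTF line 1")
})

test_that("constructor validates structural invariants", {
  tx <- data.frame(transcript_id = "t1", gene_id = "g1",
                   biotype = "protein_coding", cds_length = 0L)
  # overlapping exons
  ex_bad <- data.frame(transcript_id = "t1", chrom = "chr1",
                       start = c(0L, 50L), end = c(100L, 150L), strand = "+")
  expect_error(genome_annotation(tx, ex_bad), "overlapping exons")
  # start >= end
  ex_bad2 <- data.frame(transcript_id = "t1", chrom = "chr1",
                        start = 100L, end = 100L, strand = "+")
  expect_error(genome_annotation(tx, ex_bad2), "start < end")
  # cds longer than transcript
  tx2 <- transform(tx, cds_length = 500L)
  ex <- data.frame(transcript_id = "t1", chrom = "chr1",
                   start = 0L, end = 100L, strand = "+")
  expect_error(genome_annotation(tx2, ex), "cds_length")
  # unknown biotype
  tx3 <- transform(tx, biotype = "martian")
  expect_error(genome_annotation(tx3, ex), "unknown biotype")
})

test_that("GTF round-trip on a simulated annotation is the identity", {
  sim <- simulate_annotation(simulation_config(seed = 3))
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, p1)
  back <- read_gtf(p1)
  cols <- c("transcript_id", "gene_id", "biotype", "cds_length", "chrom",
            "start", "end", "strand", "n_exons", "tx_length", "tss")
  expect_equal(back$transcripts[, cols], sim$annotation$transcripts[, cols])
  expect_equal(back$exons, sim$annotation$exons)
  expect_equal(back$genes, sim$annotation$genes)
  # and a second write is byte-identical
  write_gtf(back, p2)
  expect_identical(readLines(p2), readLines(p1))
})

test_that("dist_point_span implements the stated convention", {
  # span [8000, 12000): inside -> 0; left gap; right gap counts from last base
  expect_equal(dist_point_span(5000, 8000, 12000), 3000)
  expect_equal(dist_point_span(8000, 8000, 12000), 0)
  expect_equal(dist_point_span(11999, 8000, 12000), 0)
  expect_equal(dist_point_span(12000, 8000, 12000), 1)
  expect_equal(dist_point_span(12500, 8000, 12000), 501)
})

test_that("nearest_gene_query matches worked examples and the NA sentinel", {
  ann <- toy_annotation()
  r <- nearest_gene_query(ann, "chr1", 5000, biotype = "protein_coding")
  expect_equal(r$gene_id, "pc1")
  expect_equal(r$distance, 3000)
  # containment
  r2 <- nearest_gene_query(ann, "chr1", 9000, biotype = "protein_coding")
  expect_equal(r2$distance, 0)
  # excluding the only qualifying gene leaves nothing
  r3 <- nearest_gene_query(ann, "chr1", 5000, biotype = "protein_coding",
                           exclude_gene = "pc1")
  expect_true(is.na(r3$gene_id))
  expect_true(is.na(r3$distance))
  # unknown chromosome
  r4 <- nearest_gene_query(ann, "chrUn", 5000)
  expect_true(is.na(r4$gene_id))
})

test_that("indexed nearest-gene queries equal the exhaustive scan", {
  ann <- random_annotation(300, seed = 42)
  set.seed(99)
  chroms <- paste0("chr", sample.int(5, 400, replace = TRUE))
  pos <- sample.int(1e7, 400)
  got <- nearest_gene_table(ann, chroms, pos,
                            pool = ann$genes$biotype == "protein_coding")
  for (i in seq_len(400)) {
    want <- oracle_nearest(ann, chroms[i], pos[i])
    expect_equal(got$distance[i], want$distance)
    expect_equal(got$gene_id[i], want$gene_id)
  }
})

test_that("nearest-gene exclusion matches the oracle", {
  ann <- random_annotation(150, n_chroms = 2, seed = 7)
  set.seed(7)
  idx <- sample.int(nrow(ann$genes), 60)
  chrom <- ann$genes$chrom[idx]
  # query right at gene starts so the excluded gene would otherwise win
  pos <- ann$genes$start[idx]
  excl <- ann$genes$gene_id[idx]
  got <- nearest_gene_table(ann, chrom, pos, exclude_gene = excl)
  for (i in seq_along(idx)) {
    want <- oracle_nearest(ann, chrom[i], pos[i], exclude_gene = excl[i])
    expect_equal(got$distance[i], want$distance)
    expect_equal(got$gene_id[i], want$gene_id)
    expect_false(identical(got$gene_id[i], excl[i]))
  }
})
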