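# Independent oracles and small fixture builders used across the suite.

# exhaustive-scan nearest-gene oracle (plain arithmetic, no interval index)
oracle_nearest <- function(ann, chrom, pos, biotype = "protein_coding",
                           exclude_gene = NULL) {
  g <- ann$genes
  g <- g[g$chrom == chrom & g$biotype %in% biotype, , drop = FALSE]
  if (!is.null(exclude_gene)) g <- g[g$gene_id != exclude_gene, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(gene_id = NA_character_, distance = NA_integer_))
  d <- ifelse(pos < g$start, g$start - pos,
              ifelse(pos >= g$end, pos - g$end + 1L, 0L))
  j <- order(d, g$gene_id)[1]
  list(gene_id = g$gene_id[j], distance = d[j])
}

# full-labeling enumeration of the two-sided exact Mann-Whitney p (no ties)
enum_mw_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  combos <- utils::combn(length(x), n1)
  u_of <- function(g1, g2) sum(outer(g1, g2, ">"))
  u_obs <- u_of(a, b)
  us <- apply(combos, 2, function(idx) u_of(x[idx], x[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# independent Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# log-space combinatorial summation of the upper hypergeometric tail
hyper_tail_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (N - K))]
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# random single-isoform protein-coding annotation for index tests
random_annotation <- function(n_genes, n_chroms = 5, chrom_len = 1e7,
                              seed = 1) {
  set.seed(seed)
  gid <- sprintf("g%05d", seq_len(n_genes))
  start <- sample.int(chrom_len - 20000L, n_genes)
  len <- sample(500:10000, n_genes, replace = TRUE)
  genome_annotation(
    data.frame(transcript_id = paste0(gid, ".t1"), gene_id = gid,
               biotype = "protein_coding", cds_length = 0L,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = paste0(gid, ".t1"),
               chrom = paste0("chr", sample.int(n_chroms, n_genes, replace = TRUE)),
               start = start, end = start + len,
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               stringsAsFactors = FALSE))
}

# minimal hand-built annotation: one coding gene [8000,12000)+ and one spliced
# lncRNA; handy for boundary tests
toy_annotation <- function(lnc_exons = data.frame(start = c(3000, 4500),
                                                  end = c(3400, 5000)),
                           lnc_strand = "-",
                           lnc_biotype = "lncRNA_candidate",
                           lnc_cds = 0L) {
  genome_annotation(
    data.frame(transcript_id = c("pc1.t1", "lnc1.t1"),
               gene_id = c("pc1", "lnc1"),
               biotype = c("protein_coding", lnc_biotype),
               cds_length = c(3000L, lnc_cds), stringsAsFactors = FALSE),
    rbind(
      data.frame(transcript_id = "pc1.t1", chrom = "chr1",
                 start = c(8000L, 10000L), end = c(9500L, 12000L),
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(transcript_id = "lnc1.t1", chrom = "chr1",
                 start = lnc_exons$start, end = lnc_exons$end,
                 strand = lnc_strand, stringsAsFactors = FALSE)))
}

# expression matrix over the standard 8-sample grid with given per-tissue fpkm
toy_matrix <- function(ids, heart, brain = 0.1, kidney = 0.1, liver = 0.1) {
  stages <- c("E10.5", "E13.5", "adult")
  heart <- matrix(rep_len(unlist(heart), 3 * length(ids)), ncol = 3, byrow = TRUE)
  v <- cbind(heart,
             matrix(rep_len(brain, 3 * length(ids)), ncol = 3),
             rep_len(kidney, length(ids)), rep_len(liver, length(ids)))
  dimnames(v) <- list(ids, c(paste0("heart_", stages), paste0("brain_", stages),
                             "kidney_adult", "liver_adult"))
  expr_matrix(v)
}

# mirror-reflect an annotation: flip every strand and reflect coordinates
# about a fixed length L, preserving all relative geometry (for the
# strand-symmetry property)
mirror_annotation <- function(ann, L = max(ann$exons$end) + 1000L) {
  ex <- ann$exons
  new_start <- L - ex$end
  ex$end <- L - ex$start
  ex$start <- new_start
  ex$strand <- ifelse(ex$strand == "+", "-", "+")
  genome_annotation(ann$transcripts[, c("transcript_id", "gene_id", "biotype",
                                        "cds_length")], ex)
}
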