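# Domain types and GTF I/O for transcript/gene models.
#
# Internal coordinate convention: 0-based half-open intervals [start, end).
# GTF files are 1-based inclusive; conversion happens only at the I/O boundary.
# A transcript's TSS is span start on '+' and span end on '-' (so in GTF terms
# the TSS equals column 4 - 1 on '+' and column 5 on '-').

VALID_BIOTYPES <- c("protein_coding", "lncRNA_candidate", "snoRNA", "tRNA", "other_nc")

#' Build a genome annotation from transcript and exon tables
#'
#' Assembles the package's central annotation container: transcripts grouped
#' into genes, with gene spans taken as the union envelope of their isoforms,
#' one TSS retained per distinct transcript start, and `GRanges`-backed
#' interval indices over gene spans and TSS points for nearest/overlap queries.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype` (one of `r paste(VALID_BIOTYPES, collapse=", ")`), and
#'   `cds_length` (total CDS nucleotides; 0 for non-coding).
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`+` or `-`). Exons of one transcript
#'   must be non-overlapping and share chrom/strand.
#' @return An object of class `genome_annotation`: a list with elements
#'   `transcripts` (per-transcript table incl. derived span, `n_exons`,
#'   `tx_length`, `tss`), `exons`, `genes` (per-gene union spans), `tss`
#'   (one row per distinct transcript start) and internal indices.
#' @export
genome_annotation <- function(transcripts, exons) {
  req_tx <- c("transcript_id", "gene_id", "biotype", "cds_length")
  req_ex <- c("transcript_id", "chrom", "start", "end", "strand")
  stopifnot(all(req_tx %in% names(transcripts)), all(req_ex %in% names(exons)))
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  bad_bt <- setdiff(unique(transcripts$biotype), VALID_BIOTYPES)
  if (length(bad_bt) > 0)
    stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
  if (any(!exons$strand %in% c("+", "-")))
    stop("validation error: exon strand must be '+' or '-'")
  if (any(exons$start < 0) || any(exons$start >= exons$end))
    stop("validation error: exon intervals must satisfy 0 <= start < end")
  if (any(!exons$transcript_id %in% transcripts$transcript_id))
    stop("validation error: exon references unknown transcript_id")

  # order exons within transcript, check non-overlap and chrom/strand unity
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (ii in sp) {
    if (length(unique(exons$chrom[ii])) > 1 || length(unique(exons$strand[ii])) > 1)
      stop("validation error: exons of one transcript span multiple chroms/strands")
    if (length(ii) > 1 && any(exons$start[ii][-1] < exons$end[ii][-length(ii)]))
      stop("validation error: overlapping exons within transcript ",
           exons$transcript_id[ii][1])
  }

  first_ex <- exons[!duplicated(exons$transcript_id), c("transcript_id", "chrom", "strand")]
  agg_min <- tapply(exons$start, exons$transcript_id, min)
  agg_max <- tapply(exons$end, exons$transcript_id, max)
  agg_n <- tapply(exons$start, exons$transcript_id, length)
  agg_len <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  key <- transcripts$transcript_id
  if (any(duplicated(key))) stop("validation error: duplicated transcript_id")
  m <- match(key, first_ex$transcript_id)
  if (anyNA(m)) stop("validation error: transcript without exons: ",
                     paste(key[is.na(m)], collapse = ", "))
  transcripts$chrom <- first_ex$chrom[m]
  transcripts$strand <- first_ex$strand[m]
  transcripts$start <- as.integer(agg_min[key])
  transcripts$end <- as.integer(agg_max[key])
  transcripts$n_exons <- as.integer(agg_n[key])
  transcripts$tx_length <- as.integer(agg_len[key])
  transcripts$cds_length <- as.integer(transcripts$cds_length)
  if (any(transcripts$cds_length < 0) ||
      any(transcripts$cds_length > transcripts$tx_length))
    stop("validation error: cds_length must lie in [0, transcript_length]")
  transcripts$tss <- ifelse(transcripts$strand == "+", transcripts$start, transcripts$end)

  # genes: union envelope over isoforms; single chrom/strand per gene
  gsp <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
  for (ii in gsp) {
    if (length(unique(transcripts$chrom[ii])) > 1 ||
        length(unique(transcripts$strand[ii])) > 1)
      stop("validation error: transcripts of gene ",
           transcripts$gene_id[ii][1], " disagree on chrom/strand")
    if (length(unique(transcripts$biotype[ii])) > 1)
      stop("validation error: transcripts of gene ",
           transcripts$gene_id[ii][1], " disagree on biotype")
  }
  gid <- names(gsp)
  genes <- data.frame(
    gene_id = gid,
    biotype = vapply(gsp, function(i) transcripts$biotype[i[1]], ""),
    chrom = vapply(gsp, function(i) transcripts$chrom[i[1]], ""),
    start = vapply(gsp, function(i) min(transcripts$start[i]), 0L),
    end = vapply(gsp, function(i) max(transcripts$end[i]), 0L),
    strand = vapply(gsp, function(i) transcripts$strand[i[1]], ""),
    n_transcripts = lengths(gsp),
    stringsAsFactors = FALSE, row.names = NULL
  )

  ord <- order(transcripts$chrom, transcripts$start, transcripts$gene_id,
               transcripts$transcript_id)
  transcripts <- transcripts[ord, , drop = FALSE]
  rownames(transcripts) <- NULL
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # one TSS per distinct transcript start within a gene
  tss <- unique(transcripts[, c("gene_id", "chrom", "tss", "strand", "biotype")])
  rownames(tss) <- NULL

  ann <- list(transcripts = transcripts, exons = exons, genes = genes, tss = tss)
  ann$gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = "*"
  )
  names(ann$gr_genes) <- genes$gene_id
  S4Vectors::mcols(ann$gr_genes)$gene_strand <- genes$strand
  S4Vectors::mcols(ann$gr_genes)$biotype <- genes$biotype
  ann$gr_tss <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$tss + 1L, width = 1L),
    strand = "*"
  )
  S4Vectors::mcols(ann$gr_tss)$gene_id <- tss$gene_id
  S4Vectors::mcols(ann$gr_tss)$gene_strand <- tss$strand
  S4Vectors::mcols(ann$gr_tss)$biotype <- tss$biotype
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$transcripts), length(unique(x$genes$chrom))))
  bt <- table(x$genes$biotype)
  cat("  gene biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

empty_annotation <- function() {
  genome_annotation(
    data.frame(transcript_id = character(), gene_id = character(),
               biotype = character(), cds_length = integer()),
    data.frame(transcript_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  )
}

#' Read a GTF file into a genome annotation
#'
#' Reads Ensembl-dialect GTF (`gene_id`/`transcript_id` quoted attributes,
#' 1-based inclusive coordinates). Exon records define transcript structure;
#' CDS records are summed into `cds_length`. Biotype is taken from a
#' `transcript_biotype` (or `gene_biotype`) attribute when present; transcripts
#' without one (e.g. novel assembled models) default to `lncRNA_candidate`.
#'
#' @param path GTF file path.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) return(empty_annotation())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    stop(sprintf("parse error: malformed GTF line %d: expected 9 tab-separated fields, found %d",
                 body[i], nf[i]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  strand <- vapply(fields, `[[`, "", 7L)
  bad <- which(feat %in% c("exon", "CDS", "transcript") & !strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop(sprintf("validation error: unknown strand symbol '%s' at GTF line %d",
                 strand[bad[1]], body[bad[1]]))

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    gene_id = as.character(mc$gene_id),
    transcript_id = if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  bt <- rep(NA_character_, nrow(df))
  if ("transcript_biotype" %in% names(mc)) bt <- as.character(mc$transcript_biotype)
  if ("gene_biotype" %in% names(mc)) bt <- ifelse(is.na(bt), as.character(mc$gene_biotype), bt)
  df$biotype <- bt

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) return(empty_annotation())
  if (anyNA(ex$transcript_id)) stop("parse error: exon record without transcript_id")
  cds <- df[df$type == "CDS", , drop = FALSE]
  txf <- df[df$type == "transcript", , drop = FALSE]

  # exon-outside-declared-transcript validation (when transcript records exist)
  if (nrow(txf) > 0) {
    m <- match(ex$transcript_id, txf$transcript_id)
    has <- !is.na(m)
    if (any(has & (ex$start < txf$start[m] | ex$end > txf$end[m])))
      stop("validation error: exon outside declared transcript bounds for transcript ",
           ex$transcript_id[which(has & (ex$start < txf$start[m] | ex$end > txf$end[m]))[1]])
  }

  tx_ids <- unique(ex$transcript_id)
  cds_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  bt_by_tx <- tapply(df$biotype[!is.na(df$transcript_id)],
                     df$transcript_id[!is.na(df$transcript_id)],
                     function(x) if (all(is.na(x))) NA_character_ else x[!is.na(x)][1])
  gid_by_tx <- tapply(ex$gene_id, ex$transcript_id, `[[`, 1L)

  biotype <- unname(bt_by_tx[tx_ids])
  biotype[is.na(biotype)] <- "lncRNA_candidate"
  biotype[!biotype %in% VALID_BIOTYPES] <- "other_nc"
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = unname(gid_by_tx[tx_ids]),
    biotype = biotype,
    cds_length = as.integer(ifelse(is.na(cds_len[tx_ids]), 0L, cds_len[tx_ids])),
    stringsAsFactors = FALSE
  )
  genome_annotation(transcripts,
                    ex[, c("transcript_id", "chrom", "start", "end", "strand")])
}

#' Write a genome annotation to GTF
#'
#' Emits transcript, exon and CDS records with 1-based inclusive coordinates
#' in stable (chrom, start, gene_id, transcript_id) order, so that
#' `read_gtf(write_gtf(x))` reproduces `x` field-by-field. CDS blocks are laid
#' out over the first `cds_length` transcribed nucleotides (5' to 3').
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  tx <- annotation$transcripts
  if (nrow(tx) == 0) return(invisible(NULL))
  ex_by_tx <- split(annotation$exons, annotation$exons$transcript_id)
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     t$gene_id, t$transcript_id, t$biotype)
    ex <- ex_by_tx[[t$transcript_id]]
    rows <- sprintf("%s\theartlnc\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                    t$chrom, t$start + 1L, t$end, t$strand, attrs)
    rows <- c(rows, sprintf("%s\theartlnc\texon\t%d\t%d\t.\t%s\t.\t%s",
                            ex$chrom, ex$start + 1L, ex$end, ex$strand, attrs))
    if (t$cds_length > 0) {
      blocks <- cds_blocks(ex$start, ex$end, t$strand, t$cds_length)
      rows <- c(rows, sprintf("%s\theartlnc\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              t$chrom, blocks$start + 1L, blocks$end, t$strand, attrs))
    }
    out[[i]] <- rows
  }
  writeLines(unlist(out), con)
  invisible(NULL)
}

# Lay cds_length transcribed nucleotides over exons, 5'->3'. Returns 0-based
# half-open blocks in genomic order.
cds_blocks <- function(ex_start, ex_end, strand, cds_length) {
  o <- if (strand == "+") order(ex_start) else order(-ex_start)
  s <- ex_start[o]; e <- ex_end[o]
  remaining <- cds_length
  bs <- integer(0); be <- integer(0)
  for (j in seq_along(s)) {
    if (remaining <= 0) break
    take <- min(remaining, e[j] - s[j])
    if (strand == "+") {
      bs <- c(bs, s[j]); be <- c(be, s[j] + take)
    } else {
      bs <- c(bs, e[j] - take); be <- c(be, e[j])
    }
    remaining <- remaining - take
  }
  o2 <- order(bs)
  list(start = bs[o2], end = be[o2])
}

# Distance from a 0-based point to a 0-based half-open span: 0 if contained,
# otherwise the coordinate gap to the nearest contained base.
dist_point_span <- function(p, s, e) {
  ifelse(p < s, s - p, ifelse(p >= e, p - e + 1L, 0L))
}

# Vectorised nearest-gene lookup for many query points, backed by the GRanges
# index. `pool` is a logical mask over annotation$genes rows. Returns a
# data.frame(gene_id, distance, gene_strand) with NA sentinel when the pool is
# empty on the query's chromosome.
nearest_gene_table <- function(annotation, chrom, pos, pool = NULL,
                               exclude_gene = NULL) {
  genes <- annotation$genes
  keep <- if (is.null(pool)) rep(TRUE, nrow(genes)) else pool
  gr_pool <- annotation$gr_genes[keep]
  gstrand <- genes$strand[keep]
  gid <- genes$gene_id[keep]
  gstart <- genes$start[keep]
  gend <- genes$end[keep]

  n <- length(pos)
  chrom <- rep_len(chrom, n)
  if (!is.null(exclude_gene)) exclude_gene <- rep_len(exclude_gene, n)
  res <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    gene_strand = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (length(gr_pool) == 0 || n == 0) return(res)
  # one seqlevel universe for query and pool, so queries on chromosomes absent
  # from the pool come back hitless instead of triggering a seqinfo merge
  lvls <- union(GenomeInfoDb::seqlevels(gr_pool), unique(chrom))
  GenomeInfoDb::seqlevels(gr_pool) <- lvls
  qgr <- GenomicRanges::GRanges(factor(chrom, levels = lvls),
                                IRanges::IRanges(start = pos + 1L, width = 1L))
  hits <- GenomicRanges::distanceToNearest(qgr, gr_pool, select = "all",
                                           ignore.strand = TRUE)
  if (length(hits) == 0) return(res)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  excl <- if (is.null(exclude_gene)) rep(FALSE, length(qh)) else
    gid[sh] == exclude_gene[qh]
  adj <- dist_point_span(pos[qh], gstart[sh], gend[sh])
  # rank hits per query: smaller adjusted distance, then lexicographic gene_id
  o <- order(qh, excl, adj, gid[sh])
  qh <- qh[o]; sh <- sh[o]; adj <- adj[o]; excl <- excl[o]
  first <- !duplicated(qh)
  take <- first & !excl
  res$gene_id[qh[take]] <- gid[sh[take]]
  res$distance[qh[take]] <- adj[take]
  res$gene_strand[qh[take]] <- gstrand[sh[take]]

  # queries whose only GRanges-nearest hits were excluded need a rescan with
  # the excluded gene removed from the pool
  unresolved <- unique(qh[first & excl & !qh %in% qh[take]])
  if (length(unresolved) > 0 && !is.null(exclude_gene)) {
    for (q in unresolved) {
      sub <- gid != exclude_gene[q] &
        genes$chrom[keep] == chrom[q]
      if (!any(sub)) next
      d <- dist_point_span(pos[q], gstart[sub], gend[sub])
      j <- order(d, gid[sub])[1]
      res$gene_id[q] <- gid[sub][j]
      res$distance[q] <- d[j]
      res$gene_strand[q] <- gstrand[sub][j]
    }
  }
  res
}

#' Nearest gene to a genomic point
#'
#' Finds the qualifying gene nearest to a point, with distance 0 when the point
#' falls inside a gene span and otherwise the coordinate gap to the nearest
#' span boundary. Ties are broken by smaller distance, then lexicographic
#' `gene_id`. When no qualifying gene exists on the chromosome, a sentinel row
#' with `NA` fields is returned (never an error).
#'
#' @param annotation A [genome_annotation()].
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @param biotype Restrict the neighbor pool to this biotype
#'   (default `"protein_coding"`); `NULL` for all genes.
#' @param exclude_gene Optional `gene_id` excluded from the pool (e.g. the
#'   query transcript's own gene).
#' @return list with `gene_id`, `distance` (bp), `gene_strand`.
#' @export
nearest_gene_query <- function(annotation, chrom, pos,
                               biotype = "protein_coding",
                               exclude_gene = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"), length(chrom) == 1)
  pool <- rep(TRUE, nrow(annotation$genes))
  if (!is.null(biotype)) pool <- annotation$genes$biotype %in% biotype
  if (!is.null(exclude_gene)) pool <- pool & annotation$genes$gene_id != exclude_gene
  r <- nearest_gene_table(annotation, chrom, pos, pool = pool)
  list(gene_id = r$gene_id[1], distance = r$distance[1],
       gene_strand = r$gene_strand[1])
}
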