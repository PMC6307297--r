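# Genomic-context classification of lncRNA candidates relative to
# protein-coding genes: bidirectional (divergent promoter), antisense
# (opposite-strand span overlap), both, or intergenic; plus nearest-gene
# distances and the orientation census.

#' Context-classification configuration
#'
#' @param bidirectional_window maximal TSS-to-TSS gap (bp) for a divergent
#'   promoter call. Default 3000.
#' @param proximity_window window (bp) for the orientation census.
#'   Default 10000.
#' @param require_divergent require head-to-head orientation (transcription
#'   pointing away from each other) in addition to opposite strands for the
#'   bidirectional call. Opposite-strand convergent or same-strand proximal
#'   pairs are then excluded (the latter flagged diagnostically). Default TRUE.
#' @param expressed_neighbors_only restrict the nearest-gene pool to coding
#'   genes expressed in at least one ventricle stage. Default TRUE.
#' @param distance_mode `"gene_body"` (TSS to nearest gene span; default) or
#'   `"tss"` (TSS to nearest coding TSS).
#' @return list of class `context_config`.
#' @export
context_config <- function(bidirectional_window = 3000L,
                           proximity_window = 10000L,
                           require_divergent = TRUE,
                           expressed_neighbors_only = TRUE,
                           distance_mode = c("gene_body", "tss")) {
  stopifnot(bidirectional_window > 0, proximity_window > 0)
  structure(list(bidirectional_window = as.integer(bidirectional_window),
                 proximity_window = as.integer(proximity_window),
                 require_divergent = isTRUE(require_divergent),
                 expressed_neighbors_only = isTRUE(expressed_neighbors_only),
                 distance_mode = match.arg(distance_mode)),
            class = "context_config")
}

# TRUE where a (lnc_tss, lnc_strand) x (gene_tss, gene_strand) pair is
# transcribed head-to-head (divergently): the lncRNA points away from the gene.
is_divergent <- function(lnc_tss, lnc_strand, gene_tss, gene_strand) {
  (lnc_strand == "-" & gene_strand == "+" & lnc_tss <= gene_tss) |
  (lnc_strand == "+" & gene_strand == "-" & lnc_tss >= gene_tss)
}

# coding genes expressed (>= min_fpkm) in >= 1 sample of `tissue`, at gene
# level (max over isoforms present in the matrix)
expressed_gene_ids <- function(annotation, matrix, min_fpkm = 1,
                               tissue = "heart") {
  tx <- annotation$transcripts
  v <- tissue_values(matrix, tx$transcript_id, tissue)
  mx <- apply(v, 1, max)
  g <- tapply(mx, tx$gene_id, max)
  names(g)[g >= min_fpkm]
}

#' Nearest protein-coding gene distance per candidate
#'
#' Computes, for each candidate TSS, the distance to the nearest protein-coding
#' gene (excluding the candidate's own gene), optionally restricting the
#' neighbor pool to genes expressed in the ventricle at a minimum of one stage.
#' Distance is 0 inside a gene span, otherwise the gap to the span boundary
#' (or, with `distance_mode = "tss"`, the TSS-to-TSS gap).
#'
#' @param candidates candidate transcript rows (need `transcript_id`,
#'   `gene_id`, `chrom`, `tss`).
#' @param annotation a [genome_annotation()].
#' @param matrix an [expr_matrix()]; required when
#'   `config$expressed_neighbors_only`.
#' @param config a [context_config()].
#' @param min_fpkm expression threshold for the neighbor pool. Default 1.
#' @return `candidates` with `nearest_gene`, `nearest_distance`,
#'   `nearest_gene_strand` (NA sentinel when the pool is empty).
#' @export
compute_nearest_distances <- function(candidates, annotation, matrix = NULL,
                                      config = context_config(),
                                      min_fpkm = 1) {
  genes <- annotation$genes
  pool <- genes$biotype == "protein_coding"
  if (config$expressed_neighbors_only) {
    if (is.null(matrix))
      stop("expression matrix required when expressed_neighbors_only = TRUE")
    expressed <- expressed_gene_ids(annotation, matrix, min_fpkm)
    pool <- pool & genes$gene_id %in% expressed
  }
  if (config$distance_mode == "gene_body") {
    r <- nearest_gene_table(annotation, candidates$chrom, candidates$tss,
                            pool = pool, exclude_gene = candidates$gene_id)
  } else {
    r <- nearest_tss_table(annotation, candidates$chrom, candidates$tss,
                           pool_genes = genes$gene_id[pool],
                           exclude_gene = candidates$gene_id)
  }
  candidates$nearest_gene <- r$gene_id
  candidates$nearest_distance <- r$distance
  candidates$nearest_gene_strand <- r$gene_strand
  candidates
}

# TSS-to-TSS nearest lookup (mode switch alternative); plain arithmetic per
# chromosome over the annotation's TSS table.
nearest_tss_table <- function(annotation, chrom, pos, pool_genes,
                              exclude_gene = NULL) {
  tss <- annotation$tss[annotation$tss$gene_id %in% pool_genes, , drop = FALSE]
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  if (!is.null(exclude_gene)) exclude_gene <- rep_len(exclude_gene, n)
  res <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    gene_strand = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sub <- tss[tss$chrom == chrom[i], , drop = FALSE]
    if (!is.null(exclude_gene))
      sub <- sub[sub$gene_id != exclude_gene[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    d <- abs(sub$tss - pos[i])
    j <- order(d, sub$gene_id)[1]
    res$gene_id[i] <- sub$gene_id[j]
    res$distance[i] <- d[j]
    res$gene_strand[i] <- sub$strand[j]
  }
  res
}

#' Classify candidates by genomic context
#'
#' A candidate is *bidirectional* iff some protein-coding TSS on the opposite
#' strand lies within `bidirectional_window` bp of the candidate TSS
#' (unstranded absolute gap) and, when `require_divergent`, the two point away
#' from each other (head-to-head). It is *antisense* iff its span overlaps a
#' protein-coding gene span on the opposite strand by at least 1 bp (gene-span,
#' not exon-level, overlap: the motivating antisense case overlaps an intron).
#' Both labels together give `"both"`; neither gives `"intergenic"`.
#' Same-strand TSS proximity is flagged diagnostically but never counts as
#' bidirectional.
#'
#' @inheritParams compute_nearest_distances
#' @return `candidates` with logical `is_bidirectional`, `is_antisense`,
#'   `same_strand_proximal`, the `context` label, and `;`-joined
#'   `bidirectional_partners` / `antisense_partners` gene ids.
#' @export
classify_genomic_context <- function(candidates, annotation,
                                     config = context_config()) {
  tssall <- annotation$tss
  coding_tss <- tssall[tssall$biotype == "protein_coding", , drop = FALSE]
  genes <- annotation$genes
  coding_genes <- genes[genes$biotype == "protein_coding", , drop = FALSE]

  n <- nrow(candidates)
  is_bid <- logical(n); is_as <- logical(n); same_prox <- logical(n)
  bid_partners <- character(n); as_partners <- character(n)

  # antisense: span overlap with opposite-strand coding gene spans
  if (n > 0 && nrow(coding_genes) > 0) {
    cgr <- GenomicRanges::GRanges(candidates$chrom,
             IRanges::IRanges(candidates$start + 1L, candidates$end))
    ggr <- GenomicRanges::GRanges(coding_genes$chrom,
             IRanges::IRanges(coding_genes$start + 1L, coding_genes$end))
    ov <- GenomicRanges::findOverlaps(cgr, ggr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    opp <- candidates$strand[qh] != coding_genes$strand[sh] &
      candidates$gene_id[qh] != coding_genes$gene_id[sh]
    qh <- qh[opp]; sh <- sh[opp]
    if (length(qh) > 0) {
      is_as[unique(qh)] <- TRUE
      parts <- tapply(coding_genes$gene_id[sh], qh,
                      function(x) paste(sort(unique(x)), collapse = ";"))
      as_partners[as.integer(names(parts))] <- unname(parts)
    }
  }

  # bidirectional: opposite-strand coding TSS within window, divergent
  if (n > 0 && nrow(coding_tss) > 0) {
    by_chrom <- split(seq_len(nrow(coding_tss)), coding_tss$chrom)
    for (i in seq_len(n)) {
      ii <- by_chrom[[candidates$chrom[i]]]
      if (is.null(ii)) next
      sub <- coding_tss[ii, , drop = FALSE]
      sub <- sub[sub$gene_id != candidates$gene_id[i], , drop = FALSE]
      gap <- abs(sub$tss - candidates$tss[i])
      near <- gap <= config$bidirectional_window
      opp <- sub$strand != candidates$strand[i]
      same_prox[i] <- any(near & !opp)
      ok <- near & opp
      if (config$require_divergent)
        ok <- ok & is_divergent(candidates$tss[i], candidates$strand[i],
                                sub$tss, sub$strand)
      if (any(ok)) {
        is_bid[i] <- TRUE
        bid_partners[i] <- paste(sort(unique(sub$gene_id[ok])), collapse = ";")
      }
    }
  }

  candidates$is_bidirectional <- is_bid
  candidates$is_antisense <- is_as
  candidates$same_strand_proximal <- same_prox
  candidates$bidirectional_partners <- bid_partners
  candidates$antisense_partners <- as_partners
  candidates$context <- ifelse(is_bid & is_as, "both",
                        ifelse(is_bid, "bidirectional",
                        ifelse(is_as, "antisense", "intergenic")))
  candidates
}

#' Orientation census of candidates near known genes
#'
#' Among candidates whose TSS lies within `proximity_window` bp of a
#' protein-coding gene, counts those transcribed on the opposite vs the same
#' strand as that gene. With `mode = "nearest"` (default) each candidate is
#' judged against its single nearest gene; with `mode = "any"` a candidate
#' counts as opposite if any opposite-strand gene lies within the window.
#'
#' @inheritParams compute_nearest_distances
#' @param mode `"nearest"` or `"any"`.
#' @return list with `opposite`, `same`, `n_within`.
#' @export
orientation_census <- function(candidates, annotation,
                               config = context_config(),
                               mode = c("nearest", "any")) {
  mode <- match.arg(mode)
  genes <- annotation$genes
  pool <- genes$biotype == "protein_coding"
  r <- nearest_gene_table(annotation, candidates$chrom, candidates$tss,
                          pool = pool, exclude_gene = candidates$gene_id)
  within <- !is.na(r$distance) & r$distance <= config$proximity_window
  if (mode == "nearest") {
    opp <- within & r$gene_strand != candidates$strand
    same <- within & r$gene_strand == candidates$strand
    return(list(opposite = sum(opp, na.rm = TRUE),
                same = sum(same, na.rm = TRUE),
                n_within = sum(within)))
  }
  # mode "any": scan all pool genes within the window per candidate
  cg <- genes[pool, , drop = FALSE]
  opp <- 0L; same <- 0L; nwin <- 0L
  for (i in seq_len(nrow(candidates))) {
    sub <- cg[cg$chrom == candidates$chrom[i] &
                cg$gene_id != candidates$gene_id[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    d <- dist_point_span(candidates$tss[i], sub$start, sub$end)
    hit <- d <= config$proximity_window
    if (!any(hit)) next
    nwin <- nwin + 1L
    if (any(sub$strand[hit] != candidates$strand[i])) opp <- opp + 1L
    else same <- same + 1L
  }
  list(opposite = opp, same = same, n_within = nwin)
}

#' Coding genes carrying a bidirectional lncRNA
#'
#' Gene-level reduction of the bidirectional classification: a coding gene
#' "has" a bidirectional lncRNA iff any classified candidate lists it among its
#' bidirectional partner genes (any isoform TSS qualifies).
#'
#' @param classified output of [classify_genomic_context()].
#' @param annotation a [genome_annotation()].
#' @return data.frame (`gene_id`, `has_bidirectional`) over all coding genes.
#' @export
genes_with_bidirectional <- function(classified, annotation) {
  coding <- annotation$genes[annotation$genes$biotype == "protein_coding", ,
                             drop = FALSE]
  partners <- unlist(strsplit(
    classified$bidirectional_partners[classified$is_bidirectional], ";",
    fixed = TRUE))
  data.frame(gene_id = coding$gene_id,
             has_bidirectional = coding$gene_id %in% partners,
             stringsAsFactors = FALSE)
}
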