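# Candidate identification: from assembled transcripts to spliced,
# heart-expressed lncRNA candidates with tissue-selectivity calls.
#
# All filters are pure row subsets of the transcript table, so they commute;
# gene-level summaries downstream take the max over isoforms.

#' Filtering configuration
#'
#' @param min_fpkm expression lower limit (fpkm; inclusive). Default 1.
#' @param cds_fraction_max maximal tolerated CDS fraction of transcript length;
#'   transcripts with `cds_length > tx_length * cds_fraction_max` are removed
#'   (strictly greater: equality is retained). Default 1/3.
#' @param min_exons minimum exon count (spliced = at least 2). Default 2.
#' @param expression_tissue tissue whose samples define "expressed". Default
#'   `"heart"`.
#' @param reference_tissue tissue that must show no expression for a candidate
#'   to be called selective. Default `"brain"`.
#' @param extra_tissues tissues tallied in the expression census. Default
#'   kidney and liver.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_fpkm = 1, cds_fraction_max = 1/3, min_exons = 2L,
                          expression_tissue = "heart", reference_tissue = "brain",
                          extra_tissues = c("kidney", "liver")) {
  stopifnot(min_fpkm > 0, cds_fraction_max > 0, cds_fraction_max <= 1,
            min_exons >= 1)
  structure(list(min_fpkm = min_fpkm, cds_fraction_max = cds_fraction_max,
                 min_exons = as.integer(min_exons),
                 expression_tissue = expression_tissue,
                 reference_tissue = reference_tissue,
                 extra_tissues = extra_tissues),
            class = "filter_config")
}

#' Keep spliced transcripts
#'
#' Retains transcripts with at least `min_exons` exons. Unspliced transcript
#' models are hard to validate from short-read assemblies and most functional
#' lncRNAs are spliced, so single-exon models are dropped.
#'
#' @param transcripts per-transcript data.frame (as in
#'   `genome_annotation()$transcripts`).
#' @param config a [filter_config()].
#' @return the retained rows.
#' @export
filter_spliced <- function(transcripts, config = filter_config()) {
  transcripts[transcripts$n_exons >= config$min_exons, , drop = FALSE]
}

#' Remove known/coding transcripts by annotation-declared coding potential
#'
#' Removes (i) transcripts whose annotated CDS exceeds `cds_fraction_max` of
#' their transcript length (strictly greater removes; equality retained), and
#' (ii) biotypes that are already-known mRNAs or functional RNAs not classed
#' as lncRNAs (`protein_coding`, `snoRNA`, `tRNA`, `other_nc`).
#'
#' @inheritParams filter_spliced
#' @return the retained rows.
#' @export
filter_coding_potential <- function(transcripts, config = filter_config()) {
  known <- transcripts$biotype %in% c("protein_coding", "snoRNA", "tRNA", "other_nc")
  too_coding <- transcripts$cds_length > transcripts$tx_length * config$cds_fraction_max
  transcripts[!known & !too_coding, , drop = FALSE]
}

#' Keep transcripts expressed in the target tissue
#'
#' Retains transcripts with fpkm at or above `min_fpkm` in at least one sample
#' of the expression tissue (heart by default), and records the per-transcript
#' maximum (`max_heart_fpkm`). Transcripts absent from the matrix count as
#' fpkm 0 everywhere.
#'
#' @inheritParams filter_spliced
#' @param matrix an [expr_matrix()].
#' @return the retained rows, with a `max_heart_fpkm` column added.
#' @export
filter_expression <- function(transcripts, matrix, config = filter_config()) {
  v <- tissue_values(matrix, transcripts$transcript_id, config$expression_tissue)
  mx <- apply(v, 1, max)
  transcripts$max_heart_fpkm <- unname(mx)
  transcripts[mx >= config$min_fpkm, , drop = FALSE]
}

#' Call tissue selectivity and the tissue expression census
#'
#' A candidate is heart-selective iff it is expressed (fpkm >= `min_fpkm`) in
#' at least one heart sample and below `min_fpkm` in *every* reference-tissue
#' (brain) sample. Per-tissue expressed flags for the census tissues are added
#' using the same threshold.
#'
#' @param candidates candidate rows (post [filter_expression()]).
#' @param matrix an [expr_matrix()].
#' @param config a [filter_config()].
#' @return `candidates` with columns `selective`, `expressed_<tissue>` and
#'   `max_<tissue>_fpkm` for the reference and extra tissues.
#' @export
classify_tissue_selectivity <- function(candidates, matrix,
                                        config = filter_config()) {
  if (!config$reference_tissue %in% matrix$samples$tissue)
    stop("configuration error: reference tissue '", config$reference_tissue,
         "' absent from expression matrix")
  ids <- candidates$transcript_id
  heart <- apply(tissue_values(matrix, ids, config$expression_tissue), 1, max)
  candidates$max_heart_fpkm <- unname(heart)
  for (tis in c(config$reference_tissue, config$extra_tissues)) {
    mx <- apply(tissue_values(matrix, ids, tis), 1, max)
    candidates[[paste0("max_", tis, "_fpkm")]] <- unname(mx)
    candidates[[paste0("expressed_", tis)]] <- unname(mx >= config$min_fpkm)
  }
  ref <- candidates[[paste0("expressed_", config$reference_tissue)]]
  candidates$selective <- heart >= config$min_fpkm & !ref
  candidates
}

#' Summarise the tissue-expression census of selective candidates
#'
#' Tallies, among heart-selective candidates, how many are expressed in none of
#' the census tissues (heart only) and how many in both kidney and liver,
#' mirroring the screen's census of 316 selective candidates.
#'
#' @param candidates output of [classify_tissue_selectivity()].
#' @param config a [filter_config()].
#' @return list with `n_selective`, `n_heart_only`, `n_both_extra`.
#' @export
selectivity_census <- function(candidates, config = filter_config()) {
  sel <- candidates[candidates$selective, , drop = FALSE]
  flags <- sapply(config$extra_tissues,
                  function(t) sel[[paste0("expressed_", t)]],
                  simplify = FALSE)
  fm <- do.call(cbind, flags)
  if (is.null(fm)) fm <- matrix(FALSE, nrow(sel), 0)
  list(n_selective = nrow(sel),
       n_heart_only = sum(rowSums(fm) == 0),
       n_both_extra = sum(rowSums(fm) == ncol(fm)))
}
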