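# Divergent-pair expression correlation across development, subcellular
# localization ratios, and the assembly-fidelity QC (exon-number error vs
# expression with an exponential fit).

#' Pearson correlation of divergent promoter pairs across development
#'
#' For each (lncRNA, partner coding gene) pair, computes the Pearson
#' correlation of `log2(fpkm + pseudocount)` across the developmental stages of
#' one tissue (the three heart-ventricle stages by default). Replicates within
#' a stage are averaged first; partner gene expression is the sum over its
#' isoforms. Pairs with zero variance in either log-series are flagged
#' undefined and excluded from the histogram.
#'
#' @param pairs data.frame with columns `lnc_id` (transcript id present in the
#'   matrix) and `partner_gene_id`.
#' @param matrix an [expr_matrix()].
#' @param annotation a [genome_annotation()] used to map partner genes to
#'   their transcripts.
#' @param pseudocount added before log2. Default 1.
#' @param tissue tissue whose stages form the developmental axis. Default
#'   `"heart"`.
#' @param breaks histogram breaks on [-1, 1]. Default width 0.2.
#' @return list with `pairs` (input plus `r`, `n_points`, `undefined`) and
#'   `histogram` (`bin_lo`, `bin_hi`, `count`).
#' @export
pair_correlation <- function(pairs, matrix, annotation, pseudocount = 1,
                             tissue = "heart", breaks = seq(-1, 1, by = 0.2)) {
  sm <- matrix$samples[matrix$samples$tissue == tissue, , drop = FALSE]
  stages <- unique(sm$stage)
  tx <- annotation$transcripts

  stage_series <- function(ids) {
    # stage-averaged fpkm of the summed expression of `ids`
    present <- intersect(ids, rownames(matrix$values))
    vapply(stages, function(st) {
      cols <- sm$sample[sm$stage == st]
      if (length(present) == 0) return(0)
      mean(colSums(matrix$values[present, cols, drop = FALSE]))
    }, 0)
  }

  r <- rep(NA_real_, nrow(pairs))
  npt <- integer(nrow(pairs))
  undef <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lnc <- log2(stage_series(pairs$lnc_id[i]) + pseudocount)
    gtx <- tx$transcript_id[tx$gene_id == pairs$partner_gene_id[i]]
    par <- log2(stage_series(gtx) + pseudocount)
    npt[i] <- length(stages)
    if (length(stages) < 3 || stats::sd(lnc) == 0 || stats::sd(par) == 0) {
      undef[i] <- TRUE
      next
    }
    r[i] <- stats::cor(lnc, par)
  }
  pairs$r <- r
  pairs$n_points <- npt
  pairs$undefined <- undef
  h <- if (any(!undef)) {
    graphics::hist(pmin(pmax(r[!undef], -1), 1), breaks = breaks, plot = FALSE)
  } else NULL
  histogram <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    count = if (is.null(h)) rep(0L, length(breaks) - 1) else h$counts)
  list(pairs = pairs, histogram = histogram)
}

#' Subcellular localization ratio
#'
#' `log10((intact + pseudocount) / (nuclear + pseudocount))` per transcript:
#' positive values indicate cytoplasm-skewed transcripts, negative values
#' nucleus-skewed ones, and values near zero transcripts with no clear
#' localization.
#'
#' @param intact_abundance,nuclear_abundance non-negative numeric vectors.
#' @param pseudocount added to both abundances. Default 0.01.
#' @return numeric vector of log10 ratios.
#' @export
localization_ratio <- function(intact_abundance, nuclear_abundance,
                               pseudocount = 0.01) {
  if (any(intact_abundance < 0) || any(nuclear_abundance < 0))
    stop("argument error: abundances must be non-negative")
  log10((intact_abundance + pseudocount) / (nuclear_abundance + pseudocount))
}

#' Assembly-fidelity QC: exon-number error vs expression
#'
#' Compares per-gene exon counts between an assembled and a reference
#' annotation (exon number = maximum over alternative transcripts), restricted
#' to genes with reference exon number at most `max_ref_exons`, and fits the
#' absolute exon-number difference as a decaying exponential of expression,
#' `diff = a * exp(-b * fpkm)`, by least squares. The fpkm at which the
#' expected difference drops below `target_diff` is reported: the expression
#' level above which gene models are reconstructed essentially intact.
#'
#' @param assembled,reference [genome_annotation()] objects sharing gene ids.
#' @param matrix an [expr_matrix()]; per-gene fpkm is the stage-maximum over
#'   the expression tissue's samples (max over isoforms).
#' @param max_ref_exons reference exon-number cap. Default 12.
#' @param target_diff exon-difference threshold for the reported fpkm.
#'   Default 0.5.
#' @param tissue expression tissue. Default `"heart"`.
#' @return list with `table` (gene_id, ref_exons, asm_exons, diff, fpkm),
#'   `fit` (list `a`, `b`, `converged`) and `fpkm_at_target` (NA when the fit
#'   failed or is degenerate).
#' @export
exon_fidelity_qc <- function(assembled, reference, matrix,
                             max_ref_exons = 12L, target_diff = 0.5,
                             tissue = "heart") {
  gene_exons <- function(ann) {
    tapply(ann$transcripts$n_exons, ann$transcripts$gene_id, max)
  }
  ref_ex <- gene_exons(reference)
  asm_ex <- gene_exons(assembled)
  shared <- intersect(names(ref_ex), names(asm_ex))
  if (length(shared) == 0)
    stop("no shared gene identifiers between assembled and reference annotation")

  atx <- assembled$transcripts
  v <- tissue_values(matrix, atx$transcript_id, tissue)
  tx_max <- apply(v, 1, max)
  gene_fpkm <- tapply(tx_max, atx$gene_id, max)

  tab <- data.frame(gene_id = shared,
                    ref_exons = as.integer(ref_ex[shared]),
                    asm_exons = as.integer(asm_ex[shared]),
                    fpkm = as.numeric(gene_fpkm[shared]),
                    stringsAsFactors = FALSE)
  tab$diff <- abs(tab$asm_exons - tab$ref_exons)
  tab <- tab[tab$ref_exons <= max_ref_exons, , drop = FALSE]
  rownames(tab) <- NULL

  fit <- list(a = NA_real_, b = NA_real_, converged = FALSE)
  fpkm_at_target <- NA_real_
  if (nrow(tab) >= 3 && stats::sd(tab$diff) > 0) {
    a0 <- max(mean(tab$diff[tab$fpkm <= stats::quantile(tab$fpkm, 0.2)]), 0.5)
    sl <- stats::coef(stats::lm(log(diff + 0.1) ~ fpkm, data = tab))[["fpkm"]]
    b0 <- max(-sl, 0.01)
    m <- tryCatch(
      minpack.lm::nlsLM(diff ~ a * exp(-b * fpkm), data = tab,
                        start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(m)) {
      cf <- stats::coef(m)
      fit <- list(a = unname(cf["a"]), b = unname(cf["b"]), converged = TRUE)
      if (fit$a > target_diff && fit$b > 0)
        fpkm_at_target <- log(fit$a / target_diff) / fit$b
      else if (fit$a <= target_diff)
        fpkm_at_target <- 0
    }
  }
  list(table = tab, fit = fit, fpkm_at_target = fpkm_at_target)
}
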