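# End-to-end orchestration: filter -> selectivity -> context -> distances ->
# correlations -> enrichment, with TSV/JSON outputs and a deterministic
# manifest.

#' Pipeline run configuration
#'
#' @param annotation_gtf path to the transcript-model GTF (assembled
#'   transcripts plus reference coding annotation with CDS records).
#' @param expression_tsv path to the transcript x sample fpkm TSV.
#' @param gene_labels_tsv optional path to a gene label TSV with
#'   `haploinsufficient` / `housekeeping` flags.
#' @param gene_sets optional named list (term -> gene ids) for gene-set
#'   enrichment of the genes nearest to candidates.
#' @param out_dir output directory; `NULL` suppresses file output.
#' @param filter a [filter_config()].
#' @param context a [context_config()].
#' @param seed recorded in the manifest (the pipeline itself is deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(annotation_gtf, expression_tsv, gene_labels_tsv = NULL,
                       gene_sets = NULL, out_dir = NULL,
                       filter = filter_config(), context = context_config(),
                       seed = 1L) {
  structure(list(annotation_gtf = annotation_gtf,
                 expression_tsv = expression_tsv,
                 gene_labels_tsv = gene_labels_tsv,
                 gene_sets = gene_sets, out_dir = out_dir,
                 filter = filter, context = context, seed = as.integer(seed)),
            class = "run_config")
}

# small polynomial content hash (hex), stable across runs for identical config
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(
    x[c("annotation_gtf", "expression_tsv", "gene_labels_tsv", "seed",
        "filter", "context")],
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Distance-distribution comparison across RNA classes
#'
#' Computes TSS-to-nearest-coding-gene distances for three groups -- mRNAs
#' (all coding transcripts), all lncRNA candidates, and heart-selective
#' candidates -- and compares lncRNA groups against mRNAs by two-sided
#' Mann-Whitney tests. The neighbor pool excludes each transcript's own gene
#' and (by default) is restricted to ventricle-expressed coding genes.
#'
#' @param candidates classified candidates (need `selective`, `chrom`, `tss`,
#'   `gene_id`, and `nearest_distance` if already computed).
#' @param annotation a [genome_annotation()].
#' @param matrix an [expr_matrix()].
#' @param config a [context_config()].
#' @param min_fpkm neighbor-pool expression threshold.
#' @return list with `summary` (group, n, median) and `tests`
#'   (comparison, U, p).
#' @export
distance_distribution_stats <- function(candidates, annotation, matrix,
                                        config = context_config(),
                                        min_fpkm = 1) {
  mrna <- annotation$transcripts[
    annotation$transcripts$biotype == "protein_coding", , drop = FALSE]
  mrna <- compute_nearest_distances(mrna, annotation, matrix, config, min_fpkm)
  if (!"nearest_distance" %in% names(candidates))
    candidates <- compute_nearest_distances(candidates, annotation, matrix,
                                            config, min_fpkm)
  d_mrna <- mrna$nearest_distance[!is.na(mrna$nearest_distance)]
  d_all <- candidates$nearest_distance[!is.na(candidates$nearest_distance)]
  sel <- candidates[candidates$selective, , drop = FALSE]
  d_sel <- sel$nearest_distance[!is.na(sel$nearest_distance)]

  summary <- data.frame(
    group = c("mRNA", "lncRNA_all", "lncRNA_heart_selective"),
    n = c(length(d_mrna), length(d_all), length(d_sel)),
    median_distance = c(stats::median(d_mrna), stats::median(d_all),
                        stats::median(d_sel)))
  tests <- data.frame(comparison = character(0), U = numeric(0), p = numeric(0))
  if (length(d_mrna) > 0 && length(d_all) > 0) {
    t1 <- mann_whitney(d_all, d_mrna)
    tests <- rbind(tests, data.frame(comparison = "lncRNA_all_vs_mRNA",
                                     U = t1$U, p = t1$p))
  }
  if (length(d_mrna) > 0 && length(d_sel) > 0) {
    t2 <- mann_whitney(d_sel, d_mrna)
    tests <- rbind(tests, data.frame(comparison = "lncRNA_selective_vs_mRNA",
                                     U = t2$U, p = t2$p))
  }
  list(summary = summary, tests = tests)
}

write_tsv_commented <- function(df, path, what) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s", what), con)
  writeLines(sprintf("# columns: %s", paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Run the full identification/classification pipeline
#'
#' Executes the whole screen on one input bundle: splicing, coding-potential
#' and expression filters; tissue-selectivity calls; genomic-context
#' classification; nearest-gene distances and distance-distribution tests;
#' orientation census; divergent-pair correlations; and (when gene labels are
#' supplied) the haploinsufficiency enrichment with its housekeeping control.
#' Per-stage record counts are logged via `message()`. Deterministic given the
#' configuration.
#'
#' @param config a [run_config()].
#' @return a report list with elements `stage_counts`, `candidates`,
#'   `class_counts`, `census`, `orientation`, `distances`, `correlations`,
#'   `enrichment`, `gene_set_enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$annotation_gtf, config$expression_tsv,
              config$gene_labels_tsv)) {
    if (!is.null(p) && !file.exists(p))
      stop("config error: missing input file: ", p)
  }
  annotation <- read_gtf(config$annotation_gtf)
  matrix <- read_expression_tsv(config$expression_tsv)
  labels <- if (!is.null(config$gene_labels_tsv))
    read_gene_labels(config$gene_labels_tsv) else NULL

  fc <- config$filter; cc <- config$context
  tx <- annotation$transcripts
  stage_counts <- c(input = nrow(tx))
  s1 <- filter_spliced(tx, fc)
  stage_counts["spliced"] <- nrow(s1)
  s2 <- filter_coding_potential(s1, fc)
  stage_counts["non_coding"] <- nrow(s2)
  s3 <- filter_expression(s2, matrix, fc)
  stage_counts["expressed"] <- nrow(s3)
  cand <- classify_tissue_selectivity(s3, matrix, fc)
  stage_counts["selective"] <- sum(cand$selective)
  message(sprintf("filter stages: %s",
                  paste(names(stage_counts), stage_counts, sep = "=",
                        collapse = ", ")))

  cand <- classify_genomic_context(cand, annotation, cc)
  cand <- compute_nearest_distances(cand, annotation, matrix, cc, fc$min_fpkm)
  class_counts <- table(factor(cand$context,
                               levels = c("bidirectional", "antisense", "both",
                                          "intergenic")))
  census <- selectivity_census(cand, fc)
  orientation <- orientation_census(cand, annotation, cc)
  distances <- distance_distribution_stats(cand, annotation, matrix, cc,
                                           fc$min_fpkm)

  # divergent-pair correlations (one row per candidate x partner gene)
  bid <- cand[cand$is_bidirectional, , drop = FALSE]
  pairs <- if (nrow(bid) > 0) {
    do.call(rbind, lapply(seq_len(nrow(bid)), function(i) {
      data.frame(lnc_id = bid$transcript_id[i],
                 partner_gene_id = strsplit(bid$bidirectional_partners[i],
                                            ";", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(lnc_id = character(0), partner_gene_id = character(0))
  correlations <- if (nrow(pairs) > 0)
    pair_correlation(pairs, matrix, annotation) else NULL

  enrichment <- NULL; control_p <- NULL
  if (!is.null(labels) && "haploinsufficient" %in% names(labels)) {
    gb <- genes_with_bidirectional(cand, annotation)
    gt <- merge(gb, labels[, setdiff(names(labels), "has_bidirectional")],
                by = "gene_id")
    enrichment <- bidirectional_hi_enrichment(gt)
    if ("housekeeping" %in% names(gt)) control_p <- proportion_control(gt)
  }

  gse <- NULL
  if (!is.null(config$gene_sets)) {
    universe <- annotation$genes$gene_id[
      annotation$genes$biotype == "protein_coding"]
    query <- unique(stats::na.omit(cand$nearest_gene))
    gse <- gene_set_enrichment(intersect(query, universe), config$gene_sets,
                               universe)
  }

  manifest <- list(
    package = "heartlnc",
    version = as.character(utils::packageVersion("heartlnc")),
    config_hash = config_hash(config),
    seed = config$seed,
    inputs = list(annotation_gtf = config$annotation_gtf,
                  expression_tsv = config$expression_tsv,
                  gene_labels_tsv = config$gene_labels_tsv),
    stage_counts = as.list(stage_counts),
    class_counts = as.list(class_counts))

  report <- list(stage_counts = stage_counts, candidates = cand,
                 class_counts = class_counts, census = census,
                 orientation = orientation, distances = distances,
                 correlations = correlations, enrichment = enrichment,
                 housekeeping_control_p = control_p,
                 gene_set_enrichment = gse, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_commented(cand, file.path(config$out_dir, "candidates.tsv"),
                        "lncRNA candidates with selectivity and genomic context")
    write_tsv_commented(distances$summary,
                        file.path(config$out_dir, "distance_summary.tsv"),
                        "median TSS-to-nearest-coding-gene distance per group")
    write_tsv_commented(distances$tests,
                        file.path(config$out_dir, "distance_tests.tsv"),
                        "Mann-Whitney distance comparisons")
    if (!is.null(correlations))
      write_tsv_commented(correlations$pairs,
                          file.path(config$out_dir, "pair_correlations.tsv"),
                          "Pearson r of divergent pairs across heart stages")
    if (!is.null(gse))
      write_tsv_commented(gse, file.path(config$out_dir, "gene_set_enrichment.tsv"),
                          "hypergeometric gene-set enrichment with BH FDR")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  report
}
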