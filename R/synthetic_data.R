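# Synthetic study generator: genome annotations with planted lncRNA classes
# (bidirectional / antisense / intergenic), tissue-graded expression with
# planted heart selectivity and divergent-pair coupling, and gene labels with
# a planted haploinsufficiency/bidirectional association.
#
# Layout: each chromosome is divided into fixed-width slots. Coding genes sit
# at a fixed offset inside their slot; bidirectional lncRNAs are planted
# upstream of their partner's TSS on the opposite strand, antisense lncRNAs
# inside their host gene's span on the opposite strand, intergenic lncRNAs in
# slots of their own. Slot geometry guarantees every planted class sits well
# clear (>10%) of the classification windows used downstream.

SLOT_WIDTH <- 50000L
GENE_OFFSET <- 15000L   # coding gene start within its slot

#' Simulation configuration
#'
#' Defaults encode the study conditions of the synthetic validation: 200
#' coding genes, 20 lncRNAs per genomic class, two thirds of lncRNAs planted
#' heart-selective, divergent-pair coupling strength 0.9 with log-scale noise
#' SD 0.2 over three heart stages, and a planted odds multiplier of 3 for
#' haploinsufficient genes carrying a bidirectional lncRNA.
#'
#' @param seed master RNG seed; three sub-streams (placement, expression,
#'   labels) are derived from it so adding genes does not reshuffle expression
#'   draws.
#' @param n_chroms,chrom_length chromosome count and length (bp).
#' @param n_coding_genes number of protein-coding genes.
#' @param n_bidirectional,n_antisense,n_intergenic planted lncRNAs per class.
#' @param bidirectional_offset_range TSS-to-TSS gap range (bp) for planted
#'   divergent pairs; kept at least 10% below the 3000 bp classification
#'   window.
#' @param antisense_overlap_fraction fraction of a planted antisense lncRNA
#'   overlapping its host gene (1 = fully contained).
#' @param intergenic_min_distance minimal gap (bp) between a planted intergenic
#'   lncRNA and any coding gene.
#' @param stages developmental stages of the heart/brain samples.
#' @param selectivity_fraction fraction of lncRNAs planted heart-selective.
#' @param coupling_strength log2-scale slope coupling a partner gene to its
#'   divergent lncRNA across heart stages (0 = uncoupled).
#' @param coupling_positive_fraction fraction of coupled pairs with positive
#'   sign.
#' @param noise_sd SD of the lognormal (log2-scale normal) expression noise on
#'   coupled partners.
#' @param hi_fraction marginal fraction of coding genes labeled
#'   haploinsufficient.
#' @param hi_bidirectional_odds odds multiplier for a bidirectional-bearing
#'   gene to be haploinsufficient (1 = planted independence).
#' @param housekeeping_fraction fraction of genes labeled housekeeping,
#'   independent of haploinsufficiency.
#' @param n_decoys single-exon snoRNA/tRNA decoy transcripts exercising the
#'   splicing/biotype filters.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length = 10000000L,
                              n_coding_genes = 200L,
                              n_bidirectional = 20L,
                              n_antisense = 20L,
                              n_intergenic = 20L,
                              bidirectional_offset_range = c(100L, 2700L),
                              antisense_overlap_fraction = 1,
                              intergenic_min_distance = 15000L,
                              stages = c("E10.5", "E13.5", "adult"),
                              selectivity_fraction = 2/3,
                              coupling_strength = 0.9,
                              coupling_positive_fraction = 0.5,
                              noise_sd = 0.2,
                              hi_fraction = 0.10,
                              hi_bidirectional_odds = 3,
                              housekeeping_fraction = 0.10,
                              n_decoys = 10L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_coding_genes = as.integer(n_coding_genes),
              n_bidirectional = as.integer(n_bidirectional),
              n_antisense = as.integer(n_antisense),
              n_intergenic = as.integer(n_intergenic),
              bidirectional_offset_range = as.integer(bidirectional_offset_range),
              antisense_overlap_fraction = antisense_overlap_fraction,
              intergenic_min_distance = as.integer(intergenic_min_distance),
              stages = stages,
              selectivity_fraction = selectivity_fraction,
              coupling_strength = coupling_strength,
              coupling_positive_fraction = coupling_positive_fraction,
              noise_sd = noise_sd,
              hi_fraction = hi_fraction,
              hi_bidirectional_odds = hi_bidirectional_odds,
              housekeeping_fraction = housekeeping_fraction,
              n_decoys = as.integer(n_decoys))
  with(cfg, stopifnot(
    n_chroms >= 1, n_coding_genes >= 0, n_bidirectional >= 0,
    n_antisense >= 0, n_intergenic >= 0,
    bidirectional_offset_range[1] >= 1,
    diff(bidirectional_offset_range) >= 0,
    antisense_overlap_fraction > 0, antisense_overlap_fraction <= 1,
    selectivity_fraction >= 0, selectivity_fraction <= 1,
    coupling_positive_fraction >= 0, coupling_positive_fraction <= 1,
    noise_sd >= 0, hi_fraction > 0, hi_fraction < 1,
    hi_bidirectional_odds > 0,
    housekeeping_fraction >= 0, housekeeping_fraction <= 1))
  if (cfg$n_bidirectional + cfg$n_antisense > cfg$n_coding_genes)
    stop("configuration error: more bidirectional+antisense lncRNAs than coding genes to host them")
  class(cfg) <- "simulation_config"
  cfg
}

#' Derive independent sub-stream seeds from a master seed
#'
#' Draws `n` seeds below 2^31 from a dedicated RNG stream keyed by `seed`,
#' restoring the caller's RNG state afterwards. Used to give placement,
#' expression and label simulation independent reproducible streams.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n = 3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# random integer composition: n parts summing to total, each >= minimum
rand_partition <- function(total, n, minimum) {
  if (n == 1) return(total)
  free <- total - n * minimum
  stopifnot(free >= 0)
  cuts <- sort(sample.int(free + n - 1, n - 1))
  parts <- diff(c(0L, cuts, free + n)) - 1L
  parts + minimum
}

# exon intervals for a transcript of span `len` starting at `start` with
# n_exons exons (alternating exon/intron partition)
make_exons <- function(start, len, n_exons, min_exon = 80L, min_intron = 100L) {
  if (n_exons == 1) return(data.frame(start = start, end = start + len))
  total_min <- n_exons * min_exon + (n_exons - 1) * min_intron
  stopifnot(len >= total_min)
  exon_len <- rand_partition(len - (n_exons - 1) * min_intron, n_exons, min_exon)
  intron_budget <- len - sum(exon_len) - (n_exons - 1) * min_intron
  # exon lengths already consume the slack; introns at minimum plus remainder
  intron_len <- rep(min_intron, n_exons - 1)
  if (intron_budget > 0) {
    add <- rand_partition(intron_budget, n_exons - 1, 0L)
    intron_len <- intron_len + add
  }
  s <- integer(n_exons); e <- integer(n_exons)
  pos <- start
  for (j in seq_len(n_exons)) {
    s[j] <- pos
    e[j] <- pos + exon_len[j]
    pos <- e[j] + if (j < n_exons) intron_len[j] else 0L
  }
  data.frame(start = s, end = e)
}

#' Simulate a genome annotation with planted lncRNA classes
#'
#' Places coding genes on a fixed slot grid and plants lncRNAs per class with
#' geometric margins: bidirectional lncRNAs on the opposite strand, divergent,
#' with a TSS gap inside `bidirectional_offset_range`; antisense lncRNAs
#' overlapping their host gene's span on the opposite strand with their TSS
#' well away (> 3300 bp) from any coding TSS; intergenic lncRNAs at least
#' `intergenic_min_distance` from any coding gene. All lncRNAs are spliced
#' (2-4 exons) with `cds_length = 0`. Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @return list with `annotation` (a [genome_annotation()]) and `truth` (list
#'   with `lnc` and `genes` data.frames of planted labels).
#' @export
simulate_annotation <- function(config = simulation_config()) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[1])

  n_slots <- config$n_coding_genes + config$n_intergenic + config$n_decoys
  per_chrom <- ceiling(n_slots / config$n_chroms)
  if (per_chrom * SLOT_WIDTH > config$chrom_length)
    stop("configuration error: chromosome too short for the requested gene count")
  slot_chrom <- paste0("chr", rep(seq_len(config$n_chroms), each = per_chrom))[seq_len(n_slots)]
  slot_start <- rep(SLOT_WIDTH * (seq_len(per_chrom) - 1L), config$n_chroms)[seq_len(n_slots)]

  coding_slots <- seq_len(config$n_coding_genes)
  intergenic_slots <- seq_len(config$n_intergenic) + config$n_coding_genes
  decoy_slots <- seq_len(config$n_decoys) + config$n_coding_genes + config$n_intergenic

  tx_rows <- list(); ex_rows <- list()
  add_tx <- function(tid, gid, biotype, cds, exdf, chrom, strand) {
    tx_rows[[length(tx_rows) + 1]] <<- data.frame(
      transcript_id = tid, gene_id = gid, biotype = biotype,
      cds_length = cds, stringsAsFactors = FALSE)
    ex_rows[[length(ex_rows) + 1]] <<- data.frame(
      transcript_id = tid, chrom = chrom, start = exdf$start, end = exdf$end,
      strand = strand, stringsAsFactors = FALSE)
  }

  # --- coding genes: length 6-12 kb, 4-12 exons, CDS ~70% of exonic length
  coding <- data.frame(gene_id = sprintf("pcg%04d", coding_slots),
                       chrom = slot_chrom[coding_slots],
                       start = NA_integer_, end = NA_integer_,
                       strand = sample(c("+", "-"), config$n_coding_genes,
                                       replace = TRUE),
                       stringsAsFactors = FALSE)
  for (i in seq_len(config$n_coding_genes)) {
    len <- as.integer(round(stats::runif(1, 6000, 12000)))
    nex <- sample(4:12, 1)
    gs <- slot_start[coding_slots[i]] + GENE_OFFSET
    exdf <- make_exons(gs, len, nex, min_exon = 150L, min_intron = 200L)
    coding$start[i] <- gs
    coding$end[i] <- gs + len
    cds <- as.integer(floor(0.7 * sum(exdf$end - exdf$start)))
    add_tx(paste0(coding$gene_id[i], ".t1"), coding$gene_id[i],
           "protein_coding", cds, exdf, coding$chrom[i], coding$strand[i])
  }
  coding_tss <- ifelse(coding$strand == "+", coding$start, coding$end)

  # --- assign host coding genes for bidirectional and antisense lncRNAs
  hosts <- sample(config$n_coding_genes, config$n_bidirectional + config$n_antisense)
  bid_hosts <- hosts[seq_len(config$n_bidirectional)]
  anti_hosts <- setdiff(hosts, bid_hosts)

  lnc <- data.frame(transcript_id = character(0), gene_id = character(0),
                    class = character(0), partner_gene_id = character(0),
                    stringsAsFactors = FALSE)
  lnc_counter <- 0L
  add_lnc <- function(class, partner, chrom, strand, exdf) {
    lnc_counter <<- lnc_counter + 1L
    gid <- sprintf("lnc%04d", lnc_counter)
    tid <- paste0(gid, ".t1")
    add_tx(tid, gid, "lncRNA_candidate", 0L, exdf, chrom, strand)
    lnc[nrow(lnc) + 1L, ] <<- list(tid, gid, class, partner)
  }

  # bidirectional: opposite strand, divergent, TSS gap in offset range
  for (h in bid_hosts) {
    gap <- as.integer(round(stats::runif(1, config$bidirectional_offset_range[1],
                                         config$bidirectional_offset_range[2])))
    len <- as.integer(round(stats::runif(1, 1500, 4000)))
    nex <- sample(2:4, 1)
    if (coding$strand[h] == "+") {
      # lncRNA on '-', TSS (= span end) gap bp left of the gene's TSS
      lstart <- coding_tss[h] - gap - len
      lnc_strand <- "-"
    } else {
      lstart <- coding_tss[h] + gap
      lnc_strand <- "+"
    }
    exdf <- make_exons(lstart, len, nex)
    add_lnc("bidirectional", coding$gene_id[h], coding$chrom[h], lnc_strand, exdf)
  }

  # antisense: opposite strand, overlaps host span, TSS far from coding TSSs;
  # overhang (1 - overlap_fraction) exits via the end away from the host TSS
  for (h in anti_hosts) {
    len <- as.integer(round(stats::runif(1, 1500, 3500)))
    nex <- sample(2:4, 1)
    over <- as.integer(round(config$antisense_overlap_fraction * len))
    over <- max(over, 1L)
    if (coding$strand[h] == "+") {
      lend <- coding$end[h] + (len - over)
      lstart <- lend - len
      lnc_strand <- "-"
    } else {
      lstart <- coding$start[h] - (len - over)
      lnc_strand <- "+"
    }
    exdf <- make_exons(lstart, len, nex)
    add_lnc("antisense", coding$gene_id[h], coding$chrom[h], lnc_strand, exdf)
  }

  # intergenic: own slot, far from every coding gene
  for (s in intergenic_slots) {
    len <- as.integer(round(stats::runif(1, 1500, 4000)))
    nex <- sample(2:4, 1)
    lstart <- slot_start[s] + 22000L
    exdf <- make_exons(lstart, len, nex)
    add_lnc("intergenic", NA_character_, slot_chrom[s],
            sample(c("+", "-"), 1), exdf)
  }

  # decoys: single-exon snoRNA/tRNA in their own slots
  for (j in seq_along(decoy_slots)) {
    s <- decoy_slots[j]
    gid <- sprintf("decoy%03d", j)
    len <- as.integer(round(stats::runif(1, 100, 300)))
    exdf <- data.frame(start = slot_start[s] + 22000L,
                       end = slot_start[s] + 22000L + len)
    add_tx(paste0(gid, ".t1"), gid, sample(c("snoRNA", "tRNA"), 1), 0L, exdf,
           slot_chrom[s], sample(c("+", "-"), 1))
  }

  # planted selectivity and coupling signs
  n_lnc <- nrow(lnc)
  sel_idx <- sample(n_lnc, round(config$selectivity_fraction * n_lnc))
  lnc$selective <- seq_len(n_lnc) %in% sel_idx
  lnc$coupling_sign <- 0L
  is_bid <- lnc$class == "bidirectional"
  lnc$coupling_sign[is_bid] <- ifelse(
    stats::runif(sum(is_bid)) < config$coupling_positive_fraction, 1L, -1L)

  annotation <- genome_annotation(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
  genes_truth <- data.frame(
    gene_id = coding$gene_id,
    has_bidirectional = coding$gene_id %in% lnc$partner_gene_id[is_bid],
    stringsAsFactors = FALSE)
  list(annotation = annotation,
       truth = list(lnc = lnc, genes = genes_truth, seed = config$seed))
}

#' Simulate the expression matrix over the tissue/stage grid
#'
#' Samples: heart and brain at each developmental stage plus adult kidney and
#' liver. lncRNA fpkm is drawn at a lower scale than coding fpkm; planted
#' heart-selective lncRNAs peak between 1.5 and 8 fpkm in at least one heart
#' stage and stay below 0.5 fpkm in every brain sample (a >= 50% margin on
#' the fpkm-1 threshold in both directions); non-selective lncRNAs are
#' expressed in brain too. For each planted divergent pair, the partner gene's
#' heart log2 fpkm follows `sign * strength * (lncRNA log2 deviation)` plus
#' normal noise (SD `noise_sd`), i.e. lognormal noise on fpkm.
#'
#' @param annotation,truth output of [simulate_annotation()].
#' @param config the same [simulation_config()].
#' @return an [expr_matrix()].
#' @export
simulate_expression <- function(annotation, truth, config = simulation_config()) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[2])
  stages <- config$stages
  samples <- c(paste0("heart_", stages), paste0("brain_", stages),
               "kidney_adult", "liver_adult")
  tx <- annotation$transcripts
  ids <- tx$transcript_id
  v <- matrix(0, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  heart_cols <- paste0("heart_", stages)
  brain_cols <- paste0("brain_", stages)

  lnc <- truth$lnc
  partner_of <- stats::setNames(lnc$partner_gene_id, lnc$transcript_id)
  coupled_partner <- lnc$partner_gene_id[lnc$class == "bidirectional"]

  # --- lncRNAs: stage-graded heart profile, selectivity margins
  lnc_heart_log2 <- matrix(0, nrow(lnc), length(stages),
                           dimnames = list(lnc$transcript_id, NULL))
  for (i in seq_len(nrow(lnc))) {
    peak <- if (lnc$selective[i]) stats::runif(1, 1.5, 8) else stats::runif(1, 1.5, 12)
    d <- stats::runif(1, 0.8, 1.5)
    prof <- log2(peak) - d * (sample(3) - 1)   # one stage at the peak
    lnc_heart_log2[i, ] <- prof
    v[lnc$transcript_id[i], heart_cols] <- 2^prof
    if (lnc$selective[i]) {
      v[lnc$transcript_id[i], brain_cols] <- stats::runif(3, 0.05, 0.5)
      kid <- stats::runif(1) < 0.25
      liv <- stats::runif(1) < 0.25
      v[lnc$transcript_id[i], "kidney_adult"] <-
        if (kid) stats::runif(1, 1.5, 6) else stats::runif(1, 0.05, 0.5)
      v[lnc$transcript_id[i], "liver_adult"] <-
        if (liv) stats::runif(1, 1.5, 6) else stats::runif(1, 0.05, 0.5)
    } else {
      v[lnc$transcript_id[i], brain_cols] <- stats::runif(3, 1.5, 6)
      v[lnc$transcript_id[i], "kidney_adult"] <- stats::runif(1, 0.05, 6)
      v[lnc$transcript_id[i], "liver_adult"] <- stats::runif(1, 0.05, 6)
    }
  }

  # --- coding genes
  coding_tx <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  for (i in seq_len(nrow(coding_tx))) {
    gid <- coding_tx$gene_id[i]
    tid <- coding_tx$transcript_id[i]
    if (gid %in% coupled_partner) {
      li <- which(lnc$partner_gene_id == gid & lnc$class == "bidirectional")[1]
      sgn <- lnc$coupling_sign[li]
      z <- lnc_heart_log2[li, ] - mean(lnc_heart_log2[li, ])
      mu <- stats::rnorm(1, log2(25), 0.8)
      v[tid, heart_cols] <- 2^(mu + sgn * config$coupling_strength * z +
                                 stats::rnorm(length(z), 0, config$noise_sd))
    } else {
      base <- 2^stats::rnorm(1, log2(30), 1.2)
      v[tid, heart_cols] <- base * 2^stats::rnorm(length(heart_cols), 0, 0.4)
    }
    v[tid, brain_cols] <- stats::runif(3, 5, 50)
    v[tid, c("kidney_adult", "liver_adult")] <- stats::runif(2, 5, 50)
  }

  # --- decoys: heart-expressed so only the splicing/biotype filters drop them
  decoy_tx <- tx$transcript_id[tx$biotype %in% c("snoRNA", "tRNA")]
  if (length(decoy_tx) > 0) {
    v[decoy_tx, heart_cols] <- matrix(stats::runif(3 * length(decoy_tx), 2, 20),
                                      ncol = 3)
    v[decoy_tx, brain_cols] <- matrix(stats::runif(3 * length(decoy_tx), 2, 20),
                                      ncol = 3)
  }
  expr_matrix(v)
}

#' Simulate haploinsufficiency and housekeeping gene labels
#'
#' Assigns the haploinsufficient flag so that genes carrying a bidirectional
#' lncRNA have their odds multiplied by `hi_bidirectional_odds`, while the
#' marginal haploinsufficient fraction matches `hi_fraction` in expectation
#' (the baseline probability is solved numerically). Housekeeping flags are
#' drawn independently of haploinsufficiency.
#'
#' @param truth output of [simulate_annotation()] (`$truth`), or any list with
#'   a `genes` data.frame containing `gene_id` and `has_bidirectional`.
#' @param config a [simulation_config()]; only the label parameters and seed
#'   are used.
#' @return the `genes` table with logical `haploinsufficient` and
#'   `housekeeping` columns.
#' @export
simulate_gene_labels <- function(truth, config = simulation_config()) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[3])
  genes <- truth$genes
  if (is.null(genes) || nrow(genes) == 0)
    stop("argument error: truth carries no gene table")
  fb <- mean(genes$has_bidirectional)
  omega <- config$hi_bidirectional_odds
  target <- config$hi_fraction
  marg <- function(p0) {
    o0 <- p0 / (1 - p0)
    p1 <- omega * o0 / (1 + omega * o0)
    fb * p1 + (1 - fb) * p0 - target
  }
  root <- tryCatch(stats::uniroot(marg, c(1e-12, 1 - 1e-12))$root,
                   error = function(e)
                     stop("configuration error: requested odds/fraction unattainable"))
  p0 <- root
  o0 <- p0 / (1 - p0)
  p1 <- omega * o0 / (1 + omega * o0)
  p <- ifelse(genes$has_bidirectional, p1, p0)
  genes$haploinsufficient <- stats::runif(nrow(genes)) < p
  genes$housekeeping <- stats::runif(nrow(genes)) < config$housekeeping_fraction
  genes
}

#' Simulate a stand-alone enrichment study (labels only)
#'
#' Convenience generator for calibration/power studies of the
#' haploinsufficiency enrichment without genome placement: `n_genes` genes get
#' a bidirectional flag at `bid_fraction`, then haploinsufficient/housekeeping
#' labels via [simulate_gene_labels()].
#'
#' @param n_genes,bid_fraction population size and bidirectional baseline.
#' @param hi_fraction,hi_bidirectional_odds,housekeeping_fraction,seed passed
#'   into the label model.
#' @return gene table with `has_bidirectional`, `haploinsufficient`,
#'   `housekeeping`.
#' @export
simulate_enrichment_study <- function(n_genes = 2000L, bid_fraction = 0.15,
                                      hi_fraction = 0.10,
                                      hi_bidirectional_odds = 3,
                                      housekeeping_fraction = 0.10,
                                      seed = 1L) {
  cfg <- simulation_config(seed = seed, hi_fraction = hi_fraction,
                           hi_bidirectional_odds = hi_bidirectional_odds,
                           housekeeping_fraction = housekeeping_fraction)
  seeds <- derive_seeds(seed)
  set.seed(seeds[1])
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      has_bidirectional = stats::runif(n_genes) < bid_fraction,
                      stringsAsFactors = FALSE)
  simulate_gene_labels(list(genes = genes), cfg)
}

#' Write a full synthetic bundle to disk
#'
#' Writes `annotation.gtf`, `expression.tsv`, `gene_labels.tsv` and
#' `truth.json` under `dir`, loadable by [run_pipeline()] without edits.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return invisible list of paths plus the in-memory objects.
#' @export
simulate_bundle <- function(config = simulation_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_annotation(config)
  mat <- simulate_expression(sim$annotation, sim$truth, config)
  labels <- simulate_gene_labels(sim$truth, config)
  paths <- list(annotation_gtf = file.path(dir, "annotation.gtf"),
                expression_tsv = file.path(dir, "expression.tsv"),
                gene_labels_tsv = file.path(dir, "gene_labels.tsv"),
                truth_json = file.path(dir, "truth.json"))
  write_gtf(sim$annotation, paths$annotation_gtf)
  write_expression_tsv(mat, paths$expression_tsv)
  write_gene_labels(labels, paths$gene_labels_tsv)
  jsonlite::write_json(sim$truth, paths$truth_json, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, list(annotation = sim$annotation, truth = sim$truth,
                          matrix = mat, labels = labels)))
}

#' Write / read gene label tables
#' @param labels gene table with logical flag columns.
#' @param path TSV path.
#' @export
write_gene_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_gene_labels
#' @export
read_gene_labels <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in intersect(c("has_bidirectional", "haploinsufficient", "housekeeping"),
                        names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Simulate reference/assembled annotation pairs with exon truncation
#'
#' Ground-truth generator for the assembly-fidelity QC: reference genes carry
#' 6-12 exons (plus `n_excluded` genes above the 12-exon cap, to be excluded);
#' the "assembled" counterpart loses exons according to a Poisson draw with
#' mean `a * exp(-b * fpkm)`, emulating reconstruction error that decays with
#' coverage.
#'
#' @param n_genes genes under the exon cap.
#' @param a,b generating exponential parameters.
#' @param fpkm_max per-gene fpkm drawn uniformly on (0, `fpkm_max`].
#' @param n_excluded extra genes with reference exon number above 12.
#' @param seed RNG seed.
#' @return list with `reference`, `assembled` (annotations), `matrix`
#'   (an [expr_matrix()]) and `params`.
#' @export
simulate_truncated_assembly <- function(n_genes = 500L, a = 3, b = 0.5,
                                        fpkm_max = 10, n_excluded = 20L,
                                        seed = 1L) {
  set.seed(seed)
  total <- n_genes + n_excluded
  ref_ex <- c(sample(6:12, n_genes, replace = TRUE),
              sample(13:16, n_excluded, replace = TRUE))
  fpkm <- stats::runif(total, 0.01, fpkm_max)
  lost <- pmin(stats::rpois(total, a * exp(-b * fpkm)), ref_ex - 1L)
  asm_ex <- ref_ex - lost

  build <- function(nex_vec) {
    txs <- list(); exs <- list()
    pos <- 0L
    for (i in seq_len(total)) {
      gid <- sprintf("qg%04d", i)
      len <- nex_vec[i] * 200L + max(nex_vec[i] - 1L, 0L) * 300L
      exdf <- make_exons(pos, len, nex_vec[i], min_exon = 150L, min_intron = 200L)
      txs[[i]] <- data.frame(transcript_id = paste0(gid, ".t1"), gene_id = gid,
                             biotype = "protein_coding",
                             cds_length = 0L, stringsAsFactors = FALSE)
      exs[[i]] <- data.frame(transcript_id = paste0(gid, ".t1"), chrom = "chr1",
                             start = exdf$start, end = exdf$end, strand = "+",
                             stringsAsFactors = FALSE)
      pos <- pos + len + 5000L
    }
    genome_annotation(do.call(rbind, txs), do.call(rbind, exs))
  }
  reference <- build(ref_ex)
  assembled <- build(asm_ex)
  v <- cbind(heart_E10.5 = fpkm * stats::runif(total, 0.3, 1),
             heart_E13.5 = fpkm * stats::runif(total, 0.3, 1),
             heart_adult = fpkm)
  rownames(v) <- sprintf("qg%04d.t1", seq_len(total))
  list(reference = reference, assembled = assembled,
       matrix = expr_matrix(v), params = list(a = a, b = b))
}
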