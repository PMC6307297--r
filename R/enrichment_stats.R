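# Inferential statistics: Mann-Whitney distance comparisons, hypergeometric
# enrichment (upper tail), Fisher control, and generic gene-set enrichment
# with Benjamini-Hochberg adjustment.

#' Mann-Whitney U test (two-sided)
#'
#' Wraps the standard Wilcoxon rank-sum machinery: the exact null distribution
#' is used when the combined sample size is at most 16 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list of class `rank_test_result` with `U` (the Mann-Whitney
#'   statistic for `group_a`), `p` (two-sided), `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("argument error: both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 16 && !ties
  wt <- stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal_approx_tie_corrected",
                 n1 = length(group_a), n2 = length(group_b)),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}

#' Hypergeometric enrichment (upper tail)
#'
#' Probability of observing at least `k` successes in `n` draws without
#' replacement from a population of `N` containing `K` successes:
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' The odds ratio comes from the implied 2x2 table, with a Haldane 0.5
#' correction when any cell is zero.
#'
#' @param N population size.
#' @param K population successes.
#' @param n sample size.
#' @param k sample successes.
#' @return list of class `enrichment_result` with the counts, `tail_p` and
#'   `odds_ratio`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n - (N - K)))
    stop("argument error: inconsistent hypergeometric counts")
  tail_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; c_ <- K - k; d <- (N - K) - (n - k)
  if (min(a, b, c_, d) == 0) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  structure(list(N = N, K = K, n = n, k = k, tail_p = tail_p,
                 odds_ratio = (a * d) / (b * c_)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: k=%d of n=%d vs K=%d of N=%d; P(X>=k)=%.4g, OR=%.3g\n",
              x$k, x$n, x$K, x$N, x$tail_p, x$odds_ratio))
  invisible(x)
}

#' Enrichment of bidirectional-lncRNA-bearing genes among haploinsufficient genes
#'
#' Tests whether genes carrying a bidirectional (divergent) lncRNA are
#' over-represented among haploinsufficient genes: population = all genes,
#' population successes = genes with a bidirectional lncRNA, sample =
#' haploinsufficient genes, sample successes = haploinsufficient genes with a
#' bidirectional lncRNA. Upper-tail hypergeometric probability.
#'
#' @param gene_table data.frame with logical columns `has_bidirectional` and
#'   `haploinsufficient`.
#' @return an `enrichment_result` (see [hypergeometric_enrichment()]).
#' @export
bidirectional_hi_enrichment <- function(gene_table) {
  if (nrow(gene_table) == 0) stop("argument error: empty gene table")
  stopifnot(is.logical(gene_table$has_bidirectional),
            is.logical(gene_table$haploinsufficient))
  hypergeometric_enrichment(
    N = nrow(gene_table),
    K = sum(gene_table$has_bidirectional),
    n = sum(gene_table$haploinsufficient),
    k = sum(gene_table$has_bidirectional & gene_table$haploinsufficient))
}

#' Housekeeping-gene control for the haploinsufficiency enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table of housekeeping x
#' haploinsufficient flags. Under the confounding scenario the enrichment of
#' bidirectional lncRNAs among haploinsufficient genes would be mirrored by a
#' housekeeping association; a non-significant result supports the specific
#' claim.
#'
#' @param gene_table data.frame with logical columns `housekeeping` and
#'   `haploinsufficient`.
#' @return two-sided p-value.
#' @export
proportion_control <- function(gene_table) {
  if (nrow(gene_table) == 0) stop("argument error: empty gene table")
  tab <- table(factor(gene_table$housekeeping, levels = c(FALSE, TRUE)),
               factor(gene_table$haploinsufficient, levels = c(FALSE, TRUE)))
  stats::fisher.test(tab)$p.value
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each term, tests over-representation of the query genes in the term's
#' gene set by an upper-tail hypergeometric probability, then adjusts across
#' terms by Benjamini-Hochberg. Output is sorted by raw p-value, mirroring a
#' GO-style enrichment table (term, count, %, p, FDR).
#'
#' @param query_genes character vector (must be a subset of `universe`).
#' @param gene_sets named list: term -> character vector of gene ids. Sets are
#'   intersected with the universe.
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with `term`, `count` (query genes in set), `set_size`,
#'   `pct` (100 * count / query size), `p`, `q`, `odds_ratio`.
#' @export
gene_set_enrichment <- function(query_genes, gene_sets, universe) {
  if (length(universe) == 0) stop("argument error: empty universe")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("argument error: query genes must be a subset of the universe")
  N <- length(universe); n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    k <- length(intersect(query_genes, set))
    e <- hypergeometric_enrichment(N, length(set), n, k)
    data.frame(term = term, count = k, set_size = length(set),
               pct = if (n > 0) 100 * k / n else 0,
               p = e$tail_p, odds_ratio = e$odds_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), c("term", "count", "set_size", "pct",
                                       "p", "q", "odds_ratio")]
  rownames(out) <- NULL
  out
}

#' Uniformized PIT of discrete enrichment p-values
#'
#' p-values of exact tests on discrete data are sub-uniform under the null
#' (they carry point masses, so `E[p] > 0.5`). The probability integral
#' transform smoothed over the observed point mass,
#' `P(p < p_obs) + U * P(p = p_obs)` with `U ~ Uniform(0,1)`, is exactly
#' Uniform(0,1) when the assumed null distribution is correct, and is the
#' quantity a calibration study should test for uniformity.
#'
#' `hypergeom_tail_pit` smooths the upper-tail hypergeometric p of
#' [hypergeometric_enrichment()]; `fisher_two_sided_pit` smooths the two-sided
#' Fisher p of [proportion_control()] by enumerating the conditional (fixed
#' margins) null over the hypergeometric support.
#'
#' @param N,K,n,k hypergeometric counts (see [hypergeometric_enrichment()]).
#' @param u smoothing uniform draw(s) on (0,1).
#' @return smoothed PIT value in (0,1).
#' @export
hypergeom_tail_pit <- function(N, K, n, k, u = stats::runif(1)) {
  stats::phyper(k, K, N - K, n, lower.tail = FALSE) +
    u * stats::dhyper(k, K, N - K, n)
}

#' @rdname hypergeom_tail_pit
#' @param gene_table as in [proportion_control()].
#' @export
fisher_two_sided_pit <- function(gene_table, u = stats::runif(1)) {
  N <- nrow(gene_table)
  K <- sum(gene_table$housekeeping)
  n <- sum(gene_table$haploinsufficient)
  k <- sum(gene_table$housekeeping & gene_table$haploinsufficient)
  support <- max(0, n - (N - K)):min(K, n)
  d <- stats::dhyper(support, K, N - K, n)
  # two-sided p at each support point: total mass of outcomes no more likely
  # (same relative tolerance as fisher.test)
  p_at <- vapply(d, function(di) sum(d[d <= di * (1 + 1e-7)]), 0)
  d_obs <- stats::dhyper(k, K, N - K, n)
  p_obs <- sum(d[d <= d_obs * (1 + 1e-7)])
  sum(d[p_at < p_obs * (1 - 1e-7)]) +
    u * sum(d[abs(p_at - p_obs) <= p_obs * 1e-7])
}

#' Null-calibration study of the enrichment statistics
#'
#' Simulates label studies with planted independence
#' (`hi_bidirectional_odds = 1`, housekeeping independent of
#' haploinsufficiency) and collects, per seed, the raw p-values of the
#' haploinsufficiency enrichment and the housekeeping Fisher control together
#' with their uniformized PITs (see [hypergeom_tail_pit()]). Under a correct
#' implementation the PITs are exactly Uniform(0,1) and the raw p-values reject
#' at close to (never above, in expectation) the nominal level.
#'
#' @param n_seeds number of simulated studies.
#' @param n_genes,bid_fraction,hi_fraction,housekeeping_fraction study size and
#'   label fractions (see [simulate_enrichment_study()]).
#' @param seed base seed; study `i` uses `seed + i`.
#' @return data.frame with `p_enrich`, `pit_enrich`, `p_fisher`, `pit_fisher`.
#' @export
calibrate_null_enrichment <- function(n_seeds = 200, n_genes = 2000,
                                      bid_fraction = 0.15, hi_fraction = 0.10,
                                      housekeeping_fraction = 0.10, seed = 1) {
  out <- matrix(NA_real_, n_seeds, 4,
                dimnames = list(NULL, c("p_enrich", "pit_enrich",
                                        "p_fisher", "pit_fisher")))
  for (i in seq_len(n_seeds)) {
    g <- simulate_enrichment_study(n_genes, bid_fraction, hi_fraction,
                                   hi_bidirectional_odds = 1,
                                   housekeeping_fraction = housekeeping_fraction,
                                   seed = seed + i)
    e <- bidirectional_hi_enrichment(g)
    set.seed(seed + i)
    u <- stats::runif(2)
    out[i, "p_enrich"] <- e$tail_p
    out[i, "pit_enrich"] <- hypergeom_tail_pit(e$N, e$K, e$n, e$k, u[1])
    out[i, "p_fisher"] <- proportion_control(g)
    out[i, "pit_fisher"] <- fisher_two_sided_pit(g, u[2])
  }
  as.data.frame(out)
}
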