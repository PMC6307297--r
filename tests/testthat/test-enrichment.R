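test_that("Mann-Whitney exact path reproduces the worked example and enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1/3)
  expect_equal(r$method, "exact")
  # random small groups vs full-labeling enumeration
  set.seed(101)
  for (i in 1:25) {
    a <- round(rnorm(sample(2:8, 1)), 6)
    b <- round(rnorm(sample(2:8, 1)), 6)
    expect_equal(mann_whitney(a, b)$p, enum_mw_p(a, b))
  }
})

test_that("Mann-Whitney is symmetric and handles ties via the approx path", {
  set.seed(5)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  tied <- mann_whitney(c(1, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(tied$method, "normal_approx_tie_corrected")
  expect_true(tied$p > 0.3)  # near-identical groups
  # identical large groups: p close to 1
  x <- rnorm(40)
  expect_gt(mann_whitney(x, x)$p, 0.9)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact and normal-approx Mann-Whitney p agree closely at n=8+8", {
  set.seed(6)
  for (i in 1:30) {
    a <- rnorm(8); b <- rnorm(8, runif(1, -1, 1))
    p_exact <- mann_whitney(a, b)$p
    p_approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.03)
  }
})

test_that("hypergeometric upper tail matches the combinatorial sum", {
  r <- hypergeometric_enrichment(N = 10, K = 4, n = 5, k = 4)
  expect_equal(r$tail_p, 6 / 252)  # C(4,4)*C(6,1)/C(10,5)
  expect_equal(r$tail_p, hyper_tail_oracle(10, 4, 5, 4))
  # random configurations against the lchoose oracle
  set.seed(11)
  for (i in 1:30) {
    N <- sample(20:500, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    got <- hypergeometric_enrichment(N, K, n, k)$tail_p
    want <- hyper_tail_oracle(N, K, n, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail edge cases and monotonicity hold", {
  expect_equal(hypergeometric_enrichment(100, 30, 20, 0)$tail_p, 1)
  # monotone decreasing in k
  ps <- vapply(0:10, function(k)
    hypergeometric_enrichment(100, 30, 10, k)$tail_p, 0)
  expect_true(all(diff(ps) < 0))
  # inconsistent counts rejected
  expect_error(hypergeometric_enrichment(10, 12, 5, 3), "inconsistent")
  expect_error(hypergeometric_enrichment(10, 4, 5, 5), "inconsistent")
  # odds ratio uses Haldane correction on zero cells (finite, positive)
  or0 <- hypergeometric_enrichment(100, 30, 10, 0)$odds_ratio
  expect_true(is.finite(or0) && or0 > 0)
})

test_that("hypergeometric tail agrees with Monte-Carlo resampling", {
  set.seed(12)
  N <- 200; K <- 50; n <- 40; k <- 16
  p <- hypergeometric_enrichment(N, K, n, k)$tail_p
  draws <- stats::rhyper(50000, K, N - K, n)
  mc <- mean(draws >= k)
  expect_lt(abs(p - mc), 3 * sqrt(p * (1 - p) / 50000))
})

test_that("Fisher control matches exact enumeration of the 2x2 table", {
  even <- data.frame(housekeeping = rep(c(TRUE, FALSE), each = 20),
                     haploinsufficient = rep(c(TRUE, FALSE), 20))
  expect_equal(proportion_control(even), 1)
  # [[8,2],[2,8]] example: compare against dhyper enumeration
  gt <- data.frame(housekeeping = rep(c(TRUE, TRUE, FALSE, FALSE),
                                      c(8, 2, 2, 8)),
                   haploinsufficient = rep(c(TRUE, FALSE, TRUE, FALSE),
                                           c(8, 2, 2, 8)))
  got <- proportion_control(gt)
  support <- 0:10
  d <- dhyper(support, 10, 10, 10)
  want <- sum(d[d <= dhyper(8, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(got, want)
})

test_that("BH adjustment equals the independent step-up oracle", {
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  }
  # q >= p always, and q is monotone in the p-ordering
  p <- runif(30)
  q <- bh_oracle(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("gene_set_enrichment ranks the exact query set first with BH q-values", {
  universe <- sprintf("g%03d", 1:100)
  query <- universe[1:10]
  sets <- list(exact = query,
               half = universe[6:25],
               unrelated = universe[51:70])
  out <- gene_set_enrichment(query, sets, universe)
  expect_equal(out$term[1], "exact")
  expect_equal(out$count[out$term == "exact"], 10L)
  expect_equal(out$pct[out$term == "exact"], 100)
  expect_equal(out$q, bh_oracle(out$p))  # rows are sorted by p
  expect_error(gene_set_enrichment(c("zzz"), sets, universe), "subset")
})

test_that("bidirectional_hi_enrichment assembles the 2x2 counts correctly", {
  gt <- data.frame(has_bidirectional = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                   haploinsufficient = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  r <- bidirectional_hi_enrichment(gt)
  expect_equal(c(r$N, r$K, r$n, r$k), c(5, 3, 3, 2))
  expect_equal(r$tail_p, hyper_tail_oracle(5, 3, 3, 2))
})

test_that("uniformized PIT of discrete p-values is exactly uniform", {
  # analytic check on a small hypergeometric: PIT at each support point with
  # U ~ Unif spans contiguous intervals covering (0,1)
  N <- 12; K <- 5; n <- 4
  support <- max(0, n - (N - K)):min(K, n)
  lo <- vapply(support, function(k) hypergeom_tail_pit(N, K, n, k, 0), 0)
  hi <- vapply(support, function(k) hypergeom_tail_pit(N, K, n, k, 1), 0)
  o <- order(lo)
  expect_equal(min(lo), 0, tolerance = 1e-12)
  expect_equal(max(hi), 1, tolerance = 1e-12)
  expect_equal(lo[o][-1], hi[o][-length(hi)], tolerance = 1e-12)
  # and the interval widths equal the point masses
  expect_equal(hi - lo, dhyper(support, K, N - K, n), tolerance = 1e-12)
})
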