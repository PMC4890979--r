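test_that("hypergeometric p matches hand-checkable configurations", {
  u <- sprintf("x%02d", 1:10)
  # all 5 query genes inside a 5-gene term: only 1 of C(10,5) draws
  expect_equal(hypergeom_test(u[1:5], u[1:5], u), 1 / choose(10, 5))
  # zero overlap -> upper tail covers the whole sample space
  expect_equal(hypergeom_test(u[1:5], u[6:10], u), 1)
  # query = universe forces k = K, still p = 1
  expect_equal(hypergeom_test(u, u[1:4], u), 1)
  expect_error(hypergeom_test(c(u[1], "zz"), u[1:2], u), "outside")
  expect_error(hypergeom_test(u[1:2], c(u[1], "zz"), u), "outside")
})

test_that("hypergeometric p equals the enumeration oracle for small universes", {
  for (N in c(5, 7, 9)) {
    u <- sprintf("x%02d", 1:N)
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        term <- u[1:K]
        for (k in max(0, n - (N - K)):min(K, n)) {
          query <- c(u[seq_len(k)], u[K + seq_len(n - k)])
          expect_equal(hypergeom_test(query, term, u),
                       hyper_enum_p(N, K, n, k),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric p is non-increasing in the overlap", {
  u <- sprintf("x%03d", 1:100)
  term <- u[1:20]
  ps <- vapply(0:15, function(k) {
    query <- c(u[seq_len(k)], u[20 + seq_len(15 - k)])
    hypergeom_test(query, term, u)
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("rank-sum enrichment matches enumeration and permutation oracles", {
  genes <- sprintf("g%02d", 1:5)
  ranked <- ranked_from_scores(stats::setNames(5:1, genes))
  # members at ranks {1,2}: U maximal = n1*n2 = 6
  rs <- rank_set_test(ranked, genes[1:2])
  expect_equal(rs$U, 6)
  # exact two-sided p by enumerating all C(5,2) = 10 placements
  us <- apply(utils::combn(5, 2), 2, function(idx) {
    sum(outer(5 - idx + 1, 5 - setdiff(1:5, idx) + 1, ">"))
  })
  p_enum <- mean(abs(us - 3) >= abs(rs$U - 3))
  expect_equal(rs$p, p_enum)

  # symmetric interleaving: null-centred U = n1*n2/2
  g8 <- sprintf("g%02d", 1:8)
  r8 <- ranked_from_scores(stats::setNames(8:1, g8))
  mid <- rank_set_test(r8, g8[c(1, 4, 5, 8)])
  expect_equal(mid$U, 8)  # 4*4/2

  # larger case vs a permutation oracle at 10,000 draws
  n <- 60
  gl <- sprintf("g%03d", 1:n)
  withr::with_seed(21, scores <- rnorm(n))
  rl <- ranked_from_scores(stats::setNames(scores, gl))
  term <- rl$gene[c(1, 2, 15, 25, 35, 45, 50, 55)]
  obs <- rank_set_test(rl, term)
  perm <- withr::with_seed(22, {
    replicate(10000, {
      idx <- sample(n, 8)
      sc <- n - idx + 1
      sum(vapply(sc, function(s) sum(s > (n - setdiff(1:n, idx) + 1)), 0))
    })
  })
  p_perm <- mean(abs(perm - 8 * 52 / 2) >= abs(obs$U - 8 * 52 / 2))
  expect_lt(abs(obs$p - p_perm), 0.02)  # Monte-Carlo error bound

  expect_error(rank_set_test(ranked, "absent"), "strictly between")
  expect_error(rank_set_test(ranked, genes), "strictly between")
})

test_that("Bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.005, 3), 0.015)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.1, 0.02), 2), c(0.2, 0.04))
  expect_equal(bonferroni(0.3, 1), 0.3)
  p <- c(0.001, 0.2, 1)
  adj <- bonferroni(p, 10)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bonferroni(0.1, 0), "positive")
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
  expect_error(bonferroni(0, 5), "\\(0, 1\\]")
})

test_that("significance filter is boundary-inclusive and sorted", {
  res <- data.frame(term = c("a", "b", "c"), name = c("a", "b", "c"),
                    K = 5, n = 10, k = 2, U = NA_real_,
                    p_raw = c(0.02, 0.005, 0.01) / 3,
                    p_adj = c(0.02, 0.005, 0.01),
                    significant = c(FALSE, TRUE, TRUE))
  class(res) <- c("enrichment_result", "data.frame")
  kept <- filter_significant(res, 0.01)
  expect_equal(kept$term, c("b", "c"))   # 0.01 retained: <= is inclusive
  expect_equal(kept$p_adj, c(0.005, 0.01))
  expect_equal(nrow(filter_significant(res[0, ], 0.01)), 0L)
  res$p_adj <- rep(1, 3)
  expect_equal(nrow(filter_significant(res, 0.01)), 0L)
  expect_error(filter_significant(res, 0), "\\(0, 1\\]")
  expect_error(filter_significant(res, 1.5), "\\(0, 1\\]")
})

test_that("enrich_terms adjusts by the number of terms actually tested", {
  u <- sprintf("g%03d", 1:100)
  ranked <- ranked_from_scores(stats::setNames(100:1, u), u)
  sets <- list(hit = u[1:10], miss = u[51:70], other = u[31:50])
  col <- gene_set_collection(sets, u)
  res <- enrich_terms(col, ranked, query = u[1:10], alpha = 0.01)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adj, pmin(1, 3 * res$p_raw))
  hit <- res[res$term == "hit", ]
  expect_equal(hit$k, 10L)
  expect_true(hit$significant)
  expect_equal(hit$p_raw, hypergeom_test(u[1:10], u[1:10], u))
  # ranksum mode: a term covering the whole ranking is untestable
  col2 <- gene_set_collection(c(sets, list(all = u)), u)
  expect_message(res2 <- enrich_terms(col2, ranked, method = "ranksum"),
                 "whole ranking")
  expect_equal(nrow(res2), 3L)
  expect_false(is.na(res2$U[1]))
})
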