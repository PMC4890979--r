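test_that("log2 ratios follow the replicate-median construction", {
  # gene 1: control reps all 1, every stressed rep 2 -> r = 1
  # gene 2: stressed identical to control -> r = 0
  # gene 3: stressed reps {1,4,16} vs reference 1 -> log2 {0,2,4}, median 2
  vals <- rbind(c(1, 1, 1, 2, 2, 2),
                c(5, 5, 5, 5, 5, 5),
                c(1, 1, 1, 1, 4, 16))
  colnames(vals) <- c(paste0("c", 1:3), paste0("t", 1:3))
  co <- manual_cohort(vals, c("control", "3h"))
  r <- log2_ratio_matrix(co)
  expect_equal(unname(r[, "3h"]), c(1, 0, 2))
})

test_that("control reference is the per-gene median of control replicates", {
  vals <- matrix(c(2, 4, 8, 16, 16, 16), nrow = 1)  # ref = 4
  colnames(vals) <- c(paste0("c", 1:3), paste0("t", 1:3))
  co <- manual_cohort(vals, c("control", "12h"))
  expect_equal(unname(log2_ratio_matrix(co)[1, ]), 2)
})

test_that("degenerate inputs are rejected or dropped", {
  vals <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 1)
  colnames(vals) <- c(paste0("c", 1:3), paste0("t", 1:3))
  expect_error(manual_cohort(vals * 0, c("control", "3h")),
               "strictly positive")
  co <- manual_cohort(vals, c("control", "3h"))
  co$intensities[1, 1] <- NA
  expect_message(expect_error(log2_ratio_matrix(co), "no valid|positive|gene"),
                 "missing")
  # missing-value genes are dropped, others survive
  vals2 <- rbind(vals, vals * 2)
  colnames(vals2) <- colnames(vals)
  co2 <- manual_cohort(vals2, c("control", "3h"))
  co2$intensities[1, 4] <- NA
  r <- suppressMessages(log2_ratio_matrix(co2))
  expect_equal(nrow(r), 1L)
  expect_equal(rownames(r), "g02")
})

test_that("sum-squared statistic and ranking match the stated examples", {
  r <- rbind(a = c(1, -1, 2), b = c(0, 0, 0), c = c(3, 0, 0),
             d = c(1, 1, 1))
  colnames(r) <- c("3h", "12h", "24h")
  tab <- sum_squared_rank(r)
  expect_equal(tab$S[tab$gene == "a"], 6)
  expect_equal(tab$S[tab$gene == "b"], 0)
  expect_equal(tab$rank[tab$gene == "b"], 4L)   # all-zero ranks last
  expect_lt(tab$rank[tab$gene == "c"], tab$rank[tab$gene == "d"])  # 9 > 3
  expect_true(all(diff(tab$S) <= 0))
  expect_equal(sort(tab$rank), 1:4)
})

test_that("ties in S break lexicographically by gene id", {
  r <- rbind(zz = c(1, 0), aa = c(0, 1), mm = c(-1, 0))
  colnames(r) <- c("3h", "12h")
  tab <- sum_squared_rank(r)
  expect_equal(tab$gene, c("aa", "mm", "zz"))
})

test_that("ranking agrees with a brute-force oracle on random matrices", {
  for (n in c(10, 200, 1000)) {
    withr::with_seed(100 + n, {
      r <- matrix(rnorm(n * 3, sd = 2), nrow = n,
                  dimnames = list(sample(sprintf("g%04d", 1:n)),
                                  c("3h", "12h", "24h")))
    })
    # oracle: per-gene loop, then sort by (-S, id)
    S <- vapply(rownames(r), function(g) sum(r[g, ]^2), 0)
    oracle <- names(S)[order(-S, names(S), method = "radix")]
    expect_equal(sum_squared_rank(r)$gene, oracle)
  }
})

test_that("S is sign-flip invariant and monotone in |r|", {
  withr::with_seed(17, {
    r <- matrix(rnorm(60), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  })
  flip <- r * sample(c(-1, 1), length(r), replace = TRUE)
  expect_equal(sum_squared_rank(abs(r))$S, sum_squared_rank(flip)$S)
  bigger <- r * 1.5
  expect_true(all(sum_squared_rank(bigger)$S >= sum_squared_rank(r)$S))
})

test_that("top_k returns min(k, n) rows, highest S first", {
  withr::with_seed(3, {
    r <- matrix(rnorm(300), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  })
  tab <- sum_squared_rank(r)
  expect_equal(nrow(top_k(tab)), 75L)
  expect_identical(top_k(tab, nrow(tab)), tab)
  expect_equal(top_k(tab, 1)$gene, tab$gene[1])
  expect_equal(top_k(tab, 1)$S, max(tab$S))
  expect_error(top_k(tab, 0), "positive")
  expect_error(top_k(tab, -3), "positive")
})

test_that("heatmap truncation clips symmetrically and is idempotent", {
  r <- matrix(c(5, -4.2, 1.2, 0, 3.7, -3.7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("3h", "12h", "24h")))
  sel <- ranked_from_scores(c(g1 = 2, g2 = 1))
  h <- truncate_for_heatmap(r, sel)
  expect_equal(unname(h["g1", ]), c(3.7, -3.7, 1.2))
  expect_equal(unname(h["g2", ]), c(0, 3.7, -3.7))
  expect_equal(attr(h, "limit"), 3.7)
  h2 <- truncate_for_heatmap(h, sel)
  expect_equal(unname(h2), unname(h))
  # tighter limit, symmetric clipping
  h05 <- truncate_for_heatmap(matrix(c(-1, 0, 1), 1,
                                     dimnames = list("g1", letters[1:3])),
                              ranked_from_scores(c(g1 = 1)), limit = 0.5)
  expect_equal(unname(h05[1, ]), c(-0.5, 0, 0.5))
})

test_that("truncation preserves within-row order and validates genes", {
  withr::with_seed(8, {
    r <- matrix(rnorm(30, sd = 3), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), c("a", "b", "c")))
  })
  sel <- top_k(sum_squared_rank(r), 5)
  h <- truncate_for_heatmap(r, sel, limit = 1.5)
  expect_equal(rownames(h), sel$gene)  # rank order preserved
  for (g in rownames(h)) {
    expect_false(is.unsorted(h[g, ][order(r[g, ])]))
  }
  bad <- ranked_from_scores(c(nope = 1))
  expect_error(truncate_for_heatmap(r, bad, 1), "not in the ratio matrix")
  expect_error(truncate_for_heatmap(r, sel, limit = 0), "positive")
})
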