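#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that a uniform draw of `length(query)` genes
#' from the universe overlaps the term by at least the observed count:
#' p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n).
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param term Character vector of term member genes (subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @return Raw p-value in (0, 1].
#' @export
#' @examples
#' u <- letters[1:10]
#' hypergeom_test(u[1:5], u[1:5], u)  # 1 / choose(10, 5)
hypergeom_test <- function(query, term, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  term <- unique(as.character(term))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe))
    stop("query genes outside the universe", call. = FALSE)
  if (!all(term %in% universe))
    stop("term genes outside the universe", call. = FALSE)
  N <- length(universe); K <- length(term); n <- length(query)
  k <- length(intersect(query, term))
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Rank-based enrichment of a term in the full ranking
#'
#' Compares the ranks of a term's member genes against all other ranked
#' genes with a two-sided Mann-Whitney test on the importance scale
#' (higher S = better rank). The statistic U counts member/non-member
#' pairs in which the member outranks the non-member, so members
#' occupying the top ranks give the maximal U = n1 * n2. The p-value is
#' exact (no ties are possible among distinct ranks) when
#' n1 * n2 <= 10000, otherwise the tie-corrected normal approximation is
#' used.
#'
#' @param ranked A `ranked_table` over the full gene universe.
#' @param term Character vector of member genes; must overlap the ranked
#'   genes strictly between 0 and all of them.
#' @return List with `U`, `p`, `n1` (members in the ranking), `n2`
#'   (non-members).
#' @export
rank_set_test <- function(ranked, term) {
  stopifnot(inherits(ranked, "ranked_table"))
  members <- ranked$gene %in% term
  n1 <- sum(members); n2 <- sum(!members)
  if (n1 == 0L || n2 == 0L)
    stop("term must overlap the ranked genes strictly between 0 and all",
         call. = FALSE)
  score <- nrow(ranked) - ranked$rank + 1L  # higher = more important
  exact <- n1 * n2 <= 10000
  wt <- suppressWarnings(
    stats::wilcox.test(score[members], score[!members],
                       alternative = "two.sided", exact = exact,
                       correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value, n1 = n1, n2 = n2)
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the family size `m` and capped at 1.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param m Family size (number of tests); must be at least `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("`m` must be a positive integer", call. = FALSE)
  if (m < length(p))
    stop("`m` must be at least the number of p-values", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  pmin(m * p, 1)  # argument order keeps the names of `p`
}

#' Enrichment of every term in a collection
#'
#' Tests each term with at least one expressed member (a member present in
#' the universe / ranking) and adjusts by Bonferroni with m = number of
#' terms actually tested. Two modes:
#' \describe{
#'   \item{`overrep`}{hypergeometric over-representation of the term in a
#'     query list (e.g. the top-75 genes) within the expressed-gene
#'     universe.}
#'   \item{`ranksum`}{two-sided rank-sum comparison of member vs
#'     non-member positions in the full ranking; terms covering none or
#'     all ranked genes are untestable and are skipped with a message.}
#' }
#'
#' @param collection A `gene_set_collection`. The universe used for
#'   testing is the intersection of the collection's universe with the
#'   expressed genes (`ranked$gene`), matching the convention that the
#'   universe is the genes on the array after filtering.
#' @param ranked A `ranked_table` over the expressed genes.
#' @param query For `overrep`: character vector of query genes (defaults
#'   to the top 75 of `ranked`).
#' @param method `"overrep"` (default) or `"ranksum"`.
#' @param alpha Significance level on the adjusted scale (default 0.01,
#'   boundary inclusive).
#' @return An `enrichment_result` data frame with columns `term`, `name`,
#'   `K` (expressed members), `n` (query size; for `ranksum`, members in
#'   the ranking), `k` (overlap; for `ranksum`, equal to `K`), `U`
#'   (rank-sum statistic, `NA` for `overrep`), `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_adj` then term id.
#' @export
enrich_terms <- function(collection, ranked, query = NULL,
                         method = c("overrep", "ranksum"), alpha = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(ranked, "ranked_table"))
  method <- match.arg(method)
  check_alpha(alpha)
  expressed <- intersect(collection$universe, ranked$gene)
  if (!length(expressed))
    stop("no collection gene is present in the ranking", call. = FALSE)
  sets <- lapply(collection$sets, intersect, expressed)
  testable <- lengths(sets) >= 1L
  if (method == "ranksum") {
    full <- lengths(sets) >= length(expressed)
    if (any(testable & full))
      message(sum(testable & full),
              " term(s) cover the whole ranking; skipped for ranksum")
    testable <- testable & !full
  }
  if (!any(testable))
    stop("no testable term (every term empty after expression filter)",
         call. = FALSE)
  sets <- sets[testable]
  m <- length(sets)
  ranked_expr <- ranked[ranked$gene %in% expressed, , drop = FALSE]
  class(ranked_expr) <- class(ranked)

  if (method == "overrep") {
    query <- unique(as.character(query %||% top_k(ranked)$gene))
    query <- intersect(query, expressed)
    rows <- lapply(names(sets), function(id) {
      s <- sets[[id]]
      data.frame(term = id, K = length(s), n = length(query),
                 k = length(intersect(query, s)), U = NA_real_,
                 p_raw = hypergeom_test(query, s, expressed),
                 stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(names(sets), function(id) {
      s <- sets[[id]]
      rs <- rank_set_test(ranked_expr, s)
      data.frame(term = id, K = length(s), n = rs$n1, k = length(s),
                 U = rs$U, p_raw = rs$p, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out$name <- unname(collection$names[out$term])
  out$p_adj <- bonferroni(out$p_raw, m)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$term, method = "radix"),
             c("term", "name", "K", "n", "k", "U",
               "p_raw", "p_adj", "significant")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  invisible(alpha)
}

#' Keep terms significant after adjustment
#'
#' Retains exactly the results with adjusted p <= `alpha` (boundary
#' inclusive, as in "adjusted p-values <= 0.01"), sorted by adjusted p
#' ascending.
#'
#' @param results An `enrichment_result` data frame.
#' @param alpha Significance level in (0, 1].
#' @return The significant subset, same class.
#' @export
filter_significant <- function(results, alpha = 0.01) {
  stopifnot(inherits(results, "enrichment_result"))
  check_alpha(alpha)
  out <- results[results$p_adj <= alpha, , drop = FALSE]
  out <- out[order(out$p_adj, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(results)
  out
}
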