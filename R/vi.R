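#' Variation of information between two gene sets
#'
#' Each set S induces the two-block partition \{S, U \ S\} of the
#' universe U. With the uniform measure on U, the variation of
#' information between the two partitions is
#' VI = H(A) + H(B) - 2 I(A;B) = 2 H(A,B) - H(A) - H(B),
#' with entropies in bits and the convention 0 log 0 = 0. VI is a true
#' metric on partitions; note that a set and its complement induce the
#' same partition, so VI(A, U \ A) = 0. For two-block partitions
#' VI <= 2 bits.
#'
#' @param setA,setB Character vectors, subsets of `universe`.
#' @param universe Non-empty character vector of gene ids.
#' @return VI distance in bits (>= 0).
#' @export
#' @examples
#' u <- as.character(1:4)
#' vi_distance(c("1", "2"), c("1", "3"), u)  # 2 bits
vi_distance <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe", call. = FALSE)
  N <- length(universe)
  k <- length(intersect(setA, setB))
  a <- length(setA); b <- length(setB)
  cells <- c(k, a - k, b - k, N - a - b + k) / N
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  hj <- h(cells)
  ha <- h(c(a, N - a) / N)
  hb <- h(c(b, N - b) / N)
  max(0, 2 * hj - ha - hb)
}

#' Pairwise VI distance matrix for a list of terms
#'
#' @param sets Named list of gene sets (>= 2).
#' @param universe Universe over which partitions are induced.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = term
#'   ids.
#' @export
vi_matrix <- function(sets, universe) {
  if (length(sets) < 2L)
    stop("need at least two terms to compute distances", call. = FALSE)
  ids <- names(sets) %||% as.character(seq_along(sets))
  n <- length(sets)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- vi_distance(sets[[i]], sets[[j]], universe)
    }
  }
  D
}

#' Agglomerative clustering of terms from a VI distance matrix
#'
#' Standard hierarchical agglomeration (via [stats::hclust()]) under the
#' requested linkage. The merge table, heights (in bits) and leaf order
#' are those of the returned `hclust` object.
#'
#' @param D Symmetric distance matrix with zero diagonal (e.g. from
#'   [vi_matrix()]), at least 2 x 2.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An object of class `hclust`.
#' @export
cluster_terms <- function(D, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 2L)
    stop("`D` must be a square matrix with >= 2 terms", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0) || any(D < 0))
    stop("`D` must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Export a cluster tree as Newick
#'
#' @param tree An `hclust` from [cluster_terms()].
#' @param path Optional output path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Shaded term table in dendrogram leaf order
#'
#' Rows are the significant terms in dendrogram display order, annotated
#' with the expressed-gene count and adjusted p-value, plus a shade weight
#' in [0, 1] proportional to -log10(adjusted p) and normalised so the most
#' significant term has shade 1 (the "darker red = more significant"
#' convention).
#'
#' @param results An `enrichment_result`; must contain exactly the terms
#'   of the tree and must be non-empty.
#' @param tree An `hclust` whose labels are the term ids, or `NULL` for a
#'   single-term table (clustering needs at least two terms).
#' @return Data frame with columns `term`, `name`, `n_genes`, `p_adj`,
#'   `shade`.
#' @export
shaded_table <- function(results, tree = NULL) {
  stopifnot(inherits(results, "enrichment_result"))
  if (!nrow(results))
    stop("no enrichment results to shade", call. = FALSE)
  if (is.null(tree)) {
    if (nrow(results) > 1L)
      stop("a cluster tree is required for more than one term",
           call. = FALSE)
    ord <- results$term
  } else {
    stopifnot(inherits(tree, "hclust"))
    if (!setequal(results$term, tree$labels) ||
        nrow(results) != length(tree$labels))
      stop("results and tree must carry the same terms", call. = FALSE)
    ord <- tree$labels[tree$order]
  }
  res <- results[match(ord, results$term), , drop = FALSE]
  w <- -log10(res$p_adj)
  shade <- if (max(w) > 0) w / max(w) else rep(1, length(w))
  data.frame(term = res$term, name = res$name, n_genes = res$K,
             p_adj = res$p_adj, shade = shade,
             stringsAsFactors = FALSE, row.names = NULL)
}
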