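# Independent brute-force oracles and tiny fixture builders.

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from
# 1..N against the term 1..K and count draws with overlap >= k.
hyper_enum_p <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}

# Cohort with explicit intensities: one row per gene, columns grouped as
# control then treatment groups, `reps` replicates each.
manual_cohort <- function(values, groups, reps = 3L) {
  genes <- rownames(values) %||% sprintf("g%02d", seq_len(nrow(values)))
  design <- data.frame(
    sample = colnames(values),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), times = length(groups)),
    stringsAsFactors = FALSE)
  rownames(values) <- genes
  as_expression_cohort(values, design, control = groups[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random gene subsets of a universe for property-style loops.
random_set <- function(universe, min_size = 1L) {
  n <- sample(min_size:(length(universe) - 1L), 1L)
  sample(universe, n)
}

# ranked_table built directly from a score vector (bypasses the ratio
# stage; used as input for rank-based tests).
ranked_from_scores <- function(scores, genes = names(scores)) {
  ord <- order(-scores, genes, method = "radix")
  out <- data.frame(gene = genes[ord], S = unname(scores[ord]),
                    rank = seq_along(scores), stringsAsFactors = FALSE)
  class(out) <- c("ranked_table", "data.frame")
  out
}
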