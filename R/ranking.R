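#' Log2 ratio trajectories against the control reference
#'
#' For each gene, the control reference is the median intensity over the
#' control replicates. Each treatment replicate then yields a log2 ratio
#' against that reference, and the gene's ratio at a time point is the
#' median of the replicate ratios (the "median of three biological
#' replicates" convention when there are three).
#'
#' Genes with any missing intensity are dropped with a message before
#' computing ratios, so the result is always finite.
#'
#' @param cohort An `expression_cohort`; its first group is the control.
#' @return Numeric matrix of log2 ratios, genes x treatment time points
#'   (columns in group order).
#' @export
#' @examples
#' co <- pool_replicates(generate_cohort(cohort_design(n_genes = 50)))
#' r <- log2_ratio_matrix(co)
#' dim(r)
log2_ratio_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  des <- cohort$design
  ctrl <- cohort$groups[1L]
  treat <- cohort$groups[-1L]
  if (!any(des$group == ctrl))
    stop("control group '", ctrl, "' has no samples", call. = FALSE)
  x <- cohort$intensities
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " gene(s) with missing intensities")
    x <- x[keep, , drop = FALSE]
    if (!nrow(x))
      stop("no gene with complete intensities", call. = FALSE)
  }
  if (any(x <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  ref <- apply(x[, des$sample[des$group == ctrl], drop = FALSE], 1L,
               stats::median)
  r <- vapply(treat, function(g) {
    cols <- des$sample[des$group == g]
    if (!length(cols))
      stop("treatment group '", g, "' has no samples", call. = FALSE)
    apply(log2(x[, cols, drop = FALSE] / ref), 1L, stats::median)
  }, numeric(nrow(x)))
  r <- matrix(r, nrow = nrow(x),
              dimnames = list(rownames(x), treat))
  r
}

#' Rank genes by the sum-squared time-course statistic
#'
#' The per-gene importance score is the sum of squared log2 ratios across
#' the time course, S_g = sum_t r[g,t]^2: large for genes strongly
#' regulated at any time point in either direction. Genes are sorted by S
#' in descending order; ties are broken lexicographically by gene id so
#' the ranking is deterministic.
#'
#' @param ratios Log2-ratio matrix from [log2_ratio_matrix()] (genes in
#'   rows, >= 1 time-point column, finite values, rownames = gene ids).
#' @return A `ranked_table` data frame with columns `gene`, `S`, `rank`.
#' @export
sum_squared_rank <- function(ratios) {
  ratios <- check_ratio_matrix(ratios)
  S <- rowSums(ratios^2)
  ord <- order(-S, rownames(ratios), method = "radix")
  out <- data.frame(gene = rownames(ratios)[ord], S = unname(S[ord]),
                    rank = seq_along(S), stringsAsFactors = FALSE)
  class(out) <- c("ranked_table", "data.frame")
  out
}

check_ratio_matrix <- function(ratios) {
  if (!is.matrix(ratios) || !is.numeric(ratios) || ncol(ratios) < 1L)
    stop("`ratios` must be a numeric matrix with >= 1 time point",
         call. = FALSE)
  if (is.null(rownames(ratios)) || anyDuplicated(rownames(ratios)))
    stop("`ratios` must carry unique gene ids as rownames", call. = FALSE)
  if (any(!is.finite(ratios)))
    stop("log2 ratios must be finite", call. = FALSE)
  ratios
}

#' Keep the top-K ranked genes
#'
#' @param table A `ranked_table` from [sum_squared_rank()].
#' @param k Number of genes to keep (default 75, the size plotted in the
#'   study's heatmap); capped at the table size.
#' @return A `ranked_table` with `min(k, n)` rows, highest S first.
#' @export
top_k <- function(table, k = 75L) {
  stopifnot(inherits(table, "ranked_table"))
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  out <- table[seq_len(min(k, nrow(table))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncated heatmap matrix for the top-ranked genes
#'
#' Extracts the log2-ratio trajectories of the selected genes, in rank
#' order, and symmetrically clips values to `[-limit, limit]` (the study
#' plots fold changes truncated to +/- 3.7). Clipping preserves the order
#' of values within a row and is idempotent.
#'
#' @param ratios Log2-ratio matrix.
#' @param selection A `ranked_table` (typically from [top_k()]); all its
#'   genes must be rows of `ratios`.
#' @param limit Positive truncation limit in log2 units.
#' @return Clipped matrix (selected genes x time points) with attribute
#'   `limit`.
#' @export
truncate_for_heatmap <- function(ratios, selection, limit = 3.7) {
  ratios <- check_ratio_matrix(ratios)
  stopifnot(inherits(selection, "ranked_table"))
  if (length(limit) != 1L || !is.finite(limit) || limit <= 0)
    stop("`limit` must be a single positive number", call. = FALSE)
  missing <- setdiff(selection$gene, rownames(ratios))
  if (length(missing))
    stop("selected gene(s) not in the ratio matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  m <- ratios[selection$gene, , drop = FALSE]
  m <- pmin(pmax(m, -limit), limit)
  attr(m, "limit") <- limit
  m
}
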