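#' Read / write tab-separated expression matrices and design tables
#'
#' The expression file has gene ids in the first column and one column per
#' sample; the design table has columns `sample`, `group` and either
#' `subject` or `replicate`. Writing then reading either file restores the
#' data exactly.
#'
#' @param path File path.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(path, ": expected a gene-id column plus >= 1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate gene id '", ids[duplicated(ids)][1L],
         "' (line ", which(duplicated(ids))[1L] + 1L, ")", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(path, ": non-numeric intensity values", call. = FALSE)
  rownames(m) <- ids
  m
}

#' @rdname expression_io
#' @param cohort An `expression_cohort`.
#' @export
write_expression <- function(cohort, path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  df <- data.frame(gene = rownames(cohort$intensities),
                   cohort$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "group")
  if (!all(req %in% names(df)))
    stop(path, ": design table needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  df
}

#' @rdname expression_io
#' @export
write_design <- function(cohort, path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  utils::write.table(cohort$design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an expression cohort from matrix + design files
#'
#' @param expression_path Tab-separated intensity matrix (first column
#'   gene id).
#' @param design_path Tab-separated design table (`sample`, `group`, and
#'   `subject` or `replicate`).
#' @param control Control group label; defaults to the first group in the
#'   design file.
#' @return An `expression_cohort`.
#' @export
read_cohort <- function(expression_path, design_path, control = NULL) {
  m <- read_expression(expression_path)
  des <- read_design(design_path)
  missing <- setdiff(colnames(m), des$sample)
  if (length(missing))
    stop(design_path, ": sample '", missing[1L],
         "' present in the matrix but absent from the design",
         call. = FALSE)
  extra <- setdiff(des$sample, colnames(m))
  if (length(extra))
    stop(design_path, ": sample '", extra[1L],
         "' has no column in the expression matrix", call. = FALSE)
  as_expression_cohort(m, des, control = control)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(m[, 0, drop = FALSE], check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m),
                                         stringsAsFactors = FALSE),
                              id_col),
              as.data.frame(m, check.names = FALSE))
  write_tsv(df, path)
}
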