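#' Gene-set collection over a declared universe
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param universe Character vector of all eligible gene ids.
#' @param names Optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, names = NULL) {
  universe <- as.character(universe)
  if (!length(universe) || anyDuplicated(universe))
    stop("universe must be non-empty with unique gene ids", call. = FALSE)
  if (!length(sets) || is.null(base::names(sets)) ||
      anyDuplicated(base::names(sets)))
    stop("`sets` must be a non-empty list with unique term ids",
         call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L))
    stop("empty terms are not allowed", call. = FALSE)
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray))
    stop("term members outside the universe: ",
         paste(utils::head(stray, 3), collapse = ", "), call. = FALSE)
  nms <- base::names(sets)
  full <- stats::setNames(nms, nms)
  if (!is.null(names)) full[base::names(names)] <- names
  structure(list(universe = universe, sets = sets, names = full),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' Draws `n_terms` random terms from a gene universe. Planted terms draw a
#' fixed fraction of their members from a designated gene list (e.g. the
#' genes you expect at the top of the ranking), so that downstream
#' over-representation tests have a known positive. Non-planted terms are
#' uniform draws and serve as nulls.
#'
#' @param n_terms Number of terms to generate.
#' @param size_range Integer vector of length 2: min and max term size
#'   (sizes drawn uniformly).
#' @param universe Character vector of gene ids, or a single integer (the
#'   universe size, ids generated as `g00001`...).
#' @param planted Named numeric vector: term id -> fraction of its members
#'   drawn from `target_genes` (the overlap count is the fraction times the
#'   term size, rounded down). These terms are generated in addition to the
#'   `n_terms` null terms.
#' @param target_genes Designated gene list for planted terms.
#' @param planted_size Size of each planted term.
#' @param seed Integer seed.
#' @return A `gene_set_collection`; planted term ids keep the names given
#'   in `planted`.
#' @export
#' @examples
#' gs <- generate_genesets(10, c(5, 20), universe = 100, seed = 3)
#' lengths(gs$sets)[1:3]
generate_genesets <- function(n_terms, size_range, universe,
                              planted = NULL, target_genes = NULL,
                              planted_size = NULL, seed = 1L) {
  if (length(universe) == 1L && is.numeric(universe))
    universe <- gene_ids(universe)
  universe <- as.character(universe)
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1L] < 1L ||
      size_range[2L] > length(universe) || size_range[1L] > size_range[2L])
    stop("size_range must lie within [1, universe size]", call. = FALSE)
  if (n_terms < 0L || (n_terms == 0L && is.null(planted)))
    stop("need at least one term", call. = FALSE)
  if (!is.null(planted)) {
    if (is.null(names(planted)) || any(planted < 0) || any(planted > 1))
      stop("`planted` must be a named vector of fractions in [0, 1]",
           call. = FALSE)
    target_genes <- as.character(target_genes)
    if (!length(target_genes) || !all(target_genes %in% universe))
      stop("`target_genes` must be a non-empty subset of the universe",
           call. = FALSE)
  }
  withr::with_seed(seed, {
    sets <- list()
    if (n_terms > 0L) {
      sizes <- sample(size_range[1L]:size_range[2L], n_terms, replace = TRUE)
      sets <- lapply(sizes, function(s) sample(universe, s))
      names(sets) <- sprintf("T%04d", seq_len(n_terms))
    }
    for (term in names(planted)) {
      sz <- as.integer(planted_size %||%
                         round(mean(size_range[1L]:size_range[2L])))
      n_in <- min(floor(planted[[term]] * sz), length(target_genes))
      pool_out <- setdiff(universe, target_genes)
      n_out <- sz - n_in
      if (n_out > length(pool_out))
        stop("planted term too large for genes outside the target list",
             call. = FALSE)
      members <- c(sample(target_genes, n_in),
                   if (n_out > 0L) sample(pool_out, n_out))
      sets[[term]] <- members
    }
  })
  gene_set_collection(sets, universe)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated. The description column (absent from most list-based GMT
#' readers) is kept as the term name.
#'
#' @param path Path to a GMT file.
#' @param universe Optional universe; defaults to the union of all members.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], " in ", path,
         ": expected term, description and >= 1 gene", call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  descr <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  gene_set_collection(sets, universe %||% unique(unlist(sets)),
                      names = descr)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
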