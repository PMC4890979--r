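#' Cohort design for a stress time-course study
#'
#' Describes the sampling layout of an expression cohort: one control group
#' plus an ordered series of treatment time-point groups, each with the same
#' number of subjects. The default design mirrors an acute restraint-stress
#' study: control plus 3 h, 12 h and 24 h groups with nine mice each, i.e.
#' 27 stressed and 9 control animals.
#'
#' @param groups Character vector of group labels; the first element is the
#'   control group and must occur exactly once.
#' @param subjects_per_group Number of subjects (arrays) per group.
#' @param replicates_per_group Number of pooled biological replicates each
#'   group is reduced to downstream (see [pool_replicates()]); must not
#'   exceed `subjects_per_group`.
#' @param n_genes Number of genes on the array.
#' @param seed Integer seed driving all randomness in [generate_cohort()].
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()], [pool_replicates()]
#' @export
#' @examples
#' d <- cohort_design()
#' d$groups
cohort_design <- function(groups = c("control", "3h", "12h", "24h"),
                          subjects_per_group = 9L,
                          replicates_per_group = 3L,
                          n_genes = 5000L,
                          seed = 1L) {
  if (length(groups) < 2L || anyDuplicated(groups))
    stop("`groups` must be >= 2 unique labels (control first)", call. = FALSE)
  if (sum(groups == groups[1L]) != 1L)
    stop("control group must appear exactly once", call. = FALSE)
  for (nm in c("subjects_per_group", "replicates_per_group", "n_genes")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop("`", nm, "` must be a positive integer", call. = FALSE)
  }
  if (replicates_per_group > subjects_per_group)
    stop("`replicates_per_group` cannot exceed `subjects_per_group`",
         call. = FALSE)
  structure(
    list(groups = as.character(groups),
         subjects_per_group = as.integer(subjects_per_group),
         replicates_per_group = as.integer(replicates_per_group),
         n_genes = as.integer(n_genes),
         seed = as.integer(seed)),
    class = "cohort_design")
}

#' Noise model for synthetic intensities
#'
#' Additive noise on the log2-intensity scale. `scale = 0` produces
#' deterministic intensities. The Gaussian default (scale 0.25 log2 units)
#' is a typical between-array spread for a well-behaved bead array;
#' `"laplace"` gives a heavier-tailed alternative with the same standard
#' deviation parameterisation.
#'
#' @param family `"gaussian"` or `"laplace"`.
#' @param scale Standard deviation of the noise in log2 units (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(family = c("gaussian", "laplace"), scale = 0.25) {
  family <- match.arg(family)
  if (length(scale) != 1L || !is.finite(scale) || scale < 0)
    stop("`scale` must be a single non-negative number", call. = FALSE)
  structure(list(family = family, scale = scale), class = "noise_model")
}

#' Planted time-course effects
#'
#' Ground-truth log2 effects attached to a subset of genes, one value per
#' treatment time point. Used by [generate_cohort()] to shift the mean
#' log2 intensity of the affected genes in the stressed groups, and by
#' recovery tests to check that the ranking stage finds them.
#'
#' @param genes Character vector of gene ids (must exist in the cohort's
#'   gene universe, `g00001` style by default).
#' @param effects Numeric vector (recycled across time points for every
#'   gene) or matrix with one row per gene and one column per treatment
#'   time point, in log2 units.
#' @param n_timepoints Number of treatment time points the effect vectors
#'   must span.
#' @return A numeric matrix (genes x time points) with class
#'   `planted_effects`.
#' @export
#' @examples
#' planted_effects(c("g00001", "g00002"), 1.5, n_timepoints = 3)
planted_effects <- function(genes, effects, n_timepoints = 3L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicated gene ids in planted effects", call. = FALSE)
  if (is.matrix(effects)) {
    if (nrow(effects) != length(genes) || ncol(effects) != n_timepoints)
      stop("effect matrix must be length(genes) x n_timepoints",
           call. = FALSE)
    m <- effects
  } else {
    m <- matrix(effects, nrow = length(genes), ncol = n_timepoints)
  }
  if (!all(is.finite(m)))
    stop("planted effects must be finite", call. = FALSE)
  rownames(m) <- genes
  structure(m, class = c("planted_effects", class(m)))
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

rnoise <- function(n, noise) {
  if (noise$scale == 0) return(numeric(n))
  switch(noise$family,
         gaussian = stats::rnorm(n, 0, noise$scale),
         # exponential difference: sd of Laplace(b) is sqrt(2) b
         laplace = (stats::rexp(n, 1) - stats::rexp(n, 1)) *
           noise$scale / sqrt(2))
}

#' Generate a synthetic expression cohort
#'
#' Simulates a strictly positive intensity matrix (genes x subjects) with
#' the group structure of `design`. Intensities are multiplicative:
#' `2^(base + effect + noise)`, with a per-gene base log2 intensity drawn
#' once (Normal(8, 1.5), a typical array intensity spread), planted effects
#' added only in the treatment groups, and noise per subject. Log2 ratios
#' downstream are therefore additive in effect and noise, and with
#' `scale = 0` the ratio of a planted gene equals its planted effect
#' exactly.
#'
#' @param design A [cohort_design()].
#' @param effects A [planted_effects()] matrix, or `NULL` for a null
#'   cohort.
#' @param noise A [noise_model()].
#' @return An object of class `expression_cohort`: a list with
#'   `intensities` (genes x samples matrix), `design` (data frame with
#'   columns `sample`, `group`, `subject`) and `groups` (ordered labels,
#'   control first). Identical inputs (including `design$seed`) give
#'   bit-identical output.
#' @export
#' @examples
#' co <- generate_cohort(cohort_design(n_genes = 100, seed = 7))
#' table(co$design$group)
generate_cohort <- function(design, effects = NULL, noise = noise_model()) {
  stopifnot(inherits(design, "cohort_design"))
  if (!inherits(noise, "noise_model"))
    stop("`noise` must be a noise_model()", call. = FALSE)
  genes <- gene_ids(design$n_genes)
  if (!is.null(effects)) {
    if (!inherits(effects, "planted_effects"))
      stop("`effects` must come from planted_effects()", call. = FALSE)
    if (ncol(effects) != length(design$groups) - 1L)
      stop("effect vectors must have one entry per treatment group",
           call. = FALSE)
    bad <- setdiff(rownames(effects), genes)
    if (length(bad))
      stop("planted effect genes outside the gene universe: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  n_samp <- design$subjects_per_group * length(design$groups)
  meta <- data.frame(
    group = rep(design$groups, each = design$subjects_per_group),
    subject = rep(seq_len(design$subjects_per_group),
                  times = length(design$groups)),
    stringsAsFactors = FALSE)
  meta$sample <- paste0(meta$group, "_s", meta$subject)
  meta <- meta[, c("sample", "group", "subject")]

  withr::with_seed(design$seed, {
    base <- stats::rnorm(design$n_genes, mean = 8, sd = 1.5)
    logi <- matrix(base, nrow = design$n_genes, ncol = n_samp)
    if (!is.null(effects)) {
      idx <- match(rownames(effects), genes)
      for (t in seq_along(design$groups[-1L])) {
        cols <- which(meta$group == design$groups[t + 1L])
        logi[idx, cols] <- logi[idx, cols] + effects[, t]
      }
    }
    logi <- logi + matrix(rnoise(design$n_genes * n_samp, noise),
                          nrow = design$n_genes)
  })
  intens <- 2^logi
  dimnames(intens) <- list(genes, meta$sample)
  structure(list(intensities = intens, design = meta,
                 groups = design$groups),
            class = "expression_cohort")
}

#' Build an expression cohort from a matrix and design table
#'
#' @param intensities Strictly positive numeric matrix, genes x samples,
#'   with unique row and column names.
#' @param design Data frame with columns `sample` and `group` (optionally
#'   `subject` or `replicate`); `sample` must match the matrix columns.
#' @param control Label of the control group; defaults to the first group
#'   encountered in `design`.
#' @return An `expression_cohort`.
#' @export
as_expression_cohort <- function(intensities, design, control = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities)))
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and strictly positive", call. = FALSE)
  req <- c("sample", "group")
  if (!all(req %in% names(design)))
    stop("design table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!setequal(design$sample, colnames(intensities)) ||
      anyDuplicated(design$sample))
    stop("design samples must match matrix columns exactly", call. = FALSE)
  design <- design[match(colnames(intensities), design$sample), ,
                   drop = FALSE]
  rownames(design) <- NULL
  grps <- unique(design$group)
  control <- control %||% grps[1L]
  if (!control %in% grps)
    stop("control group '", control, "' not present in design",
         call. = FALSE)
  structure(list(intensities = intensities, design = design,
                 groups = c(control, setdiff(grps, control))),
            class = "expression_cohort")
}

#' Pool subjects into biological replicates
#'
#' Averages the intensities of `pool_size` consecutive subjects within each
#' group into one pooled biological replicate, emulating designs in which
#' several animals are pooled per array. The default (3) turns a
#' 9-subject group into the three biological replicates whose median feeds
#' the log2-ratio stage.
#'
#' @param cohort An `expression_cohort` with per-subject samples.
#' @param pool_size Subjects averaged per replicate; must divide the
#'   subject count of every group.
#' @return An `expression_cohort` whose design has columns `sample`,
#'   `group`, `replicate`.
#' @export
pool_replicates <- function(cohort, pool_size = 3L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (length(pool_size) != 1L || pool_size < 1 || pool_size != round(pool_size))
    stop("`pool_size` must be a positive integer", call. = FALSE)
  des <- cohort$design
  pooled <- list(); meta <- list()
  for (g in cohort$groups) {
    cols <- des$sample[des$group == g]
    if (length(cols) %% pool_size != 0L)
      stop("group '", g, "' has ", length(cols),
           " subjects, not divisible by pool_size = ", pool_size,
           call. = FALSE)
    n_rep <- length(cols) %/% pool_size
    for (r in seq_len(n_rep)) {
      take <- cols[((r - 1L) * pool_size + 1L):(r * pool_size)]
      pooled[[length(pooled) + 1L]] <-
        rowMeans(cohort$intensities[, take, drop = FALSE])
      meta[[length(meta) + 1L]] <-
        data.frame(sample = paste0(g, "_r", r), group = g, replicate = r,
                   stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, pooled)
  meta <- do.call(rbind, meta)
  colnames(m) <- meta$sample
  structure(list(intensities = m, design = meta, groups = cohort$groups),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort: ", nrow(x$intensities), " genes x ",
      ncol(x$intensities), " samples\n", sep = "")
  cat("groups:", paste(x$groups, collapse = ", "),
      "(control =", x$groups[1L], ")\n")
  print(table(x$design$group)[x$groups])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
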