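#' Pipeline run configuration
#'
#' Collects the parameters of a full simulate/rank/enrich/cluster run. The
#' defaults are the study's printed analysis settings: top 75 genes,
#' heatmap truncation at +/- 3.7 log2 units, Bonferroni-adjusted
#' significance at alpha = 0.01 (inclusive), over-representation testing,
#' average linkage.
#'
#' @param expression,design,gmt Optional input paths; when all three are
#'   `NULL` a synthetic study is simulated (see [simulate_study()]).
#' @param out_dir Optional output directory for the stage tables and the
#'   run report; created if missing.
#' @param top_k Number of top-ranked genes kept for the heatmap and the
#'   default enrichment query.
#' @param truncate Heatmap truncation limit in log2 units.
#' @param alpha Adjusted-p significance level, boundary inclusive.
#' @param method Enrichment mode, `"overrep"` or `"ranksum"`.
#' @param linkage Agglomeration linkage for term clustering.
#' @param pool_size Subjects pooled per biological replicate.
#' @param seed Single seed driving all randomness of the run.
#' @param simulate Named list of overrides for [simulate_study()]
#'   (e.g. `n_genes`, `n_planted`, `effect`, `noise_scale`).
#' @return A `run_config` list.
#' @export
run_config <- function(expression = NULL, design = NULL, gmt = NULL,
                       out_dir = NULL, top_k = 75L, truncate = 3.7,
                       alpha = 0.01, method = "overrep",
                       linkage = "average", pool_size = 3L, seed = 1L,
                       simulate = list()) {
  cfg <- list(expression = expression, design = design, gmt = gmt,
              out_dir = out_dir, top_k = as.integer(top_k),
              truncate = as.numeric(truncate), alpha = as.numeric(alpha),
              method = match.arg(method, c("overrep", "ranksum")),
              linkage = match.arg(linkage,
                                  c("average", "single", "complete")),
              pool_size = as.integer(pool_size), seed = as.integer(seed),
              simulate = simulate)
  check_alpha(cfg$alpha)
  if (cfg$top_k < 1L) stop("`top_k` must be positive", call. = FALSE)
  if (cfg$truncate <= 0) stop("`truncate` must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML key-value file)
#'
#' @param path Config file path.
#' @return [read_config()] returns a `run_config`; [write_config()] the
#'   path, invisibly. A config written and re-read is identical.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (!length(vals$simulate)) vals$simulate <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Builds the default acute-stress cohort (27 stressed subjects in three
#' time-point groups plus 9 controls) with `n_planted` genes carrying
#' time-course effects, and a gene-set collection in which `planted_terms`
#' terms draw a fraction of their members from the planted genes. This is
#' the standard scenario every downstream stage is exercised against.
#'
#' @param n_genes Genes on the simulated array.
#' @param n_planted Genes given a planted time-course effect.
#' @param effect Per-time-point log2 effect magnitude for planted genes;
#'   signs alternate across genes so both up- and down-regulation occur.
#' @param noise_scale Log2-scale noise standard deviation.
#' @param n_terms Null (random) terms in the gene-set collection.
#' @param set_size Size range for null terms.
#' @param planted_terms Number of enriched terms planted.
#' @param planted_fraction Fraction of each planted term's members drawn
#'   from the planted genes.
#' @param planted_term_size Size of each planted term.
#' @param subjects_per_group,pool_size Cohort layout (see
#'   [cohort_design()] and [pool_replicates()]).
#' @param seed Seed for the whole scenario.
#' @return List with `cohort` (per-subject), `collection`, and `truth`
#'   (planted gene ids, planted term ids, effect matrix).
#' @export
simulate_study <- function(n_genes = 5000L, n_planted = 50L, effect = 2,
                           noise_scale = 0.25, n_terms = 50L,
                           set_size = c(10L, 200L), planted_terms = 2L,
                           planted_fraction = 0.8,
                           planted_term_size = 50L,
                           subjects_per_group = 9L, pool_size = 3L,
                           seed = 1L) {
  des <- cohort_design(subjects_per_group = subjects_per_group,
                       replicates_per_group =
                         subjects_per_group %/% pool_size,
                       n_genes = n_genes, seed = seed)
  genes <- gene_ids(n_genes)
  truth <- list(planted_genes = character(0), planted_term_ids = character(0),
                effects = NULL)
  eff <- NULL
  if (n_planted > 0L) {
    sel <- withr::with_seed(seed + 1L,
                            sort(sample(genes, n_planted)))
    signs <- rep_len(c(1, -1), n_planted)
    emat <- matrix(effect * signs, nrow = n_planted,
                   ncol = length(des$groups) - 1L)
    eff <- planted_effects(sel, emat,
                           n_timepoints = length(des$groups) - 1L)
    truth$planted_genes <- sel
    truth$effects <- eff
  }
  cohort <- generate_cohort(des, effects = eff,
                            noise = noise_model(scale = noise_scale))
  planted <- NULL
  if (planted_terms > 0L && n_planted > 0L) {
    ids <- sprintf("P%02d", seq_len(planted_terms))
    planted <- stats::setNames(rep(planted_fraction, planted_terms), ids)
    truth$planted_term_ids <- ids
  }
  collection <- generate_genesets(
    n_terms = n_terms, size_range = set_size, universe = genes,
    planted = planted, target_genes = truth$planted_genes,
    planted_size = planted_term_size, seed = seed + 2L)
  list(cohort = cohort, collection = collection, truth = truth)
}

#' Run the full time-course analysis pipeline
#'
#' Executes simulate (or load) -> pool -> log2 ratios -> sum-squared
#' ranking -> top-K heatmap -> enrichment -> Bonferroni filter -> VI
#' clustering and shaded term table. If fewer than two terms pass the
#' significance filter the clustering stage is skipped with a message and
#' the run still succeeds. With `out_dir` set, each stage's table is
#' written as tab-separated text plus a JSON run report; identical config
#' (including seed) gives identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage objects (`cohort`, `pooled`,
#'   `ratios`, `ranked`, `top`, `heatmap`, `enrichment`, `significant`,
#'   `distances`, `tree`, `shaded`, `truth`) and `report` (parameters and
#'   per-stage counts).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$expression)) {
    if (is.null(config$design) || is.null(config$gmt))
      stop("`expression` requires `design` and `gmt` paths",
           call. = FALSE)
    cohort <- read_cohort(config$expression, config$design)
    collection <- read_gmt(config$gmt,
                           universe = rownames(cohort$intensities))
    pooled <- if ("replicate" %in% names(cohort$design)) cohort
              else pool_replicates(cohort, config$pool_size)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim_args$pool_size <- config$pool_size
    sim <- do.call(simulate_study, sim_args)
    cohort <- sim$cohort
    collection <- sim$collection
    truth <- sim$truth
    pooled <- pool_replicates(cohort, config$pool_size)
  }

  ratios <- log2_ratio_matrix(pooled)
  ranked <- sum_squared_rank(ratios)
  top <- top_k(ranked, config$top_k)
  heatmap <- truncate_for_heatmap(ratios, top, config$truncate)
  enrichment <- enrich_terms(collection, ranked, query = top$gene,
                             method = config$method, alpha = config$alpha)
  signif <- filter_significant(enrichment, config$alpha)

  distances <- NULL; tree <- NULL; shaded <- NULL
  if (nrow(signif) >= 2L) {
    expressed <- intersect(collection$universe, ranked$gene)
    sets <- lapply(collection$sets[signif$term], intersect, expressed)
    distances <- vi_matrix(sets, expressed)
    tree <- cluster_terms(distances, config$linkage)
    shaded <- shaded_table(signif, tree)
  } else if (nrow(signif) == 1L) {
    shaded <- shaded_table(signif, NULL)
    message("only one significant term; clustering skipped")
  } else {
    message("no significant term at alpha = ", config$alpha,
            "; clustering skipped")
  }

  report <- list(
    parameters = list(top_k = config$top_k, truncate = config$truncate,
                      alpha = config$alpha, method = config$method,
                      linkage = config$linkage,
                      pool_size = config$pool_size, seed = config$seed),
    counts = list(
      genes = nrow(cohort$intensities),
      samples = ncol(cohort$intensities),
      control_samples = sum(cohort$design$group == cohort$groups[1L]),
      treatment_samples = sum(cohort$design$group != cohort$groups[1L]),
      pooled_replicates = ncol(pooled$intensities),
      ranked_genes = nrow(ranked),
      heatmap_genes = nrow(heatmap),
      terms_tested = nrow(enrichment),
      significant_terms = nrow(signif),
      clustered_terms = if (is.null(tree)) 0L else length(tree$labels)),
    versions = list(
      stressrank = as.character(utils::packageVersion("stressrank")),
      r = paste(R.version$major, R.version$minor, sep = ".")))

  result <- list(cohort = cohort, pooled = pooled, ratios = ratios,
                 ranked = ranked, top = top, heatmap = heatmap,
                 enrichment = enrichment, significant = signif,
                 distances = distances, tree = tree, shaded = shaded,
                 truth = truth, report = report)
  if (!is.null(config$out_dir)) write_outputs(result, config$out_dir)
  invisible(result)
}

#' Write every stage table of a pipeline run
#'
#' @param result The list returned by [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(result$ranked, p("ranked.tsv"))
  write_matrix_tsv(result$heatmap, p("heatmap.tsv"))
  write_tsv(result$enrichment, p("enrichment.tsv"))
  if (!is.null(result$distances)) {
    write_matrix_tsv(result$distances, p("vi_distances.tsv"),
                     id_col = "term")
    merges <- data.frame(left = result$tree$merge[, 1L],
                         right = result$tree$merge[, 2L],
                         height = result$tree$height,
                         id = seq_len(nrow(result$tree$merge)))
    write_tsv(merges, p("merges.tsv"))
    tree_newick(result$tree, p("tree.nwk"))
  }
  if (!is.null(result$shaded)) write_tsv(result$shaded, p("shaded_terms.tsv"))
  jsonlite::write_json(result$report, p("report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
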