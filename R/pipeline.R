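#' Default pipeline configuration
#'
#' Materializes every tunable of the end-to-end run with its default;
#' override any subset via `...`. The resolved configuration is written to
#' the output directory before any computation, so a run is fully described
#' by its config file and master seed.
#'
#' @param ... Named overrides of the defaults (unknown names are an error).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_confidence = 0.7,
    lfc_threshold = 1,
    padj_threshold = 0.05,
    k_deg = 50, k_np = 50, deg_offset = 0, np_offset = 0,
    fallback_unfiltered = FALSE,
    restart_prob = 0.5,
    h = 0.9, outer_max = 20, prior_tol = 1e-3,
    damping = 0.5, lbp_tol = 1e-6, lbp_max_iter = 200,
    epochs = 60, learning_rate = 0.01, hidden = 16, heads = 4,
    repeats = 10, folds = 5,
    aggregator = "dibra", prune_keep_fraction = 0.5,
    ns = c(200, 300),
    truth_denominator = "all",
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Select the labeled positive set for a run
#'
#' DEG filtering (strict cutoffs, falling back to the unfiltered
#' p-value-ordered table when requested and the filtered list is too
#' short), top-k slicing with optional offsets, then
#' [build_positive_set()].
#'
#' @param deg_table DEG tibble.
#' @param network A `gene_network`.
#' @param ko_gene Knock-out gene identifier.
#' @param config A `run_config`.
#' @return A `positive_set` (see [build_positive_set()]).
#' @export
select_positives <- function(deg_table, network, ko_gene, config = run_config()) {
  filtered <- filter_degs(deg_table, config$lfc_threshold,
                          config$padj_threshold)
  if (isTRUE(config$fallback_unfiltered) &&
      nrow(filtered) < config$k_deg + config$deg_offset) {
    filtered <- as_tibble(deg_table) |>
      arrange(.data$padj, desc(abs(.data$log2fc)), .data$gene)
  }
  deg_in_net <- filtered$gene[filtered$gene %in% network_genes(network)]
  deg_top <- top_k(deg_in_net, k = config$k_deg, exclude = ko_gene,
                   offset = config$deg_offset)
  build_positive_set(deg_top, network, ko_gene,
                     k_deg = config$k_deg, k_np = config$k_np,
                     np_offset = config$np_offset,
                     restart_prob = config$restart_prob)
}

#' Run the full prioritization pipeline on in-memory inputs
#'
#' Composes positive selection, cross-validated PU learning, rank
#' aggregation, input-positive exclusion and partial-AUC evaluation. With
#' `truth = NULL` the evaluation step is skipped.
#'
#' @param network A `gene_network` (already confidence-filtered, or filter
#'   at load time with [load_edge_list()]).
#' @param deg_table DEG tibble (`gene`, `log2fc`, `pvalue`, `padj`).
#' @param ko_gene Knock-out gene identifier.
#' @param truth Optional ground-truth phenotype gene set for evaluation.
#' @param config A `run_config`; its `seed` drives every random step.
#' @param baselines Character vector of baseline rankings to compute for
#'   comparison; subset of `c("rwr", "diamond")`. Default none.
#' @return A `pugrank_run` list: `positives`, `aggregate` (aggregated
#'   ranking), `evaluation` (tibble or NULL), `baseline_rankings`, `config`.
#' @export
run_prioritization <- function(network, deg_table, ko_gene, truth = NULL,
                               config = run_config(), baselines = character()) {
  positives <- select_positives(deg_table, network, ko_gene, config)
  np <- attr(positives, "np_scores")
  inst <- pu_instance(network, positives$gene)
  inst <- default_features(inst, np, deg_table,
                           lfc_threshold = config$lfc_threshold,
                           padj_threshold = config$padj_threshold)
  plan <- make_folds(positives$gene, repeats = config$repeats,
                     folds = config$folds, seed = config$seed)
  agg <- run_cv_aggregate(
    inst, plan, aggregator = config$aggregator,
    prune_keep_fraction = config$prune_keep_fraction,
    h = config$h, outer_max = config$outer_max,
    prior_tol = config$prior_tol, damping = config$damping,
    lbp_tol = config$lbp_tol, lbp_max_iter = config$lbp_max_iter,
    epochs = config$epochs, learning_rate = config$learning_rate,
    hidden = config$hidden, heads = config$heads
  )
  baseline_rankings <- list()
  seeds_for_baseline <- unique(c(ko_gene, positives$gene))
  if ("rwr" %in% baselines) {
    baseline_rankings$rwr <- {
      sc <- rwr(network, seeds_for_baseline,
                restart_prob = config$restart_prob)
      new_ranking(sc$gene, sc$score)
    }
  }
  if ("diamond" %in% baselines) {
    k <- min(2000, length(network_genes(network)) -
               length(seeds_for_baseline))
    baseline_rankings$diamond <- diamond_rank(network, seeds_for_baseline,
                                              k = k)
  }
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate_methods(
      c(list(pugrank = agg), baseline_rankings),
      truth = truth, input_positives = positives$gene,
      ns = config$ns, truth_denominator = config$truth_denominator
    )
  }
  structure(list(
    positives = positives,
    aggregate = agg,
    evaluation = evaluation,
    baseline_rankings = baseline_rankings,
    config = config
  ), class = "pugrank_run")
}

#' Run the pipeline from files and write a run directory
#'
#' File-based front end: reads the network, either a DEG table or an
#' expression matrix + design (run through [wilcoxon_deg()]), the KO gene
#' and an optional truth list, then calls [run_prioritization()] and writes
#' the resolved config, positives, per-fold rankings, aggregate and
#' evaluation table into `outdir`.
#'
#' @param paths Named list with `network`, `ko_gene`, and either `deg_table`
#'   or both `expression` and `design`; optionally `truth`.
#' @param outdir Output directory.
#' @param config A `run_config`.
#' @param baselines Passed to [run_prioritization()].
#' @return The `pugrank_run`, invisibly; files are written to `outdir`.
#' @export
run_pipeline <- function(paths, outdir, config = run_config(),
                         baselines = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  log_rows <- list()
  stamp <- function(stage, t0) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      stage = stage,
      wall_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
      seed = config$seed
    )
  }
  t0 <- Sys.time()
  network <- load_edge_list(paths$network,
                            min_confidence = config$min_confidence)
  ko_gene <- load_gene_list(paths$ko_gene)[1]
  deg_table <- if (!is.null(paths$deg_table)) {
    read_deg_table(paths$deg_table)
  } else if (!is.null(paths$expression) && !is.null(paths$design)) {
    expr <- readr::read_tsv(paths$expression, col_types = readr::cols())
    mat <- as.matrix(expr[, -1])
    rownames(mat) <- expr[[1]]
    design <- readr::read_tsv(paths$design, col_types = readr::cols())
    wilcoxon_deg(mat, design)
  } else {
    abort("paths must include deg_table, or expression and design")
  }
  truth <- if (!is.null(paths$truth)) load_gene_list(paths$truth) else NULL
  stamp("load_inputs", t0)
  t0 <- Sys.time()
  run <- run_prioritization(network, deg_table, ko_gene, truth = truth,
                            config = config, baselines = baselines)
  stamp("prioritize", t0)
  readr::write_tsv(as_tibble(run$positives),
                   file.path(outdir, "positives.tsv"))
  folds <- attr(run$aggregate, "fold_rankings")
  fold_dir <- file.path(outdir, "fold_rankings")
  dir.create(fold_dir, showWarnings = FALSE)
  for (i in seq_along(folds)) {
    write_ranking(folds[[i]],
                  file.path(fold_dir, sprintf("fold_%03d.tsv", i)))
  }
  write_ranking(run$aggregate, file.path(outdir, "aggregate.tsv"))
  if (!is.null(run$evaluation)) {
    readr::write_tsv(run$evaluation, file.path(outdir, "evaluation.tsv"))
  }
  readr::write_tsv(purrr::list_rbind(log_rows), file.path(outdir, "log.tsv"))
  invisible(run)
}
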