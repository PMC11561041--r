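#' Assemble a positive-unlabeled learning instance
#'
#' Bundles a gene network with the labeled positive set R, the unlabeled set
#' U (all remaining network genes) and a per-gene feature matrix, the three
#' ingredients of PU learning on the network.
#'
#' @param network A `gene_network`.
#' @param positives Character vector of labeled positive genes, or a
#'   `positive_set` from [build_positive_set()]. Positives absent from the
#'   network are dropped with a warning.
#' @param features Numeric matrix with one row per network gene (rownames =
#'   gene identifiers), or `NULL` to fill in later with [default_features()].
#' @return A `pu_instance` list with elements `network`, `genes`,
#'   `positives`, `unlabeled`, `features`.
#' @export
pu_instance <- function(network, positives, features = NULL) {
  if (is.data.frame(positives)) positives <- positives$gene
  genes <- network_genes(network)
  keep <- positives %in% genes
  if (!any(keep)) abort("no positive gene is present in the network")
  if (!all(keep)) {
    warn(sprintf("%d positive gene(s) absent from the network were dropped",
                 sum(!keep)))
  }
  positives <- unique(positives[keep])
  inst <- structure(list(
    network = network,
    genes = genes,
    positives = positives,
    unlabeled = setdiff(genes, positives),
    features = NULL
  ), class = "pu_instance")
  if (!is.null(features)) inst <- set_features(inst, features)
  inst
}

set_features <- function(instance, features) {
  features <- as.matrix(features)
  if (is.null(rownames(features)) ||
      !setequal(rownames(features), instance$genes)) {
    abort("feature matrix must have one row per network gene")
  }
  instance$features <- features[instance$genes, , drop = FALSE]
  instance
}

#' Default node features for the graph attention classifier
#'
#' Builds the per-gene feature matrix used when no user-supplied features are
#' given: log(1 + degree), the network-propagation score on a log10 scale
#' (propagation mass decays geometrically with distance from the seeds, so
#' the log is the informative scale) and its rank percentile, plus
#' `|log2FC|` and a strict-cutoff significance indicator when a DEG table
#' is available (genes absent from the table get 0 for both). Each column
#' is standardized to zero mean and unit variance.
#'
#' @param instance A `pu_instance`.
#' @param np_scores Propagation scores from [rwr()] on the same network.
#' @param deg_table Optional DEG tibble (`gene`, `log2fc`, `pvalue`, `padj`).
#' @param lfc_threshold,padj_threshold Strict cutoffs for the significance
#'   indicator feature; same meaning as in [filter_degs()].
#' @return The instance with its `features` slot filled (5 columns).
#' @export
default_features <- function(instance, np_scores, deg_table = NULL,
                             lfc_threshold = 1, padj_threshold = 0.05) {
  genes <- instance$genes
  deg <- table(c(instance$network$from, instance$network$to))
  degree <- as.numeric(deg[genes])
  np <- setNames(np_scores$score, np_scores$gene)[genes]
  if (anyNA(np)) abort("np_scores must cover every network gene")
  np_pct <- 1 - (rank(-np, ties.method = "average") - 1) / length(np)
  lfc <- rep(0, length(genes))
  sig <- rep(0, length(genes))
  if (!is.null(deg_table)) {
    m <- match(genes, deg_table$gene)
    hit <- !is.na(m)
    lfc[hit] <- abs(deg_table$log2fc[m[hit]])
    sig[hit] <- as.numeric(
      abs(deg_table$log2fc[m[hit]]) > lfc_threshold &
        deg_table$padj[m[hit]] < padj_threshold
    )
  }
  X <- cbind(
    log_degree = log1p(degree),
    log_np_score = log10(np + 1e-12),
    np_percentile = np_pct,
    abs_log2fc = lfc,
    deg_significant = sig
  )
  X <- apply(X, 2, function(col) {
    s <- stats::sd(col)
    if (s < 1e-12) col - mean(col) else (col - mean(col)) / s
  })
  rownames(X) <- genes
  set_features(instance, X)
}
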