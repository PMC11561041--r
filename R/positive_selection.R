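#' Filter a DEG table with strict effect-size and significance cutoffs
#'
#' Keeps genes with `|log2fc| > lfc_threshold` and `padj < padj_threshold`
#' (both strict) and orders them by ascending adjusted p-value; ties in
#' `padj` are broken by descending `|log2fc|`, then gene identifier, so the
#' order is deterministic.
#'
#' @param deg_table Tibble with columns `gene`, `log2fc`, `pvalue`, `padj`.
#' @param lfc_threshold Absolute log2 fold-change cutoff (strict). Default 1.
#' @param padj_threshold Adjusted p-value cutoff (strict). Default 0.05.
#' @return The filtered, re-ordered DEG tibble (possibly zero rows).
#' @export
filter_degs <- function(deg_table, lfc_threshold = 1, padj_threshold = 0.05) {
  deg_table <- as_tibble(deg_table)
  deg_table |>
    filter(abs(.data$log2fc) > lfc_threshold, .data$padj < padj_threshold) |>
    arrange(.data$padj, desc(abs(.data$log2fc)), .data$gene)
}

#' Take the top k genes of an ordered table
#'
#' Works on any already-ordered gene table (a filtered DEG table, propagation
#' scores sorted by descending score, a ranking). Genes in `exclude` are
#' skipped; `offset` skips the first `offset` eligible genes first, which is
#' how a "secondary top" slice (e.g. ranks 51-100) is taken.
#'
#' @param x Data frame with a `gene` column, already in priority order, or a
#'   character vector of genes in priority order.
#' @param k Number of genes to return (fewer if the input is exhausted).
#' @param exclude Genes to skip over (they consume no rank).
#' @param offset Number of eligible genes to skip before taking `k`.
#' @return Character vector of at most `k` genes, in input order.
#' @export
top_k <- function(x, k = 50, exclude = character(), offset = 0) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) abort("`k` must be positive")
  genes <- if (is.character(x)) x else x$gene
  genes <- genes[!genes %in% exclude]
  if (offset > 0) genes <- genes[-seq_len(min(offset, length(genes)))]
  utils::head(genes, k)
}

#' Random walk with restart over a gene network
#'
#' Iterates `p <- restart_prob * p0 + (1 - restart_prob) * W %*% p`, where
#' `p0` is uniform over the seed genes present in the network and `W` is the
#' column-stochastic (weighted-degree-normalized) adjacency matrix of edge
#' confidences, until the L1 change drops below `tol`. Probability mass is
#' conserved at every iteration, so the fixed point is a probability vector
#' over all network genes.
#'
#' @param network A `gene_network`.
#' @param seeds Character vector of seed genes. Seeds absent from the network
#'   are dropped with a warning; if none remain this is an error.
#' @param restart_prob Restart probability in (0, 1]. Default 0.5.
#' @param tol L1 convergence tolerance. Default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual. Default 10000.
#' @param weighted Use edge confidences as walk weights (default); `FALSE`
#'   gives the unweighted walk on the same topology.
#' @return Tibble with columns `gene`, `score`, sorted by descending score
#'   (ties by gene identifier); scores sum to 1.
#' @examples
#' net <- as_gene_network(data.frame(from = "a", to = "b"))
#' rwr(net, seeds = "a")
#' @export
rwr <- function(network, seeds, restart_prob = 0.5, tol = 1e-10,
                max_iter = 10000, weighted = TRUE) {
  assert_scalar_number(restart_prob, "restart_prob", 0, 1, strict_lower = TRUE)
  genes <- network_genes(network)
  keep <- seeds %in% genes
  if (!any(keep)) abort("no seed gene is present in the network")
  if (!all(keep)) {
    warn(sprintf(
      "%d seed gene(s) absent from the network were dropped: %s",
      sum(!keep), paste(utils::head(seeds[!keep], 5), collapse = ", ")
    ))
  }
  seeds <- unique(seeds[keep])
  W <- transition_matrix(network, weighted = weighted)
  n <- length(genes)
  p0 <- numeric(n)
  p0[match(seeds, genes)] <- 1 / length(seeds)
  p <- p0
  r <- restart_prob
  for (it in seq_len(max_iter)) {
    p_new <- r * p0 + (1 - r) * as.numeric(W %*% p)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      p <- p / sum(p)
      out <- tibble(gene = genes, score = p) |>
        arrange(desc(.data$score), .data$gene)
      return(out)
    }
  }
  abort(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                max_iter, delta))
}

# Column-stochastic transition matrix of edge confidences, genes in
# network_genes() order.
transition_matrix <- function(network, weighted = TRUE) {
  genes <- network_genes(network)
  i <- match(network$from, genes)
  j <- match(network$to, genes)
  w <- if (weighted) network$confidence else rep(1, nrow(network))
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = c(w, w),
    dims = c(length(genes), length(genes))
  )
  deg <- Matrix::colSums(A)
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Build the labeled positive gene set from DEGs and network propagation
#'
#' Runs network propagation seeded by the knock-out gene together with the
#' top differentially expressed genes, then unions the DEG positives with
#' the top propagation-ranked genes (seeds excluded, so propagation
#' contributes genuinely new genes). The knock-out gene itself is a seed,
#' never a positive.
#'
#' @param deg_top Character vector of top DEGs in priority order (e.g. from
#'   `filter_degs() |> top_k()`); genes absent from the network are dropped
#'   with a warning.
#' @param network A `gene_network`.
#' @param ko_gene The knocked-out gene identifier.
#' @param k_deg Number of DEG positives to keep. Default 50.
#' @param k_np Number of propagation positives to add. Default 50.
#' @param np_offset Skip this many propagation-ranked genes before taking
#'   `k_np` (0 for the top slice; 50 selects ranks 51-100). Default 0.
#' @param restart_prob,tol,max_iter Passed to [rwr()].
#' @return A `positive_set`: tibble with columns `gene` and `provenance`
#'   (`"DEG"`, `"NP"` or `"BOTH"`), with attributes `ko_gene` and
#'   `np_scores` (the full propagation result).
#' @export
build_positive_set <- function(deg_top, network, ko_gene, k_deg = 50,
                               k_np = 50, np_offset = 0, restart_prob = 0.5,
                               tol = 1e-10, max_iter = 10000) {
  genes <- network_genes(network)
  in_net <- deg_top %in% genes
  if (!all(in_net)) {
    warn(sprintf("%d DEG gene(s) absent from the network were dropped",
                 sum(!in_net)))
    deg_top <- deg_top[in_net]
  }
  deg_pos <- top_k(deg_top, k = k_deg, exclude = ko_gene)
  seeds <- unique(c(ko_gene, deg_pos))
  np <- rwr(network, seeds, restart_prob = restart_prob, tol = tol,
            max_iter = max_iter)
  np_pos <- top_k(np, k = k_np, exclude = seeds, offset = np_offset)
  all_genes <- union(deg_pos, np_pos)
  prov <- dplyr::case_when(
    all_genes %in% deg_pos & all_genes %in% np_pos ~ "BOTH",
    all_genes %in% deg_pos ~ "DEG",
    TRUE ~ "NP"
  )
  out <- tibble::new_tibble(
    list(gene = all_genes, provenance = prov),
    nrow = length(all_genes), class = "positive_set"
  )
  attr(out, "ko_gene") <- ko_gene
  attr(out, "np_scores") <- np
  out
}

#' Minimal Wilcoxon rank-sum differential expression
#'
#' A small two-group DEG routine for synthetic fixtures: per gene, a
#' two-sided Wilcoxon rank-sum test between knock-out and wild-type samples,
#' a pseudo-count log2 fold change
#' `log2((mean_KO + 1) / (mean_WT + 1))`, and Benjamini-Hochberg adjustment
#' across all genes. It is not a replacement for a count-model DE method on
#' real data.
#'
#' @param expr Numeric matrix or data frame, genes as rows (rownames = gene
#'   identifiers), samples as columns.
#' @param design Data frame with columns `sample`, `condition` (values `WT`
#'   and `KO`); `sample` must match `colnames(expr)`.
#' @return DEG tibble with columns `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
wilcoxon_deg <- function(expr, design) {
  expr <- as.matrix(expr)
  if (!all(design$sample %in% colnames(expr))) {
    abort("design samples missing from expression matrix columns")
  }
  cond <- setNames(design$condition, design$sample)[colnames(expr)]
  if (!all(cond %in% c("WT", "KO"))) abort("conditions must be WT or KO")
  if (sum(cond == "WT") < 2 || sum(cond == "KO") < 2) {
    abort("need at least 2 samples per condition")
  }
  ko <- expr[, cond == "KO", drop = FALSE]
  wt <- expr[, cond == "WT", drop = FALSE]
  pvals <- vapply(seq_len(nrow(expr)), function(g) {
    suppressWarnings(
      stats::wilcox.test(ko[g, ], wt[g, ], exact = FALSE)$p.value
    )
  }, numeric(1))
  pvals[is.na(pvals)] <- 1  # constant genes: no evidence
  tibble(
    gene = rownames(expr),
    log2fc = unname(log2((rowMeans(ko) + 1) / (rowMeans(wt) + 1))),
    pvalue = pvals,
    padj = stats::p.adjust(pvals, method = "BH")
  )
}
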