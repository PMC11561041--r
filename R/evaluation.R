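#' Remove input positive genes from a ranking
#'
#' Evaluation targets genes not yet known to be phenotype-related, so the
#' labeled positives fed into PU learning are excluded from the ranked list
#' before scoring; the relative order of the remaining genes is preserved
#' and ranks are recomputed.
#'
#' @param ranking A `gene_ranking`.
#' @param input_positives Character vector of genes to drop.
#' @return A `gene_ranking` without the input positives.
#' @export
exclude_input_positives <- function(ranking, input_positives) {
  out <- as_tibble(ranking) |> filter(!.data$gene %in% input_positives)
  out$rank <- seq_len(nrow(out))
  tibble::new_tibble(out, class = "gene_ranking")
}

#' Partial AUC of a gene ranking (area under the ROCn curve)
#'
#' Scores how many ground-truth phenotype-related genes are ranked above
#' each of the top `n` negatives:
#' `AUC_n = (1 / (n R)) * sum_{i=1}^{n} R_i`, where `R` is the number of
#' ground-truth genes and `R_i` the number of them ranked strictly above the
#' i-th highest-ranked negative (non-truth) gene. Because phenotype-related
#' genes are a small fraction of the network, values well below 1 are
#' expected even for good rankings.
#'
#' @param ranking A `gene_ranking` (typically after
#'   [exclude_input_positives()]).
#' @param truth Character vector of ground-truth phenotype-related genes.
#' @param n Number of top-ranked negatives to cover (e.g. 200 or 300).
#' @param truth_denominator `"all"` (default) counts every truth gene in the
#'   denominator `R`, including genes absent from the ranking (conservative:
#'   coverage loss is penalized); `"ranked"` counts only truth genes present
#'   in the ranking.
#' @return A `partial_auc` object: list with `auc`, `n`, `r_truth` and the
#'   counter vector `r_i`.
#' @examples
#' rk <- tibble::tibble(
#'   rank = 1:5, gene = c("t1", "n1", "t2", "n2", "n3"), score = 5:1
#' )
#' partial_auc(rk, truth = c("t1", "t2"), n = 2)$auc  # 0.75
#' @export
partial_auc <- function(ranking, truth, n,
                        truth_denominator = c("all", "ranked")) {
  truth_denominator <- match.arg(truth_denominator)
  truth <- unique(truth)
  if (length(truth) == 0L) abort("empty ground-truth gene set")
  if (nrow(ranking) == 0L) abort("empty ranking")
  is_truth <- ranking$gene %in% truth
  r_truth <- if (truth_denominator == "all") length(truth) else sum(is_truth)
  if (r_truth == 0L) abort("no truth gene to score against")
  neg_pos <- which(!is_truth)
  if (length(neg_pos) < n) {
    abort(sprintf("ranking has only %d negatives; n = %d requested",
                  length(neg_pos), n))
  }
  truth_above <- cumsum(is_truth)
  r_i <- truth_above[neg_pos[seq_len(n)]]
  structure(list(
    auc = sum(r_i) / (n * r_truth),
    n = as.integer(n),
    r_truth = as.integer(r_truth),
    r_i = as.integer(r_i)
  ), class = "partial_auc")
}

#' @export
print.partial_auc <- function(x, ...) {
  cat(sprintf("Partial AUC_%d = %.4f  (R = %d truth genes)\n",
              x$n, x$auc, x$r_truth))
  invisible(x)
}

#' DIAMOnD connectivity-significance baseline
#'
#' Iteratively grows the seed set: at each step every non-seed gene is
#' scored by the hypergeometric tail probability of having at least its
#' observed number of links into the current seed set, given its degree;
#' the gene with the smallest p-value (ties: more seed links, then gene
#' identifier) is added. The ranking is the order of addition.
#'
#' @param network A `gene_network`.
#' @param seeds Character vector of seed genes (must be in the network).
#' @param k Number of genes to rank. If the network is exhausted first, a
#'   shorter list is returned with a message.
#' @return A `gene_ranking` of the first `k` added genes, score =
#'   `-log10(p)` at the step of addition.
#' @export
diamond_rank <- function(network, seeds, k) {
  if (k < 1) abort("`k` must be at least 1")
  genes <- network_genes(network)
  if (!all(seeds %in% genes)) abort("all seeds must be network genes")
  g <- network_igraph(network)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v))
  degree <- lengths(adj)
  n_total <- length(genes)
  in_seed <- genes %in% seeds
  k_seed <- vapply(adj, function(nb) sum(in_seed[nb]), integer(1))
  added <- character(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    cand <- which(!in_seed)
    if (length(cand) == 0L) {
      inform(sprintf("network exhausted after %d genes", length(added)))
      break
    }
    s <- sum(in_seed)
    # P(X >= k_seed) for X ~ Hypergeometric(seeds s, others, draws = degree)
    p <- stats::phyper(k_seed[cand] - 1L, s, n_total - s, degree[cand],
                       lower.tail = FALSE)
    ord <- order(p, -k_seed[cand], genes[cand])
    pick <- cand[ord[1]]
    added <- c(added, genes[pick])
    scores <- c(scores, -log10(max(p[ord[1]], 1e-300)))
    in_seed[pick] <- TRUE
    for (nb in adj[[pick]]) k_seed[nb] <- k_seed[nb] + 1L
  }
  tibble::new_tibble(
    list(rank = seq_along(added), gene = added, score = scores),
    nrow = length(added), class = "gene_ranking"
  )
}

#' Score several rankings with partial AUC
#'
#' Applies [exclude_input_positives()] then [partial_auc()] to each method's
#' ranking at each `n`, producing a tidy comparison table.
#'
#' @param rankings Named list of `gene_ranking` objects.
#' @param truth Ground-truth phenotype-related genes.
#' @param input_positives Genes to exclude from every ranking before
#'   scoring.
#' @param ns Integer vector of negative-coverage cutoffs. Default
#'   `c(200, 300)`.
#' @param truth_denominator Passed to [partial_auc()].
#' @return Tibble with columns `method`, `n`, `auc`.
#' @export
evaluate_methods <- function(rankings, truth, input_positives = character(),
                             ns = c(200, 300),
                             truth_denominator = "all") {
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  purrr::map(names(rankings), function(method) {
    rk <- exclude_input_positives(rankings[[method]], input_positives)
    purrr::map(ns, function(n) {
      tibble(method = method, n = as.integer(n),
             auc = partial_auc(rk, truth, n,
                               truth_denominator = truth_denominator)$auc)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
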