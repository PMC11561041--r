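# Independent oracles and fixture builders shared across the test files.

# Exact marginals of a pairwise Markov network by exhaustive enumeration
# over all 2^n label assignments (+ = 1, - = 2). Edges: 2-column integer
# matrix of node indices; phi: n x 2 node potentials; psi: 2 x 2 edge
# potential. Tractable for n <= ~14.
mrf_marginals_brute <- function(phi, edges, psi) {
  n <- nrow(phi)
  states <- as.matrix(expand.grid(rep(list(1:2), n)))
  joint <- apply(states, 1, function(y) {
    p <- prod(phi[cbind(seq_len(n), y)])
    if (nrow(edges)) {
      p <- p * prod(psi[cbind(y[edges[, 1]], y[edges[, 2]])])
    }
    p
  })
  joint <- joint / sum(joint)
  t(vapply(seq_len(n), function(i) {
    c(sum(joint[states[, i] == 1]), sum(joint[states[, i] == 2]))
  }, numeric(2)))
}

# Brute-force partial AUC: double loop over truth x top-n negatives,
# counting truth genes ranked strictly above each negative.
pauc_brute <- function(ranked_genes, truth, n, r_truth = length(truth)) {
  is_truth <- ranked_genes %in% truth
  neg_rank <- which(!is_truth)
  stopifnot(length(neg_rank) >= n)
  truth_pos <- which(is_truth)
  total <- 0
  for (i in seq_len(n)) {
    for (tp in truth_pos) {
      if (tp < neg_rank[i]) total <- total + 1
    }
  }
  total / (n * r_truth)
}

# Random labeled tree on n nodes (each node attaches to a random earlier
# node), as a 2-column index matrix.
random_tree_edges <- function(n) {
  if (n < 2) return(matrix(integer(), ncol = 2))
  cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
}

# Wrap an integer edge matrix as a gene_network with unit confidences.
index_network <- function(edges, n) {
  g <- sprintf("g%02d", seq_len(n))
  as_gene_network(data.frame(from = g[edges[, 1]], to = g[edges[, 2]]))
}

# Random connected weighted network for RWR / pipeline tests: a random
# tree plus extra random edges.
random_network <- function(n, extra = n, seed = NULL) {
  build <- function() {
    edges <- random_tree_edges(n)
    more <- cbind(sample.int(n, extra, replace = TRUE),
                  sample.int(n, extra, replace = TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    edges <- rbind(edges, more)
    g <- sprintf("g%03d", seq_len(n))
    as_gene_network(data.frame(
      from = g[edges[, 1]], to = g[edges[, 2]],
      confidence = stats::runif(nrow(edges), 0.5, 1)
    ))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Simple gene_ranking constructor for fixtures.
ranking_of <- function(genes) {
  tibble::new_tibble(
    list(rank = seq_along(genes), gene = genes,
         score = rev(seq_along(genes)) / length(genes)),
    nrow = length(genes), class = "gene_ranking"
  )
}

# A small PU instance on an index network with uninformative features.
toy_instance <- function(network, positives, n_features = 2, seed = 1) {
  genes <- network_genes(network)
  X <- withr::with_seed(seed, {
    matrix(stats::rnorm(length(genes) * n_features), ncol = n_features,
           dimnames = list(genes, paste0("f", seq_len(n_features))))
  })
  pu_instance(network, positives, features = X)
}
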