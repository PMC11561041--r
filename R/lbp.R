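#' Node and edge potentials of the pairwise Markov network
#'
#' Labeled positives are clamped to `(1 - 1e-6, 1e-6)` (not exact one-hot, so
#' message products stay strictly positive); unlabeled genes get the current
#' class-prior estimate as their positive-class potential, floored at 1e-12
#' so the all-negative initial prior of 0 is still numerically defined. The
#' edge potential is a single homophily matrix `[[h, 1-h], [1-h, h]]` with
#' `h > 0.5` (neighboring genes tend to share phenotype responsibility).
#'
#' @param instance A `pu_instance`.
#' @param prior Current class-prior estimate in \[0, 1\] (fraction of true
#'   positives among the unlabeled genes).
#' @param h Edge homophily in (0.5, 1). Default 0.9.
#' @return A `pu_potentials` list: `phi` (n x 2 matrix, columns positive /
#'   negative), `psi` (2 x 2), `h`.
#' @export
init_potentials <- function(instance, prior = 0, h = 0.9) {
  assert_scalar_number(prior, "prior", 0, 1)
  if (!is.numeric(h) || length(h) != 1L || h <= 0.5 || h >= 1) {
    abort("`h` must be in (0.5, 1): the edge potential must be homophilous")
  }
  n <- length(instance$genes)
  pos_prior <- max(prior, 1e-12)
  phi <- matrix(c(rep(pos_prior, n), rep(1 - pos_prior, n)), ncol = 2,
                dimnames = list(instance$genes, c("pos", "neg")))
  is_pos <- instance$genes %in% instance$positives
  phi[is_pos, ] <- matrix(c(1 - 1e-6, 1e-6), nrow = sum(is_pos), ncol = 2,
                          byrow = TRUE)
  structure(list(phi = phi, psi = matrix(c(h, 1 - h, 1 - h, h), 2, 2), h = h),
            class = "pu_potentials")
}

# Directed-edge index of an undirected network: both orientations, with the
# position of each edge's reverse. Gene order = network_genes(network).
directed_edges <- function(network) {
  genes <- network_genes(network)
  i <- match(network$from, genes)
  j <- match(network$to, genes)
  m <- length(i)
  list(
    src = c(i, j), dst = c(j, i),
    rev = c(m + seq_len(m), seq_len(m)),
    n = length(genes), genes = genes
  )
}

#' Approximate marginals by loopy belief propagation
#'
#' Sum-product message passing on the pairwise Markov network defined by
#' [init_potentials()]. Messages start uniform, are updated synchronously
#' with damping (`new = (1 - damping) * update + damping * old`) and
#' normalized every step; iteration stops when the largest absolute message
#' change falls below `tol`. Hitting `max_iter` logs a warning (beliefs are
#' still returned). Beliefs are the normalized product of a gene's node
#' potential with all incoming messages — on trees they are the exact
#' marginals; on cyclic networks they are the standard LBP approximation.
#'
#' @param instance A `pu_instance`.
#' @param potentials A `pu_potentials` from [init_potentials()].
#' @param damping Damping factor in \[0, 1). Default 0.5.
#' @param tol Message convergence tolerance. Default 1e-6.
#' @param max_iter Message-passing sweep cap. Default 200.
#' @return An n x 2 belief matrix (columns `pos`, `neg`, rows = genes), each
#'   row on the simplex, with attributes `iterations` and `converged`.
#' @export
lbp_marginalize <- function(instance, potentials, damping = 0.5, tol = 1e-6,
                            max_iter = 200) {
  assert_scalar_number(damping, "damping", 0, 1, strict_upper = TRUE)
  ed <- directed_edges(instance$network)
  phi <- potentials$phi
  psi <- potentials$psi
  res <- lbp_run_cpp(phi, psi, ed$src - 1L, ed$dst - 1L, ed$rev - 1L,
                     ed$n, damping, tol, max_iter)
  if (!res$converged) {
    warn(sprintf("LBP reached max_iter = %d (last change %.3g)",
                 max_iter, res$delta))
  }
  B <- res$beliefs
  dimnames(B) <- dimnames(phi)
  attr(B, "iterations") <- res$iterations
  attr(B, "converged") <- res$converged
  B
}
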