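#' Train the graph attention classifier on soft labels
#'
#' One update step of the PU loop: fits the two-layer graph attention node
#' classifier by minimizing the soft-label negative log likelihood
#' `(1/|R|) sum_{i in R} l(one_hot_i, yhat_i) + (1/|U|) sum_{j in U} l(b_j,
#' yhat_j)` with `l(t, yhat) = -sum_c t(c) log yhat(c)`, full batch, Adam.
#' Weight initialization and training are fully determined by `seed` (or by
#' the supplied warm-start parameters).
#'
#' @param instance A `pu_instance` with features.
#' @param beliefs n x 2 belief matrix from [lbp_marginalize()] (soft labels
#'   for the unlabeled genes).
#' @param epochs Gradient steps. Default 60.
#' @param learning_rate Adam step size. Default 0.01.
#' @param seed Integer seed for weight initialization.
#' @param hidden,heads Width and number of attention heads of the first
#'   layer. Defaults 16 and 4.
#' @param params Optional warm-start parameters from a previous call
#'   (overrides `seed` initialization).
#' @param edges Optional precomputed edge structure (internal; reused
#'   across calls on the same instance).
#' @return List with `prob` (n x 2 matrix of class probabilities, rows =
#'   genes), `params` (trained weights) and `loss` (final objective value).
#' @export
train_classifier <- function(instance, beliefs, epochs = 60,
                             learning_rate = 0.01, seed = 1, hidden = 16,
                             heads = 4, params = NULL, edges = NULL) {
  if (is.null(params)) {
    params <- gat_init(ncol(instance$features), hidden = hidden,
                       heads = heads, seed = seed)
  }
  fit <- gat_fit(instance, beliefs, params, epochs = epochs,
                 lr = learning_rate, edges = edges)
  rownames(fit$prob) <- instance$genes
  colnames(fit$prob) <- c("pos", "neg")
  fit
}

#' Re-estimate the class prior from classifier output
#'
#' The updated prior is the fraction of unlabeled genes whose positive-class
#' probability is strictly greater than 0.5.
#'
#' @param prob Named numeric vector (or n x 2 matrix with a `pos` column) of
#'   positive-class probabilities, names = gene identifiers.
#' @param unlabeled Character vector of unlabeled genes.
#' @return The estimated prior, a number in \[0, 1\].
#' @examples
#' update_prior(c(a = 0.6, b = 0.4, c = 0.7, d = 0.2), c("a", "b", "c", "d"))
#' @export
update_prior <- function(prob, unlabeled) {
  if (length(unlabeled) == 0L) abort("unlabeled gene set is empty")
  if (is.matrix(prob)) prob <- setNames(prob[, "pos"], rownames(prob))
  p <- prob[unlabeled]
  if (anyNA(p)) abort("missing probability for some unlabeled gene")
  mean(p > 0.5)
}

#' Rank genes by PU learning on the network
#'
#' The core loop: starting from a class prior of 0 (all unlabeled genes
#' presumed negative), alternate (i) loopy belief propagation on the
#' pairwise Markov network to get approximate marginals, (ii) a graph
#' attention classifier update on those soft labels, and (iii) class-prior
#' re-estimation, until the prior stabilizes or `outer_max` rounds are done.
#' All genes are returned ranked by final positive-class probability
#' (labeled positives included; exclude them downstream with
#' [exclude_input_positives()] before evaluation).
#'
#' @param instance A `pu_instance` with features.
#' @param h Edge homophily in (0.5, 1). Default 0.9.
#' @param outer_max Maximum outer iterations. Default 20.
#' @param prior_tol Stop when the prior changes by less than this. Default
#'   1e-3.
#' @param damping,lbp_tol,lbp_max_iter Passed to [lbp_marginalize()].
#' @param epochs Gradient steps per outer iteration (default 60). A vector
#'   is recycled along the outer loop with its last value repeated, so
#'   `c(150, 50)` trains the freshly initialized classifier longer on the
#'   first round and refines on later rounds.
#' @param learning_rate,hidden,heads Passed to [train_classifier()].
#' @param warm_start Keep classifier weights across outer iterations
#'   (default) instead of re-initializing each round.
#' @param seed Integer seed; fixes weight initialization, so two runs with
#'   the same seed give identical rankings.
#' @return A `gene_ranking` tibble (`rank`, `gene`, `score` = positive-class
#'   probability; ties broken by gene identifier) with attributes
#'   `prior_history` (estimate per outer iteration, starting at 0),
#'   `outer_iterations` and `converged`.
#' @export
grab_rank <- function(instance, h = 0.9, outer_max = 20, prior_tol = 1e-3,
                      damping = 0.5, lbp_tol = 1e-6, lbp_max_iter = 200,
                      epochs = 60, learning_rate = 0.01,
                      hidden = 16, heads = 4, warm_start = TRUE, seed = 1) {
  if (is.null(instance$features)) {
    abort("instance has no feature matrix; see default_features()")
  }
  prior <- 0
  history <- prior
  params <- NULL
  prob <- NULL
  converged <- FALSE
  iter <- 0L
  edges <- gat_edges(instance)
  for (iter in seq_len(outer_max)) {
    potentials <- init_potentials(instance, prior = prior, h = h)
    beliefs <- lbp_marginalize(instance, potentials, damping = damping,
                               tol = lbp_tol, max_iter = lbp_max_iter)
    fit <- train_classifier(instance, beliefs,
                            epochs = epochs[min(iter, length(epochs))],
                            learning_rate = learning_rate, seed = seed,
                            hidden = hidden, heads = heads,
                            params = if (warm_start) params else NULL,
                            edges = edges)
    params <- fit$params
    prob <- fit$prob
    prior_new <- update_prior(prob, instance$unlabeled)
    history <- c(history, prior_new)
    if (abs(prior_new - prior) < prior_tol) {
      prior <- prior_new
      converged <- TRUE
      break
    }
    prior <- prior_new
  }
  ranking <- new_ranking(instance$genes, unname(prob[, "pos"]))
  attr(ranking, "prior_history") <- history
  attr(ranking, "final_prior") <- prior
  attr(ranking, "outer_iterations") <- iter
  attr(ranking, "converged") <- converged
  class(ranking) <- c("grab_ranking", class(ranking))
  ranking
}
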