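#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_col
#'   geom_point labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a gene ranking
#'
#' @param x A `gene_ranking`.
#' @param ... Unused.
#' @return A plain tibble with columns `rank`, `gene`, `score`.
#' @export
tidy.gene_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "gene", "score")])
}

#' One-row summary of a PU-learning ranking
#'
#' @param x A `grab_ranking` from [grab_rank()].
#' @param ... Unused.
#' @return Tibble with `n_genes`, `final_prior`, `outer_iterations`,
#'   `converged`.
#' @export
glance.grab_ranking <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    final_prior = attr(x, "final_prior"),
    outer_iterations = attr(x, "outer_iterations"),
    converged = attr(x, "converged")
  )
}

#' Tidy an aggregated ranking's voter weights
#'
#' @param x An `aggregated_ranking` from [dibra_aggregate()].
#' @param ... Unused.
#' @return Tibble with `list_id`, `weight`.
#' @export
glance.aggregated_ranking <- function(x, ...) {
  w <- attr(x, "weights")
  tibble(n_kept = nrow(x), n_pruned = length(attr(x, "pruned")),
         min_weight = min(w), max_weight = max(w))
}

#' Tidy a partial-AUC result
#'
#' @param x A `partial_auc`.
#' @param ... Unused.
#' @return Tibble with one row per covered negative: `i`, `r_i`,
#'   `recall_i` (= `r_i / r_truth`).
#' @export
tidy.partial_auc <- function(x, ...) {
  tibble(i = seq_len(x$n), r_i = x$r_i, recall_i = x$r_i / x$r_truth)
}

#' @rdname tidy.partial_auc
#' @export
glance.partial_auc <- function(x, ...) {
  tibble(auc = x$auc, n = x$n, r_truth = x$r_truth)
}

#' Score-vs-rank curve of a gene ranking
#'
#' @param object A `gene_ranking`.
#' @param top Show only the first `top` ranks (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_ranking <- function(object, top = nrow(object), ...) {
  df <- tidy.gene_ranking(object)[seq_len(min(top, nrow(object))), ]
  ggplot(df, aes(x = .data$rank, y = .data$score)) +
    geom_line() +
    labs(x = "Rank", y = "Score") +
    theme_minimal()
}

#' ROCn-style curve of a partial-AUC result
#'
#' Plots the fraction of ground-truth genes recovered above the i-th
#' top-ranked negative; the area under this step curve is `AUC_n`.
#'
#' @param object A `partial_auc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.partial_auc <- function(object, ...) {
  df <- tidy.partial_auc(object)
  ggplot(df, aes(x = .data$i, y = .data$recall_i)) +
    geom_step() +
    labs(
      x = "Top-ranked negatives covered",
      y = "Fraction of truth genes ranked above",
      title = sprintf("AUC_%d = %.4f", object$n, object$auc)
    ) +
    theme_minimal()
}

#' Partial-AUC comparison plot for an evaluation table
#'
#' @param evaluation Tibble from [evaluate_methods()] (columns `method`,
#'   `n`, `auc`).
#' @return A ggplot bar chart.
#' @export
plot_evaluation <- function(evaluation) {
  ggplot(evaluation,
         aes(x = .data$method, y = .data$auc,
             fill = factor(.data$n))) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "Partial AUC", fill = "n") +
    theme_minimal()
}

#' @export
print.pugrank_run <- function(x, ...) {
  cat("PU-learning gene prioritization run\n")
  cat(sprintf("  positives: %d (%s)\n", nrow(x$positives),
              paste(sprintf("%s=%d", names(table(x$positives$provenance)),
                            table(x$positives$provenance)),
                    collapse = ", ")))
  cat(sprintf("  aggregated ranking: %d genes\n", nrow(x$aggregate)))
  if (!is.null(x$evaluation)) {
    cat("  evaluation:\n")
    print(x$evaluation)
  }
  invisible(x)
}
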