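#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange filter distinct desc bind_rows
#' @importFrom stats setNames
NULL

# Derive a stream of independent sub-seeds from one master seed.
# Keeps every derived seed in [1, 2^31 - 2] so it is a valid R integer seed.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), {
    sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
  })
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g)", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

new_ranking <- function(gene, score) {
  stopifnot(length(gene) == length(score))
  ord <- order(-score, gene)
  tibble::new_tibble(
    list(rank = seq_along(gene), gene = gene[ord], score = score[ord]),
    nrow = length(gene), class = "gene_ranking"
  )
}

validate_ranking <- function(ranking) {
  if (!is.data.frame(ranking) ||
      !all(c("rank", "gene", "score") %in% names(ranking))) {
    abort("a ranking must be a data frame with columns rank, gene, score")
  }
  if (anyDuplicated(ranking$gene)) abort("ranking genes must be unique")
  if (nrow(ranking) > 1 && any(diff(ranking$score) > 1e-12)) {
    abort("ranking scores must be non-increasing with rank")
  }
  invisible(ranking)
}
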