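#' Cross-validation folds over the labeled positive set
#'
#' Repeated k-fold splits of the positives: within each repeat a seeded
#' shuffle is cut into `folds` near-equal parts, and each training subset is
#' the positive set minus one held-out fold, giving `repeats * folds`
#' subsets in total.
#'
#' @param positives Character vector of labeled positive genes (or a
#'   `positive_set`).
#' @param repeats Number of repeats. Default 10.
#' @param folds Folds per repeat. Default 5.
#' @param seed Integer seed; the same seed reproduces the plan exactly.
#' @return A `fold_plan` tibble with one row per subset: columns `repeat_id`,
#'   `fold_id`, `train` (list of positive subsets), `held_out` (list of
#'   held-out folds) and `run_seed` (per-run seed derived from `seed`).
#' @export
make_folds <- function(positives, repeats = 10, folds = 5, seed = 1) {
  if (is.data.frame(positives)) positives <- positives$gene
  positives <- unique(positives)
  if (length(positives) < folds) {
    abort(sprintf("need at least %d positives for %d folds (got %d)",
                  folds, folds, length(positives)))
  }
  repeat_seeds <- derive_seeds(seed, repeats + 1)
  run_seeds <- derive_seeds(repeat_seeds[repeats + 1], repeats * folds)
  rows <- purrr::map(seq_len(repeats), function(r) {
    shuffled <- withr::with_seed(repeat_seeds[r], sample(positives))
    fold_of <- sort(rep_len(seq_len(folds), length(positives)))
    purrr::map(seq_len(folds), function(f) {
      held <- shuffled[fold_of == f]
      tibble(
        repeat_id = r, fold_id = f,
        train = list(sort(setdiff(positives, held))),
        held_out = list(sort(held))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows$run_seed <- run_seeds
  tibble::new_tibble(rows, class = "fold_plan")
}

# Shared absent-gene convention: a gene missing from a list is treated as
# ranked one past the end of that list (rank m + 1).
rank_lookup <- function(ranking, universe) {
  r <- match(universe, ranking$gene)
  r[is.na(r)] <- nrow(ranking) + 1L
  r
}

ranking_universe <- function(lists) {
  sort(unique(unlist(lapply(lists, function(l) l$gene))))
}

check_lists <- function(lists) {
  if (length(lists) == 0L) abort("no rankings to aggregate")
  for (l in lists) {
    if (nrow(l) == 0L) abort("cannot aggregate an empty ranking")
  }
  invisible(lists)
}

#' Borda rank aggregation
#'
#' Per gene, the weighted sum of Borda-normalized positions
#' `(m_l - rank_l) / (m_l - 1)` over input lists `l` of length `m_l`; a gene
#' absent from a list contributes 0 from it. Output sorted by descending
#' score, ties broken by gene identifier.
#'
#' @param lists List of `gene_ranking` tibbles.
#' @param weights Optional non-negative weight per list (default all 1).
#' @return A `gene_ranking` over the union of input genes.
#' @export
borda_aggregate <- function(lists, weights = NULL) {
  check_lists(lists)
  weights <- weights %||% rep(1, length(lists))
  stopifnot(length(weights) == length(lists), all(weights >= 0))
  universe <- ranking_universe(lists)
  score <- numeric(length(universe))
  for (k in seq_along(lists)) {
    m <- nrow(lists[[k]])
    r <- match(universe, lists[[k]]$gene)
    present <- !is.na(r)
    contrib <- if (m == 1) 1 else (m - r[present]) / (m - 1)
    score[present] <- score[present] + weights[k] * contrib
  }
  # rounding at 12 significant digits makes exact ties independent of the
  # floating-point summation order, so aggregation is anonymous
  new_ranking(universe, signif(score, 12))
}

#' Median-rank aggregation
#'
#' Genes are ordered by the median of their ranks across input lists (a gene
#' absent from a list of length `m` is imputed rank `m + 1`); ties in the
#' median are broken by mean rank, then gene identifier.
#'
#' @inheritParams borda_aggregate
#' @return A `gene_ranking` over the union of input genes (score = negative
#'   median rank).
#' @export
median_rank_aggregate <- function(lists) {
  check_lists(lists)
  universe <- ranking_universe(lists)
  R <- vapply(lists, rank_lookup, numeric(length(universe)),
              universe = universe)
  R <- matrix(R, nrow = length(universe))
  med <- apply(R, 1, stats::median)
  mn <- rowMeans(R)
  ord <- order(med, mn, universe)
  tibble::new_tibble(
    list(rank = seq_along(universe), gene = universe[ord],
         score = -med[ord]),
    nrow = length(universe), class = "gene_ranking"
  )
}

# Normalized Spearman footrule distance between a ranking and the current
# aggregate over the union universe; absent genes imputed rank m + 1.
footrule_distance <- function(ranking, aggregate, universe) {
  r1 <- rank_lookup(ranking, universe)
  r2 <- rank_lookup(aggregate, universe)
  u <- length(universe)
  dmax <- if (u < 2) 1 else ceiling(u^2 / 2) / u
  mean(abs(r1 - r2)) / dmax
}

#' Weighted distance-based rank aggregation (DIBRA-style)
#'
#' Iterative voter weighting: start from an unweighted Borda aggregate, then
#' repeatedly (i) measure each input list's normalized Spearman footrule
#' distance `d_l` to the current aggregate, (ii) reweight it as
#' `w_l = 1 / (1 + d_l)`, and (iii) re-aggregate by weighted Borda, until
#' the aggregate order stops changing or `max_rounds` is reached. Finally
#' the lower portion of the aggregate is pruned, keeping the top
#' `ceiling(prune_keep_fraction * |union|)` genes — the method's focus is
#' the head of the ranking.
#'
#' @inheritParams borda_aggregate
#' @param max_rounds Reweighting round cap. Default 10.
#' @param prune_keep_fraction Fraction of the union universe kept. Default
#'   0.5.
#' @return An `aggregated_ranking`: a `gene_ranking` with attributes
#'   `weights` (final per-list weights) and `pruned` (genes removed as the
#'   lower portion).
#' @export
dibra_aggregate <- function(lists, max_rounds = 10, prune_keep_fraction = 0.5) {
  check_lists(lists)
  assert_scalar_number(prune_keep_fraction, "prune_keep_fraction", 0, 1,
                       strict_lower = TRUE)
  universe <- ranking_universe(lists)
  agg <- borda_aggregate(lists)
  weights <- rep(1, length(lists))
  for (round in seq_len(max_rounds)) {
    d <- vapply(lists, footrule_distance, numeric(1), aggregate = agg,
                universe = universe)
    weights <- 1 / (1 + d)
    agg_new <- borda_aggregate(lists, weights)
    if (identical(agg_new$gene, agg$gene)) {
      agg <- agg_new
      break
    }
    agg <- agg_new
  }
  keep <- ceiling(prune_keep_fraction * length(universe))
  pruned <- agg$gene[-seq_len(min(keep, nrow(agg)))]
  out <- agg[seq_len(min(keep, nrow(agg))), ]
  out$rank <- seq_len(nrow(out))
  out <- tibble::new_tibble(out, class = c("aggregated_ranking",
                                           "gene_ranking"))
  attr(out, "weights") <- weights
  attr(out, "pruned") <- pruned
  out
}

#' Run PU learning across cross-validation folds and aggregate the rankings
#'
#' For each subset of a [make_folds()] plan, relabels the instance with that
#' subset as its positive set, runs [grab_rank()] with the subset's derived
#' seed, and aggregates the per-fold rankings.
#'
#' @param instance A `pu_instance` with features (its positive set is the
#'   full labeled set; fold subsets are taken from `fold_plan`).
#' @param fold_plan A `fold_plan` from [make_folds()].
#' @param aggregator One of `"dibra"`, `"borda"`, `"median"`.
#' @param prune_keep_fraction Passed to [dibra_aggregate()].
#' @param ... Passed to [grab_rank()] (h, outer_max, epochs, ...).
#' @return An `aggregated_ranking` (for `"dibra"`) or `gene_ranking`, with
#'   attribute `fold_rankings` (the per-fold `gene_ranking` list).
#' @export
run_cv_aggregate <- function(instance, fold_plan,
                             aggregator = c("dibra", "borda", "median"),
                             prune_keep_fraction = 0.5, ...) {
  aggregator <- match.arg(aggregator)
  rankings <- purrr::map(seq_len(nrow(fold_plan)), function(i) {
    sub <- pu_instance(instance$network, fold_plan$train[[i]],
                       features = instance$features)
    grab_rank(sub, seed = fold_plan$run_seed[i], ...)
  })
  agg <- switch(aggregator,
    dibra = dibra_aggregate(rankings,
                            prune_keep_fraction = prune_keep_fraction),
    borda = borda_aggregate(rankings),
    median = median_rank_aggregate(rankings)
  )
  attr(agg, "fold_rankings") <- rankings
  agg
}
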