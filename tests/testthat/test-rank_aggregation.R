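test_that("fold plans partition positives and are seed-reproducible", {
  positives <- sprintf("p%03d", 1:100)
  plan <- make_folds(positives, repeats = 10, folds = 5, seed = 3)
  expect_equal(nrow(plan), 50)
  expect_true(all(lengths(plan$train) == 80))
  for (r in 1:10) {
    held <- plan$held_out[plan$repeat_id == r]
    expect_setequal(unlist(held), positives)             # cover
    expect_equal(sum(lengths(held)), length(positives))  # disjoint
  }
  plan2 <- make_folds(positives, repeats = 10, folds = 5, seed = 3)
  expect_identical(plan, plan2)
  expect_false(identical(plan,
                         make_folds(positives, repeats = 10, folds = 5,
                                    seed = 4)))
  expect_error(make_folds(positives[1:3], folds = 5), "at least")
})

test_that("Borda aggregation matches hand computation and its axioms", {
  l1 <- ranking_of(c("a", "b", "c"))
  l2 <- ranking_of(c("b", "a", "c"))
  agg <- borda_aggregate(list(l1, l2))
  # a and b tie at 1.5 Borda points; tie broken by gene id
  expect_equal(agg$gene, c("a", "b", "c"))
  expect_equal(agg$score[1], agg$score[2])
  expect_equal(agg$score[1], 1.5)
  # unanimity and single-list identity
  expect_equal(borda_aggregate(list(l1, l1))$gene, l1$gene)
  expect_equal(borda_aggregate(list(l1))$gene, l1$gene)
  # anonymity
  expect_equal(borda_aggregate(list(l2, l1)), agg)
  expect_error(borda_aggregate(list(l1, ranking_of(character()))), "empty")
})

test_that("median-rank aggregation uses rank medians with m+1 imputation", {
  l1 <- ranking_of(c("x", "y", "z", "w", "v", "u", "t", "s", "q"))
  filler <- sprintf("f%d", 1:6)
  lists <- list(
    ranking_of(c("a", "b", filler, "z")),        # a: 1, b: 2
    ranking_of(c("a", "z", "b", filler)),        # a: 1, b: 3
    ranking_of(c("z", "b", filler, "a"))         # a: 9, b: 2
  )
  # gene with ranks (1, 1, 9) has median 1 and beats ranks (2, 3, 2)
  expect_lt(stats::median(c(1, 1, 9)), stats::median(c(2, 3, 2)))
  agg <- median_rank_aggregate(lists)
  expect_lt(agg$rank[agg$gene == "a"], agg$rank[agg$gene == "b"])
  # identical lists aggregate to themselves
  expect_equal(median_rank_aggregate(list(l1, l1))$gene, l1$gene)
  # a gene absent everywhere except one tail entry lands last
  tail_lists <- list(ranking_of(c("a", "b", "c")),
                     ranking_of(c("a", "b", "c")),
                     ranking_of(c("a", "b", "c", "zz")))
  aggt <- median_rank_aggregate(tail_lists)
  expect_equal(aggt$gene[nrow(aggt)], "zz")
})

test_that("DIBRA downweights an adversarial reversed list", {
  genes <- c("a", "b", "c", "d", "e")
  lists <- list(
    ranking_of(genes),
    ranking_of(genes[c(1, 2, 3, 5, 4)]),
    ranking_of(rev(genes))
  )
  agg <- dibra_aggregate(lists, prune_keep_fraction = 1)
  w <- attr(agg, "weights")
  expect_equal(which.min(w), 3L)
  expect_true(all(w > 0 & w <= 1))
  expect_equal(agg$gene[1], "a")
})

test_that("DIBRA satisfies unanimity, anonymity and weight bounds", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      genes <- sprintf("g%02d", 1:12)
      lists <- lapply(1:4, function(i) ranking_of(sample(genes)))
      agg <- dibra_aggregate(lists, prune_keep_fraction = 1)
      perm <- sample(length(lists))
      agg_perm <- dibra_aggregate(lists[perm], prune_keep_fraction = 1)
      expect_equal(agg$gene, agg_perm$gene)              # anonymity
      expect_equal(sort(attr(agg, "weights")),
                   sort(attr(agg_perm, "weights")))
      expect_true(all(attr(agg, "weights") > 0 &
                        attr(agg, "weights") <= 1))
    }
  })
  l <- ranking_of(sprintf("g%02d", 1:10))
  same <- dibra_aggregate(list(l, l, l), prune_keep_fraction = 1)
  expect_equal(same$gene, l$gene)                        # unanimity
  expect_equal(attr(same, "weights"), rep(1, 3))         # exact match => 1
  single <- dibra_aggregate(list(l), prune_keep_fraction = 1)
  expect_equal(single$gene, l$gene)
  expect_equal(attr(single, "weights"), 1)
})

test_that("pruning removes exactly the suffix of the aggregate order", {
  withr::with_seed(31, {
    genes <- sprintf("g%02d", 1:20)
    lists <- lapply(1:3, function(i) ranking_of(sample(genes)))
    full <- dibra_aggregate(lists, prune_keep_fraction = 1)
    half <- dibra_aggregate(lists, prune_keep_fraction = 0.5)
    keep <- ceiling(0.5 * 20)
    expect_equal(half$gene, full$gene[seq_len(keep)])   # survivors in order
    expect_equal(attr(half, "pruned"), full$gene[(keep + 1):20])
    expect_equal(nrow(half) + length(attr(half, "pruned")), 20)
  })
})

test_that("cross-validated PU runs are counted and aggregated per plan", {
  net <- random_network(40, extra = 80, seed = 14)
  genes <- network_genes(net)
  positives <- genes[1:10]
  inst <- default_features(pu_instance(net, positives), rwr(net, positives))
  plan <- make_folds(positives, repeats = 1, folds = 5, seed = 9)
  agg <- run_cv_aggregate(inst, plan, aggregator = "dibra",
                          outer_max = 2, epochs = 10)
  folds <- attr(agg, "fold_rankings")
  expect_length(folds, 5)
  # each fold ranks the whole network
  for (f in folds) expect_setequal(f$gene, genes)
  # aggregators share the pre-pruning universe
  agg_b <- run_cv_aggregate(inst, plan, aggregator = "borda",
                            outer_max = 2, epochs = 10)
  expect_setequal(union(agg$gene, attr(agg, "pruned")), agg_b$gene)
  # same master seed, same files
  agg2 <- run_cv_aggregate(inst, plan, aggregator = "dibra",
                           outer_max = 2, epochs = 10)
  expect_identical(as.data.frame(agg), as.data.frame(agg2))
})
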