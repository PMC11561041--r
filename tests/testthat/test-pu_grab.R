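test_that("PU instance partitions genes into R and U with features", {
  net <- random_network(20, seed = 8)
  genes <- network_genes(net)
  inst <- toy_instance(net, positives = genes[1:4])
  expect_setequal(c(inst$positives, inst$unlabeled), genes)
  expect_length(intersect(inst$positives, inst$unlabeled), 0)
  expect_equal(rownames(inst$features), genes)
  expect_warning(pu_instance(net, c(genes[1], "nope")), "absent")
  expect_error(pu_instance(net, "nope"), "no positive")
})

test_that("default features are standardized and impute absent DEG info", {
  net <- random_network(40, seed = 9)
  genes <- network_genes(net)
  np <- rwr(net, genes[1:3])
  deg <- tibble::tibble(gene = genes[1:10],
                        log2fc = seq(-3, 3, length.out = 10),
                        pvalue = rep(0.01, 10), padj = rep(0.01, 10))
  inst <- pu_instance(net, genes[1:3])
  inst <- default_features(inst, np, deg)
  X <- inst$features
  expect_equal(ncol(X), 5)
  expect_equal(unname(colMeans(X)), rep(0, 5), tolerance = 1e-9)
  # genes absent from the DEG table carry the imputed (standardized) zero
  raw_lfc <- abs(c(seq(-3, 3, length.out = 10), rep(0, length(genes) - 10)))
  expect_equal(length(unique(X[genes[11:20], "abs_log2fc"])), 1)
})

test_that("soft-label NLL matches its closed-form micro-examples", {
  # a positive predicted at (0.5, 0.5) contributes exactly log 2
  expect_equal(pugrank:::soft_nll(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1),
                                  weights = 1),
               log(2), tolerance = 1e-12)
  # a (1, 0) belief is the same loss term as a hard positive label
  yhat <- matrix(c(0.8, 0.2), 1)
  expect_equal(pugrank:::soft_nll(matrix(c(1, 0), 1), yhat, 1),
               -log(0.8))
  # perfect prediction has zero loss
  expect_equal(pugrank:::soft_nll(matrix(c(1, 0), 1), matrix(c(1, 0), 1), 1),
               0)
})

test_that("analytic GAT gradients match numerical differentiation", {
  withr::with_seed(42, {
    net <- random_network(10, extra = 8)
    genes <- network_genes(net)
    inst <- toy_instance(net, positives = genes[1:3], n_features = 3)
    b <- stats::runif(length(genes))
    beliefs <- cbind(b, 1 - b)
    rownames(beliefs) <- genes
    params <- pugrank:::gat_init(3, hidden = 4, heads = 2, seed = 7)
    edges <- pugrank:::gat_edges(inst)
    lt <- pugrank:::gat_loss_targets(inst, beliefs)
    lossfun <- function(p) {
      fwd <- pugrank:::gat_forward(p, inst$features, edges)
      pugrank:::soft_nll(lt$targets, fwd$P, lt$weights)
    }
    fwd <- pugrank:::gat_forward(params, inst$features, edges)
    grads <- pugrank:::gat_grad(params, inst$features, edges, fwd,
                                lt$targets, lt$weights)
    flat <- unlist(params)
    gflat <- unlist(grads)
    eps <- 1e-6
    num <- vapply(seq_along(flat), function(i) {
      up <- flat; up[i] <- up[i] + eps
      dn <- flat; dn[i] <- dn[i] - eps
      (lossfun(utils::relist(up, params)) -
         lossfun(utils::relist(dn, params))) / (2 * eps)
    }, numeric(1))
    expect_equal(gflat, num, tolerance = 1e-6, ignore_attr = TRUE)
  })
})

test_that("classifier training is seeded and decreases the objective", {
  net <- random_network(30, seed = 5)
  genes <- network_genes(net)
  inst <- toy_instance(net, positives = genes[1:6], n_features = 2)
  b <- rep(0.2, length(genes))
  beliefs <- cbind(b, 1 - b)
  rownames(beliefs) <- genes
  f1 <- train_classifier(inst, beliefs, epochs = 30, seed = 10)
  f2 <- train_classifier(inst, beliefs, epochs = 30, seed = 10)
  expect_identical(f1$prob, f2$prob)
  expect_equal(unname(rowSums(f1$prob)), rep(1, length(genes)),
               tolerance = 1e-9)
  # more training cannot be worse at this budget scale
  f0 <- train_classifier(inst, beliefs, epochs = 1, seed = 10)
  expect_lt(f1$loss, f0$loss)
})

test_that("prior update is the strict indicator mean over unlabeled genes", {
  expect_equal(update_prior(c(a = 0.6, b = 0.4, c = 0.7, d = 0.2),
                            c("a", "b", "c", "d")), 0.5)
  expect_equal(update_prior(c(a = 0.5, b = 0.2), c("a", "b")), 0)
  expect_equal(update_prior(c(a = 0.9, b = 0.51), c("a", "b")), 1)
  expect_error(update_prior(c(a = 0.9), character()), "empty")
  # oracle: direct loop over random vectors
  withr::with_seed(2, {
    for (rep in 1:20) {
      p <- stats::runif(50)
      names(p) <- paste0("u", 1:50)
      manual <- sum(vapply(p, function(x) x > 0.5, logical(1))) / 50
      expect_equal(update_prior(p, names(p)), manual)
      expect_gte(update_prior(p, names(p)), 0)
      expect_lte(update_prior(p, names(p)), 1)
    }
  })
})

test_that("grab_rank honors the iteration contract and is deterministic", {
  net <- random_network(40, seed = 12)
  genes <- network_genes(net)
  inst <- toy_instance(net, positives = genes[1:8], n_features = 2)
  r1 <- grab_rank(inst, outer_max = 1, epochs = 10, seed = 5)
  expect_equal(attr(r1, "outer_iterations"), 1L)
  expect_length(attr(r1, "prior_history"), 2)  # initial 0 + one update
  expect_equal(attr(r1, "prior_history")[1], 0)
  r2 <- grab_rank(inst, outer_max = 1, epochs = 10, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$gene, genes)
  expect_true(all(diff(r1$score) <= 1e-12))
})

test_that("genes adjacent to several positives outrank degree-matched controls", {
  # hub-and-module fixture: u1 touches three positives, u2 three background
  # genes, with matching degrees
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 1),          # positive triangle
    c(4, 1), c(4, 2), c(4, 3),          # u1 -> three positives
    c(5, 6), c(5, 7), c(5, 8),          # u2 -> three background genes
    c(6, 7), c(7, 8), c(8, 6),          # background triangle
    c(3, 6)                             # connect components
  )
  net <- index_network(edges, 8)
  genes <- network_genes(net)
  positives <- c("g01", "g02", "g03")
  inst <- default_features(pu_instance(net, positives), rwr(net, positives))
  # exact-marginal oracle on the same Markov network says u1 > u2
  pot <- init_potentials(inst, prior = 0.2, h = 0.9)
  idx_edges <- cbind(match(net$from, genes), match(net$to, genes))
  exact <- mrf_marginals_brute(pot$phi, idx_edges, pot$psi)
  expect_gt(exact[match("g04", genes), 1], exact[match("g05", genes), 1])
  # the full PU loop agrees on the ordering
  rk <- grab_rank(inst, epochs = 40, outer_max = 5, seed = 2)
  expect_lt(rk$rank[rk$gene == "g04"], rk$rank[rk$gene == "g05"])
})

test_that("held-out planted positives outrank non-positives in a full run", {
  p_pooled <- c()
  sub_ranks <- c()
  bg_ranks <- c()
  for (seed in 1:2) {
    bm <- make_benchmark("small", seed = seed)
    deg <- wilcoxon_deg(bm$expression$expr, bm$expression$design)
    cfg <- run_config(k_deg = 25, k_np = 25, seed = seed)
    pos <- select_positives(deg, bm$network, bm$ko_gene, cfg)
    inst <- pu_instance(bm$network, pos$gene)
    inst <- default_features(inst, attr(pos, "np_scores"), deg)
    rk <- grab_rank(inst, seed = seed)
    ex <- exclude_input_positives(rk, pos$gene)
    held <- setdiff(bm$truth, pos$gene)
    sub_ranks <- c(sub_ranks, ex$rank[ex$gene %in% held])
    bg_ranks <- c(bg_ranks, ex$rank[!ex$gene %in% bm$truth])
  }
  wt <- stats::wilcox.test(sub_ranks, bg_ranks, alternative = "less")
  expect_lt(wt$p.value, 0.01)
  expect_lt(stats::median(sub_ranks), stats::median(bg_ranks))
})

test_that("the final prior roughly recovers a planted positive fraction", {
  hits <- 0
  for (pi_true in c(0.05, 0.1, 0.2)) {
    ok <- 0
    for (seed in 1:3) {
      # dense planted module over sparse background = strong homophily;
      # the planted positive fraction is pi_true, half of it labeled
      n <- 400
      module <- round(2 * pi_true * n)
      net <- simulate_network(n, module, p_in = 0.3, p_out = 0.005,
                              background_degree = 6, seed = seed)
      planted <- net$truth
      labeled <- planted[seq_len(ceiling(length(planted) / 2))]
      inst <- pu_instance(net$network, labeled)
      np <- rwr(net$network, labeled)
      inst <- default_features(inst, np)
      rk <- grab_rank(inst, epochs = 40, outer_max = 10, seed = seed)
      pi_hat <- attr(rk, "final_prior")
      truth_frac <- (length(planted) - length(labeled)) /
        (length(network_genes(net$network)) - length(labeled))
      if (abs(pi_hat - truth_frac) <= 0.5 * pi_true) ok <- ok + 1
    }
    hits <- hits + (ok >= 2)
  }
  expect_gte(hits, 2)  # loose stochastic bound: 2 of 3 settings recover
})
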