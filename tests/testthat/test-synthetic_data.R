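test_that("planted networks are reproducible with connected KO gene", {
  net1 <- simulate_network(300, 30, p_in = 0.2, p_out = 0.005,
                           background_degree = 6, seed = 5)
  net2 <- simulate_network(300, 30, p_in = 0.2, p_out = 0.005,
                           background_degree = 6, seed = 5)
  expect_identical(net1, net2)
  expect_true(net1$ko_gene %in% network_genes(net1$network))
  expect_true(all(net1$truth %in% network_genes(net1$network)))
  expect_true(all(net1$network$confidence >= 0.75 &
                    net1$network$confidence <= 1))
  # one connected component by construction
  g <- pugrank:::network_igraph(net1$network)
  expect_equal(igraph::components(g)$no, 1)
  expect_error(simulate_network(100, 100, 0.2, 0.01, 5), "below")
  expect_error(simulate_network(100, 10, 0.01, 0.2, 5), "exceed")
})

test_that("module wiring is denser inside than out", {
  net <- simulate_network(400, 40, p_in = 0.2, p_out = 0.003,
                          background_degree = 6, seed = 2)
  in_mod <- net$network$from %in% net$truth & net$network$to %in% net$truth
  cross <- xor(net$network$from %in% net$truth,
               net$network$to %in% net$truth)
  n_mod_pairs <- choose(length(net$truth), 2)
  n_bg <- length(setdiff(network_genes(net$network),
                         c(net$truth, net$ko_gene)))
  expect_gt(sum(in_mod) / n_mod_pairs,
            10 * sum(cross) / (length(net$truth) * (n_bg + 1)))
})

test_that("simulated expression encodes KO ablation and planted shifts", {
  net <- simulate_network(400, 40, p_in = 0.2, p_out = 0.003,
                          background_degree = 6, seed = 3)
  ex <- simulate_expression(net$network, net$ko_gene, net$truth,
                            n_wt = 10, n_ko = 10, effect_lfc = 2,
                            noise_sd = 0.3, seed = 4)
  ko_cols <- ex$design$sample[ex$design$condition == "KO"]
  expect_true(all(ex$expr[net$ko_gene, ko_cols] == 0))
  expect_true(all(ex$expr >= 0))
  # strong truth genes show |log2FC| near the planted effect
  deg <- wilcoxon_deg(ex$expr, ex$design)
  strong_lfc <- abs(deg$log2fc[deg$gene %in% ex$strong_truth])
  expect_true(mean(abs(strong_lfc - 2) < 0.5) > 0.9)
  # sub-threshold truth genes sit well below the strict cutoff
  sub_lfc <- abs(deg$log2fc[deg$gene %in% ex$subthreshold_truth])
  expect_true(all(sub_lfc < 1.5))
  expect_identical(
    ex$expr,
    simulate_expression(net$network, net$ko_gene, net$truth, n_wt = 10,
                        n_ko = 10, effect_lfc = 2, noise_sd = 0.3,
                        seed = 4)$expr
  )
  expect_error(
    simulate_expression(net$network, net$ko_gene, net$truth, n_wt = 2,
                        n_ko = 10), "3 samples"
  )
})

test_that("a null effect yields no significant DEGs beyond BH expectation", {
  hits <- vapply(1:5, function(seed) {
    net <- simulate_network(300, 30, p_in = 0.2, p_out = 0.005,
                            background_degree = 6, seed = seed)
    ex <- simulate_expression(net$network, net$ko_gene, net$truth,
                              effect_lfc = 0, dropout = 0, seed = seed)
    deg <- wilcoxon_deg(ex$expr, ex$design)
    sig <- filter_degs(deg)
    sum(sig$gene != net$ko_gene)
  }, numeric(1))
  expect_lte(stats::median(hits), 1)
})

test_that("benchmark presets honor their parameter contracts", {
  small <- make_benchmark("small", seed = 2)
  expect_lte(length(network_genes(small$network)), 500)
  expect_identical(make_benchmark("small", seed = 2), small)
  expect_error(make_benchmark("nope", seed = 1))
  default <- make_benchmark("default", seed = 2)
  inflated <- make_benchmark("inflated_fp", seed = 2)
  secondary <- make_benchmark("secondary_top", seed = 2)
  # same planted topology, different downstream selection knobs
  expect_identical(default$network, inflated$network)
  expect_identical(default$network, secondary$network)
  expect_equal(inflated$selection$k_deg, 10 * default$selection$k_deg)
  expect_equal(inflated$selection$k_np, 10 * default$selection$k_np)
  expect_equal(secondary$selection$deg_offset, 50)
  expect_equal(secondary$selection$np_offset, 50)
})

test_that("sub-threshold truth genes escape the strict DEG cutoff", {
  missed <- vapply(1:5, function(seed) {
    bm <- make_benchmark("small", seed = seed)
    deg <- wilcoxon_deg(bm$expression$expr, bm$expression$design)
    sig <- filter_degs(deg)
    sub <- bm$expression$subthreshold_truth
    mean(!sub %in% sig$gene)
  }, numeric(1))
  # the rescue scenario exists: >= 90% of sub-threshold genes are missed
  expect_gte(mean(missed >= 0.9), 0.8)
})

test_that("propagation seeded by KO + top DEGs concentrates on the module", {
  ranks <- vapply(1:3, function(seed) {
    bm <- make_benchmark("small", seed = seed)
    deg <- wilcoxon_deg(bm$expression$expr, bm$expression$design)
    deg_top <- top_k(filter_degs(deg), 25, exclude = bm$ko_gene)
    np <- rwr(bm$network, unique(c(bm$ko_gene, deg_top)))
    stats::median(match(bm$truth, np$gene)) / nrow(np)
  }, numeric(1))
  expect_true(all(ranks < 0.2))  # median truth rank in the top 20%
})

test_that("synthetic instances round-trip through their file layout", {
  bm <- make_benchmark("small", seed = 6)
  dir <- withr::local_tempdir()
  write_synthetic_instance(bm, dir)
  net <- load_edge_list(file.path(dir, "network.tsv"))
  expect_equal(as.data.frame(net), as.data.frame(bm$network))
  expect_equal(load_gene_list(file.path(dir, "truth_genes.txt")), bm$truth)
  expect_equal(load_gene_list(file.path(dir, "ko_gene.txt")), bm$ko_gene)
})
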