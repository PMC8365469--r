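test_that("spec invariants are enforced at construction", {
  expect_s3_class(synth_spec(), "synth_spec")
  expect_error(synth_spec(n_seeds = 70, n_disease = 60), "n_seeds")
  expect_error(synth_spec(p_in = 0.05, p_out = 0.05), "p_out < p_in")
  expect_error(synth_spec(enrich_module = 0.05, enrich_background = 0.05),
               "enrich_background < enrich_module")
  expect_error(synth_spec(weight_range = c(0, 1)), "positive")
  expect_error(synth_spec(n_module_lnc = 50, n_lnc = 40), "exceed")
})

test_that("generated bundles have the requested bookkeeping", {
  b <- generate_bundle(synth_spec(
    n_genes = 60, n_disease = 15, n_seeds = 8, p_in = 0.6, p_out = 0.05,
    n_lnc = 10, n_mi = 10, n_module_lnc = 4, n_module_mi = 4, rng_seed = 1
  ))
  expect_lte(length(b$network$nodes), 60)
  expect_length(b$seeds, 8)
  expect_true(all(b$seeds %in% b$network$nodes))
  expect_lte(sum(b$truth$label), 15)
  # seeds are a subset of the truth positives
  expect_true(all(b$seeds %in% b$truth$gene[b$truth$label == 1]))
  # network connected after retention
  g <- igraph::graph_from_data_frame(b$network$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  # regulation rows follow network node order, binary entries
  expect_equal(rownames(b$regulation), b$network$nodes)
  expect_true(all(b$regulation %in% c(0, 1)))
})

test_that("same seed reproduces the bundle exactly; different seeds differ", {
  s <- synth_spec(n_genes = 80, n_disease = 20, n_seeds = 10, rng_seed = 9)
  b1 <- generate_bundle(s)
  b2 <- generate_bundle(s)
  expect_identical(adjacency_matrix(b1$network), adjacency_matrix(b2$network))
  expect_identical(b1$seeds, b2$seeds)
  expect_identical(b1$regulation, b2$regulation)
  s2 <- synth_spec(n_genes = 80, n_disease = 20, n_seeds = 10, rng_seed = 10)
  expect_false(identical(generate_bundle(s2)$seeds, b1$seeds))
})

test_that("planted module is denser than background across bundles", {
  set.seed(1)
  ratios <- vapply(1:20, function(i) {
    b <- generate_bundle(synth_spec(
      n_genes = 80, n_disease = 20, n_seeds = 10, p_in = 0.3, p_out = 0.04,
      n_lnc = 10, n_mi = 10, n_module_lnc = 4, n_module_mi = 4, rng_seed = i
    ))
    A <- adjacency_matrix(b$network)
    deg <- rowSums(A > 0)
    module <- b$truth$gene[b$truth$label == 1]
    mean(deg[module]) / mean(deg[setdiff(rownames(A), module)])
  }, 1)
  expect_true(all(ratios > 1))
})

test_that("module genes are enriched for the module regulators", {
  b <- generate_bundle(synth_spec(rng_seed = 2))
  module <- b$truth$label == 1
  module_rna_cols <- c(sprintf("L%03d", 1:10), sprintf("M%03d", 1:10))
  hit_mod <- mean(b$regulation[module, module_rna_cols])
  hit_bg <- mean(b$regulation[!module, module_rna_cols])
  expect_gt(hit_mod, 3 * hit_bg)
})

test_that("exported files round-trip to the identical in-memory bundle", {
  b <- generate_bundle(synth_spec(
    n_genes = 60, n_disease = 15, n_seeds = 8, p_in = 0.6, p_out = 0.05,
    n_lnc = 10, n_mi = 10, n_module_lnc = 4, n_module_mi = 4, rng_seed = 4
  ))
  dir <- withr::local_tempdir()
  export_bundle(b, dir)
  net2 <- read_gene_network(file.path(dir, "edges.tsv"), score_scale = 1)
  expect_identical(adjacency_matrix(net2), adjacency_matrix(b$network))
  expect_message(seeds2 <- read_seed_genes(file.path(dir, "seeds.txt"), net2))
  expect_identical(seeds2, b$seeds)
  reg2 <- regulation_matrix(
    read_regulation_pairs(file.path(dir, "regulation.tsv")), net2
  )
  expect_identical(unname(reg2), unname(b$regulation))
  expect_identical(colnames(reg2), colnames(b$regulation))
  truth2 <- readr::read_tsv(file.path(dir, "truth.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(truth2), length(net2$nodes))
})

test_that("signal ablation degrades ranking monotonically", {
  # three spec levels: strong, weak, none — pipeline separation must decay
  specs <- list(
    strong = synth_spec(n_genes = 100, n_disease = 25, n_seeds = 12,
                        p_in = 0.4, p_out = 0.04, enrich_module = 0.7,
                        enrich_background = 0.05, n_lnc = 16, n_mi = 16,
                        n_module_lnc = 6, n_module_mi = 6, rng_seed = 8),
    weak = synth_spec(n_genes = 100, n_disease = 25, n_seeds = 12,
                      p_in = 0.1, p_out = 0.05, enrich_module = 0.2,
                      enrich_background = 0.1, n_lnc = 16, n_mi = 16,
                      n_module_lnc = 6, n_module_mi = 6, rng_seed = 8)
  )
  aucs <- vapply(specs, function(s) {
    b <- generate_bundle(s)
    res <- rwrvm_run(b$network, b$seeds, b$regulation, rng_seed = 8)
    sc <- dplyr::left_join(res$scores, b$truth, by = "gene")
    sc <- sc[!sc$is_seed, ]
    roc_auc(sc$score_final, sc$label)
  }, 1)
  expect_gt(aucs[["strong"]], aucs[["weak"]])
  expect_gt(aucs[["strong"]], 0.8)
})
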