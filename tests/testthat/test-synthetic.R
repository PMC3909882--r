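test_that("generate_network honors its construction contract", {
  g <- generate_network(10, model = "random", mean_degree = 2, seed = 1)
  expect_equal(igraph::gorder(g), 10)
  expect_equal(igraph::ecount(g), 10) # p * mean_degree / 2
  expect_false(any(igraph::which_loop(g)))
  expect_false(igraph::any_multiple(g))

  g2 <- generate_network(10, model = "random", mean_degree = 2, seed = 1)
  expect_setequal(grnscape:::network_edge_keys(g2),
                  grnscape:::network_edge_keys(g))

  expect_error(generate_network(2, mean_degree = 1), "p")
  expect_error(generate_network(10, mean_degree = 20), "more than")
})

test_that("scale-free generator yields a heavy-tailed degree sequence", {
  g <- generate_network(5000, model = "scale-free", mean_degree = 2,
                        seed = 11)
  fit <- fit_power_law(igraph::degree(g), xmin = 1)
  expect_gt(fit$alpha, 2)
  expect_lt(fit$alpha, 4)
})

test_that("simulate_expression realizes planted edge correlations", {
  g <- g_from_edges("A-B")
  truth <- planted_truth(g, edge_strength = 0.8)
  x <- simulate_expression(truth, n_samples = 2000, seed = 3)
  expect_equal(dim(x), c(2, 2000))
  r <- cor(x["A", ], x["B", ])
  expect_gt(abs(r), 0.7)
  expect_lt(abs(r), 0.9)
})

test_that("empty networks give near-zero correlations everywhere", {
  g <- igraph::make_empty_graph(20, directed = FALSE)
  igraph::V(g)$name <- grnscape:::gene_ids(20)
  n <- 2000
  x <- simulate_expression(planted_truth(g), n_samples = n, seed = 4)
  cc <- cor(t(x))
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 4 / sqrt(n))
})

test_that("simulate_expression is deterministic and validates inputs", {
  g <- g_from_edges(c("A-B", "B-C"))
  x1 <- simulate_expression(planted_truth(g), 10, seed = 5)
  x2 <- simulate_expression(planted_truth(g), 10, seed = 5)
  expect_identical(x1, x2)
  expect_error(simulate_expression(planted_truth(g), 2), "n_samples")
  expect_error(simulate_expression(planted_truth(g), 10, noise_sd = 0),
               "noise_sd")
  expect_error(planted_truth(g, edge_strength = 1), "edge_strength")
})

test_that("planted annotation terms carry excess within-term edges", {
  net <- generate_network(100, model = "scale-free", mean_degree = 3,
                          seed = 6)
  truth <- planted_truth(net)
  ann <- generate_annotations(truth, n_terms = 20, size_range = c(12, 12),
                              n_planted = 5, seed = 7)
  planted <- attr(ann, "planted")
  expect_length(planted, 5)
  p <- igraph::gorder(net)
  dens <- igraph::ecount(net) / pair_count(p)
  for (id in planted) {
    k <- igraph::ecount(igraph::induced_subgraph(net, ann[[id]]))
    # expected within-term edges under a uniform draw of the same size
    expect_gte(k, pair_count(length(ann[[id]])) * dens)
  }
})

test_that("catalogs label every gene with an allowed chromosome", {
  genes <- grnscape:::gene_ids(200)
  cat24 <- generate_catalog(genes, n_chrom = 24, seed = 8)
  expect_identical(cat24$gene, genes)
  expect_true(all(cat24$chromosome %in% c(as.character(1:22), "X", "Y")))
  expect_true(all(table(cat24$gene) == 1))
  # with enough genes every chromosome is populated, as in a real genome
  expect_length(unique(cat24$chromosome), 24)
  expect_error(generate_catalog(genes, n_chrom = 25), "n_chrom")
})

test_that("census draws are uniform without bias and skewed with it", {
  genes <- grnscape:::gene_ids(400)
  module <- genes[1:40]
  # biased draws hit the module far more often than the 10% base rate
  hits <- replicate(20, {
    cs <- generate_census(genes, 40, bias_genes = module, bias_weight = 20,
                          seed = sample.int(1e6, 1))
    mean(cs %in% module)
  })
  expect_gt(mean(hits), 0.3)
  unb <- replicate(20, {
    cs <- generate_census(genes, 40, seed = sample.int(1e6, 1))
    mean(cs %in% module)
  })
  expect_lt(mean(unb), 0.2)
  expect_error(generate_census(genes, 401), "exceeds")
})

test_that("plant_cooperation concentrates edges on the chosen pair", {
  net <- generate_network(200, model = "random", mean_degree = 4, seed = 9)
  catalog <- generate_catalog(igraph::V(net)$name, n_chrom = 4, seed = 10)
  before <- chrom_pair_counts(net, catalog)["1", "2"]
  net2 <- plant_cooperation(net, catalog, c("1", "2"), fraction = 0.3,
                            seed = 11)
  after <- chrom_pair_counts(net2, catalog)["1", "2"]
  expect_gt(after, before + 0.2 * igraph::ecount(net))
})

test_that("simulate_study wires all artifacts together consistently", {
  study <- simulate_study(p = 30, n_samples = 20, n_terms = 10,
                          n_census = 5, coop_pair = c("1", "2"), seed = 12)
  genes <- igraph::V(study$truth$network)$name
  expect_identical(rownames(study$expression), genes)
  expect_identical(study$catalog$gene, genes)
  expect_true(all(study$census %in% genes))
  expect_identical(sum(study$catalog$census), 5L)
  expect_identical(study$truth$module_terms, attr(study$annotations, "planted"))
})
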