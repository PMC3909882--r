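test_that("gaussian_mi matches the bivariate-Gaussian closed form", {
  expect_identical(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.9), -0.5 * log(0.19))
  expect_equal(gaussian_mi(0.9), 0.8303655, tolerance = 1e-6)
  # even in rho, and finite at the clamp ceiling
  rhos <- seq(-1, 1, by = 0.1)
  expect_equal(gaussian_mi(rhos), gaussian_mi(-rhos))
  expect_equal(gaussian_mi(1), -0.5 * log(1e-12))
  expect_error(gaussian_mi(1.5), "rho")
})

test_that("estimate_mi_matrix is symmetric with clamped duplicates", {
  set.seed(1)
  x <- matrix(rnorm(5 * 50), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  x[2, ] <- x[1, ] # duplicated pair -> rho = 1 boundary
  mi <- estimate_mi_matrix(x)
  expect_identical(mi, t(mi))
  expect_equal(mi["g1", "g2"], -0.5 * log(1e-12))
  expect_true(all(mi >= 0))

  x[3, ] <- 7 # zero variance
  expect_error(estimate_mi_matrix(x), "zero-variance.*g3")
  expect_silent(mi0 <- estimate_mi_matrix(x, zero_var = "zero"))
  expect_equal(mi0["g3", "g1"], 0)
})

test_that("independent genes give near-zero MI off the diagonal", {
  set.seed(2)
  x <- matrix(rnorm(20 * 1000), nrow = 20,
              dimnames = list(paste0("g", 1:20), NULL))
  mi <- estimate_mi_matrix(x)
  diag(mi) <- 0
  expect_lt(max(mi), 0.01)
})

test_that("mi_null is deterministic, self-calibrating, and bounded below", {
  set.seed(3)
  x <- matrix(rnorm(30 * 100), nrow = 30,
              dimnames = list(paste0("g", 1:30), NULL))
  null1 <- mi_null(x, n_resample = 2000, seed = 7)
  expect_identical(null1, mi_null(x, n_resample = 2000, seed = 7))
  expect_error(mi_null(x, n_resample = 50), "n_resample")

  # the pool's own 95th percentile classifies ~5% of fresh null MIs
  thr <- quantile(null1, 0.95)
  fresh <- mi_null(x, n_resample = 4000, seed = 8)
  expect_equal(mean(fresh > thr), 0.05, tolerance = 0.02)

  # boundary: larger than every null value -> pseudo-count floor
  expect_equal(mi_pvalue(max(null1) + 1, null1), 1 / (length(null1) + 1))
  expect_equal(mi_pvalue(-1, null1), 1)
})

test_that("c3net applies the per-gene max rule with significance gating", {
  genes <- c("A", "B", "C")
  mi <- matrix(0, 3, 3, dimnames = list(genes, genes))
  mi["A", "B"] <- mi["B", "A"] <- 0.9
  mi["A", "C"] <- mi["C", "A"] <- 0.2
  mi["B", "C"] <- mi["C", "B"] <- 0.5
  null_small <- seq(0, 0.1, length.out = 1000) # everything significant
  g <- c3net(mi, null_small, alpha = 0.05)
  # A picks B; B picks A; C picks B
  expect_setequal(grnscape:::network_edge_keys(g), c("A|B", "B|C"))

  # nothing passes against a null that dominates all observed MIs
  null_big <- rep(10, 1000)
  expect_equal(igraph::ecount(c3net(mi, null_big, alpha = 0.05)), 0)
})

test_that("c3net never exceeds one contributed edge per gene", {
  set.seed(4)
  for (rep in 1:5) {
    p <- 20
    x <- matrix(rnorm(p * 40), nrow = p,
                dimnames = list(grnscape:::gene_ids(p), NULL))
    mi <- estimate_mi_matrix(x)
    null <- mi_null(x, n_resample = 500, seed = rep)
    g <- c3net(mi, null, alpha = 0.5)
    expect_lte(igraph::ecount(g), p)
  }
})

test_that("bootstrap ensembles are reproducible with B members", {
  set.seed(5)
  g0 <- generate_network(20, "random", mean_degree = 2, seed = 5)
  x <- simulate_expression(planted_truth(g0), 60, seed = 5)
  ens <- bootstrap_ensemble(x, B = 5, seed = 9, null_size = 500)
  expect_s3_class(ens, "bootstrap_ensemble")
  expect_length(ens$networks, 5)
  ens2 <- bootstrap_ensemble(x, B = 5, seed = 9, null_size = 500)
  for (k in 1:5) {
    expect_setequal(grnscape:::network_edge_keys(ens2$networks[[k]]),
                    grnscape:::network_edge_keys(ens$networks[[k]]))
  }
})

test_that("true edges recur in more ensemble members than non-edges", {
  g0 <- generate_network(50, "scale-free", mean_degree = 1.5, seed = 6)
  x <- simulate_expression(planted_truth(g0, edge_strength = 0.8), 150,
                           seed = 6)
  ens <- bootstrap_ensemble(x, B = 10, seed = 10, null_size = 2000)
  freq <- aggregate_ensemble(ens)
  keys <- grnscape:::edge_keys(freq$gene1, freq$gene2)
  truth_keys <- grnscape:::network_edge_keys(g0)
  is_true <- keys %in% truth_keys
  # average occurrence over all possible pairs, absent pairs count 0
  p <- igraph::gorder(g0)
  n_true <- length(truth_keys)
  mean_true <- sum(freq$count[is_true]) / n_true
  mean_false <- sum(freq$count[!is_true]) / (pair_count(p) - n_true)
  expect_gt(mean_true, mean_false)
})

test_that("binomial edge test matches exact tails and keeps boundaries", {
  freq <- structure(
    data.frame(gene1 = c("A", "B", "C"), gene2 = c("B", "C", "D"),
               count = c(100L, 10L, 1L), stringsAsFactors = FALSE),
    B = 100L, genes = c("A", "B", "C", "D"),
    class = c("edge_frequency", "data.frame"))
  # fixed p0 = 0.01: k = 10 has tail ~1.1e-7 (kept), k = 1 is sub-null
  net <- binomial_edge_test(freq, ensemble_alpha = 0.05, p0 = 0.01)
  keys <- grnscape:::network_edge_keys(net)
  expect_true(all(c("A|B", "B|C") %in% keys))
  expect_false("C|D" %in% keys)
  expect_equal(pbinom(9, 100, 0.01, lower.tail = FALSE),
               bf_binom_tail(10, 100, 0.01), tolerance = 1e-12)
  # maximal count survives even a large p0
  net2 <- binomial_edge_test(freq, ensemble_alpha = 0.05, p0 = 0.2)
  expect_true("A|B" %in% grnscape:::network_edge_keys(net2))
  # k = 1 against p0 = 0.5 has tail ~1 -> dropped
  expect_gt(pbinom(0, 100, 0.5, lower.tail = FALSE), 0.999)
})

test_that("the aggregation test is monotone in alpha and in counts", {
  mk_freq <- function(counts) {
    structure(
      data.frame(gene1 = paste0("A", seq_along(counts)),
                 gene2 = paste0("B", seq_along(counts)),
                 count = as.integer(counts), stringsAsFactors = FALSE),
      B = 50L,
      genes = c(paste0("A", seq_along(counts)),
                paste0("B", seq_along(counts))),
      class = c("edge_frequency", "data.frame"))
  }
  freq <- mk_freq(c(2, 5, 10, 20, 40))
  kept <- function(net) grnscape:::network_edge_keys(net)
  lo <- kept(binomial_edge_test(freq, ensemble_alpha = 0.01, p0 = 0.1))
  hi <- kept(binomial_edge_test(freq, ensemble_alpha = 0.2, p0 = 0.1))
  expect_true(all(lo %in% hi))
  # raising one count never flips kept -> dropped
  freq2 <- mk_freq(c(2, 5, 11, 20, 40))
  k1 <- kept(binomial_edge_test(freq, ensemble_alpha = 0.05, p0 = 0.1))
  k2 <- kept(binomial_edge_test(freq2, ensemble_alpha = 0.05, p0 = 0.1))
  expect_true(all(k1 %in% k2))
})

test_that("the final network is a subset of the ensemble union", {
  study <- simulate_study(p = 30, n_samples = 60, seed = 13)
  cfg <- pipeline_config(bootstrap_count = 8, null_size = 1000,
                         rng_seed = 13)
  fit <- bc3net(study$expression, cfg)
  union_keys <- grnscape:::edge_keys(fit$frequency$gene1,
                                     fit$frequency$gene2)
  expect_true(all(grnscape:::network_edge_keys(fit$network) %in% union_keys))
})
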