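#' Gaussian mutual information from a Pearson correlation
#'
#' Under a bivariate Gaussian model the mutual information between two
#' variables with correlation \eqn{\rho} has the closed form
#' \eqn{I = -\tfrac{1}{2}\log(1-\rho^2)} (in nats). \eqn{\rho^2} is
#' clamped to `1 - 1e-12` so perfectly correlated pairs map to a large
#' finite ceiling rather than infinity.
#'
#' @param rho Numeric vector of correlations in \[-1, 1\].
#' @return Non-negative mutual information values (nats), vectorized.
#' @examples
#' gaussian_mi(0)    # 0
#' gaussian_mi(0.9)  # -0.5 * log(1 - 0.81)
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) > 1 + 1e-9, na.rm = TRUE)) {
    stop("`rho` must lie in [-1, 1]")
  }
  # floor 1 - rho^2 itself so the ceiling value is exact at |rho| = 1
  -0.5 * log(pmax(1 - rho^2, 1e-12))
}

# Row variances without an extra dependency.
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Pairwise mutual-information matrix of an expression matrix
#'
#' Estimates all pairwise gene-gene mutual information values by applying
#' the Gaussian transform [gaussian_mi()] to the sample Pearson
#' correlation of each gene pair.
#'
#' @param expr Numeric genes x samples matrix with >= 3 samples.
#' @param zero_var How to treat genes with zero variance: `"error"`
#'   (default) aborts listing the offending genes; `"zero"` defines their
#'   correlations as 0, appropriate inside bootstrap replicates where a
#'   resample can flatten a gene.
#' @return Symmetric p x p matrix of MI values (nats) with gene dimnames;
#'   the diagonal is set to 0 and is ignored by all consumers.
#' @export
estimate_mi_matrix <- function(expr, zero_var = c("error", "zero")) {
  zero_var <- match.arg(zero_var)
  if (ncol(expr) < 3) stop("need >= 3 samples")
  v <- row_vars(expr)
  if (any(v == 0)) {
    if (zero_var == "error") {
      stop("zero-variance gene(s): ",
           paste(rownames(expr)[v == 0], collapse = ", "))
    }
  }
  cc <- suppressWarnings(cor(t(expr)))
  cc[!is.finite(cc)] <- 0
  mi <- gaussian_mi(cc)
  diag(mi) <- 0
  dimnames(mi) <- list(rownames(expr), rownames(expr))
  mi
}

# Correlation between corresponding rows of two equal-shape matrices.
paired_row_cor <- function(x, y) {
  xs <- x - rowMeans(x)
  ys <- y - rowMeans(y)
  num <- rowSums(xs * ys)
  den <- sqrt(rowSums(xs^2) * rowSums(ys^2))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Permutation null distribution of mutual-information estimates
#'
#' Pools MI values computed between independently permuted gene rows:
#' random gene pairs are drawn, one member's samples are shuffled
#' (destroying any dependence while keeping both marginals), and the
#' Gaussian MI of the resulting correlation is recorded. The pool serves
#' as the empirical null for right-tail p-values of observed MI values.
#'
#' @param expr Numeric genes x samples matrix.
#' @param n_resample Size of the null pool (>= 100; default 10000).
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of null MI values.
#' @seealso [mi_pvalue()]
#' @export
mi_null <- function(expr, n_resample = 10000, seed = NULL) {
  if (n_resample < 100) stop("`n_resample` must be >= 100")
  p <- nrow(expr)
  n <- ncol(expr)
  if (p < 2) stop("need >= 2 genes")
  with_seed(seed, {
    i <- sample.int(p, n_resample, replace = TRUE)
    j <- sample.int(p, n_resample, replace = TRUE)
    x <- expr[i, , drop = FALSE]
    y <- expr[j, , drop = FALSE]
    yp <- matrix(y[cbind(rep(seq_len(n_resample), n),
                         as.vector(vapply(seq_len(n_resample),
                                          function(k) sample.int(n),
                                          integer(n))))],
                 nrow = n_resample)
    sort(gaussian_mi(paired_row_cor(x, yp)))
  })
}

#' Right-tail empirical p-value of MI values against a null pool
#'
#' Uses the pseudo-count rule `p = (#\{null >= mi\} + 1) / (n + 1)`, so an
#' observation exceeding every null value gets `1 / (n + 1)` rather
#' than 0.
#'
#' @param mi Numeric vector of observed MI values.
#' @param null Sorted null pool from [mi_null()].
#' @return Numeric vector of p-values in (0, 1\].
#' @export
mi_pvalue <- function(mi, null) {
  n <- length(null)
  n_below <- findInterval(mi, null, left.open = TRUE) # null values < mi
  (n - n_below + 1) / (n + 1)
}

#' Conservative maximum-MI network (C3NET step)
#'
#' For each gene `g`, the single candidate partner is the gene maximizing
#' `MI(g, .)` (ties broken toward the lexicographically smaller partner
#' id); the edge is added if and only if the empirical p-value of that
#' maximal MI passes a Bonferroni correction at level `alpha` with
#' multiplier `p` (one independence test per gene). Each gene therefore
#' contributes at most one edge and the result has at most `p` edges.
#'
#' @param mi Symmetric MI matrix with gene dimnames
#'   (see [estimate_mi_matrix()]).
#' @param null Sorted null pool from [mi_null()].
#' @param alpha Significance level before correction (default 0.05).
#' @return Undirected simple igraph network over all genes of `mi`.
#' @export
c3net <- function(mi, null, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  genes <- rownames(mi)
  p <- nrow(mi)
  thr <- alpha / p
  mm <- mi
  diag(mm) <- -Inf
  edges <- character(0)
  for (g in seq_len(p)) {
    best <- max(mm[g, ])
    cand <- which(mm[g, ] == best)
    h <- cand[order(genes[cand])][1]
    if (mi_pvalue(mi[g, h], null) <= thr) {
      edges <- c(edges, edge_keys(genes[g], genes[h]))
    }
  }
  edges <- unique(edges)
  g_out <- igraph::make_empty_graph(n = p, directed = FALSE)
  igraph::V(g_out)$name <- genes
  if (length(edges) > 0) {
    parts <- do.call(rbind, strsplit(edges, "|", fixed = TRUE))
    g_out <- igraph::add_edges(g_out, rbind(parts[, 1], parts[, 2]))
  }
  igraph::simplify(g_out)
}

#' Bootstrap ensemble of C3NET networks
#'
#' Draws `B` bootstrap datasets by resampling samples (columns) with
#' replacement -- never genes, so every replicate is a dataset over the
#' same gene set -- and infers one C3NET network from each. Genes that
#' lose all variance in a replicate contribute correlation 0 there. The
#' MI null pool is estimated once from the original dataset and shared
#' across replicates (the independence null does not depend on the
#' resample; pooling stabilizes the p-value resolution).
#'
#' @param expr Numeric genes x samples matrix.
#' @param B Number of bootstrap members (>= 1).
#' @param seed Optional integer seed.
#' @param alpha Per-member significance level (default 0.05).
#' @param null Optional precomputed null pool; estimated via [mi_null()]
#'   with `null_size` values when missing.
#' @param null_size Null pool size when `null` is missing.
#' @return An object of class `bootstrap_ensemble`: list with `networks`
#'   (length-`B` list of igraph networks in index order), `B`, `genes`.
#' @export
bootstrap_ensemble <- function(expr, B = 100, seed = NULL, alpha = 0.05,
                               null = NULL, null_size = 10000) {
  if (B < 1) stop("`B` must be >= 1")
  n <- ncol(expr)
  if (is.null(null)) {
    null <- mi_null(expr, n_resample = null_size,
                    seed = if (is.null(seed)) NULL else seed + 1000003L)
  }
  nets <- with_seed(seed, {
    lapply(seq_len(B), function(k) {
      cols <- sample.int(n, n, replace = TRUE)
      mi <- estimate_mi_matrix(expr[, cols, drop = FALSE],
                               zero_var = "zero")
      c3net(mi, null, alpha = alpha)
    })
  })
  structure(list(networks = nets, B = B, genes = rownames(expr)),
            class = "bootstrap_ensemble")
}

#' Aggregate a bootstrap ensemble into edge frequencies
#'
#' Counts, for every edge observed in any member network, the number of
#' members `k_e` (1..B) containing it: the weighted aggregate network
#' whose counts are the test statistics of the binomial edge test.
#'
#' @param ensemble A [bootstrap_ensemble()] object.
#' @return An object of class `edge_frequency`: data frame with columns
#'   `gene1`, `gene2`, `count`, plus attributes `B` and `genes`.
#' @export
aggregate_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "bootstrap_ensemble")) {
    stop("`ensemble` must be a bootstrap_ensemble")
  }
  keys <- unlist(lapply(ensemble$networks, network_edge_keys))
  if (length(keys) == 0) {
    counts <- integer(0)
    keys_u <- character(0)
  } else {
    tab <- table(keys)
    keys_u <- names(tab)
    counts <- as.integer(tab)
  }
  parts <- if (length(keys_u) > 0) {
    do.call(rbind, strsplit(keys_u, "|", fixed = TRUE))
  } else {
    matrix(character(0), ncol = 2)
  }
  out <- data.frame(gene1 = parts[, 1], gene2 = parts[, 2],
                    count = counts, stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, B = ensemble$B, genes = ensemble$genes,
            class = c("edge_frequency", "data.frame"))
}

#' Binomial test on ensemble edge frequencies
#'
#' An edge observed in `k_e` of `B` bootstrap members is kept if its
#' one-sided binomial tail probability `P(X >= k_e | B, p0)` is at most
#' `ensemble_alpha`. By default `p0` is the ensemble's mean edge frequency
#' over the union of observed edges, `sum(k_e) / (B * #edges)`, a
#' data-driven null that asks which edges recur more often than a typical
#' observed edge.
#'
#' @param freq An [aggregate_ensemble()] result.
#' @param ensemble_alpha Significance level (default 0.05).
#' @param p0 Optional fixed binomial null probability in (0, 1).
#' @return The final undirected network (igraph) over the ensemble's gene
#'   set, with edge attributes `count` and `p_value`.
#' @export
binomial_edge_test <- function(freq, ensemble_alpha = 0.05, p0 = NULL) {
  if (!inherits(freq, "edge_frequency")) {
    stop("`freq` must come from aggregate_ensemble()")
  }
  B <- attr(freq, "B")
  if (is.null(B) || B == 0) stop("ensemble size B must be >= 1")
  genes <- attr(freq, "genes")
  g_out <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g_out)$name <- genes
  if (nrow(freq) == 0) return(g_out)
  if (is.null(p0)) {
    p0 <- sum(freq$count) / (B * nrow(freq))
    p0 <- min(max(p0, 1e-12), 1 - 1e-12)
  }
  if (p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)")
  pv <- pbinom(freq$count - 1, size = B, prob = p0, lower.tail = FALSE)
  keep <- pv <= ensemble_alpha
  if (any(keep)) {
    g_out <- igraph::add_edges(g_out,
                               rbind(freq$gene1[keep], freq$gene2[keep]),
                               attr = list(count = freq$count[keep],
                                           p_value = pv[keep]))
  }
  igraph::simplify(g_out, edge.attr.comb = "first")
}

#' Bagged C3NET network inference
#'
#' The full inference pipeline: a pooled MI permutation null is estimated
#' from the data, `B` bootstrap C3NET networks are inferred
#' ([bootstrap_ensemble()]), edge occurrence counts are aggregated
#' ([aggregate_ensemble()]) and the final network is selected by the
#' binomial edge test ([binomial_edge_test()]).
#'
#' @param expr Numeric genes x samples matrix.
#' @param config A [pipeline_config()]; its `bootstrap_count`,
#'   `edge_alpha`, `ensemble_alpha`, `null_size`, `p0` and `rng_seed`
#'   fields drive the run.
#' @return A list of class `bc3net_fit`: `network` (the final igraph),
#'   `frequency` (the [aggregate_ensemble()] table), `p0`, `B`.
#' @examples
#' study <- simulate_study(p = 25, n_samples = 80, seed = 3)
#' fit <- bc3net(study$expression,
#'               pipeline_config(bootstrap_count = 10, null_size = 2000,
#'                               rng_seed = 3))
#' igraph::ecount(fit$network)
#' @export
bc3net <- function(expr, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config")
  }
  null <- mi_null(expr, n_resample = config$null_size,
                  seed = config$rng_seed + 1000003L)
  ens <- bootstrap_ensemble(expr, B = config$bootstrap_count,
                            seed = config$rng_seed,
                            alpha = config$edge_alpha, null = null)
  freq <- aggregate_ensemble(ens)
  net <- binomial_edge_test(freq, ensemble_alpha = config$ensemble_alpha,
                            p0 = config$p0)
  p0_used <- if (is.null(config$p0) && nrow(freq) > 0) {
    sum(freq$count) / (attr(freq, "B") * nrow(freq))
  } else {
    config$p0
  }
  structure(list(network = net, frequency = freq, p0 = p0_used,
                 B = config$bootstrap_count),
            class = "bc3net_fit")
}

#' @export
print.bc3net_fit <- function(x, ...) {
  cat(sprintf("Bagged C3NET fit: %d genes, %d edges (B = %d, p0 = %s)\n",
              igraph::gorder(x$network), igraph::ecount(x$network), x$B,
              format(x$p0, digits = 4)))
  invisible(x)
}
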