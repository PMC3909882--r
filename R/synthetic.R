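#' Planted ground truth for synthetic studies
#'
#' Bundles a ground-truth network with the generative parameters the
#' simulator uses: the per-edge correlation strength, the annotation terms
#' planted as enriched modules, and chromosome pairs planted with excess
#' inter-chromosome edges.
#'
#' @param network Undirected simple igraph network with named vertices.
#' @param edge_strength Target correlation magnitude per edge, strictly in
#'   (0, 1); a scalar is recycled over edges.
#' @param module_terms Optional character vector of planted term ids.
#' @param coop_pairs Optional list of length-2 chromosome-label vectors
#'   planted as cooperating pairs.
#' @return An object of class `planted_truth`.
#' @export
planted_truth <- function(network, edge_strength = 0.8,
                          module_terms = NULL, coop_pairs = NULL) {
  assert_network(network)
  if (any(igraph::which_loop(network)) || igraph::any_multiple(network)) {
    stop("planted network must be simple (no loops or multi-edges)")
  }
  if (any(edge_strength <= 0) || any(edge_strength >= 1)) {
    stop("`edge_strength` must lie strictly inside (0, 1)")
  }
  structure(
    list(network = network,
         edge_strength = rep_len(edge_strength, igraph::ecount(network)),
         module_terms = module_terms,
         coop_pairs = coop_pairs),
    class = "planted_truth")
}

#' Generate a planted gene network
#'
#' Scale-free networks are grown by preferential attachment (heavy-tailed
#' degree sequence) and then thinned at random to the requested edge
#' count; random networks are Erdos-Renyi G(n, m).
#'
#' @param p Number of genes (>= 3).
#' @param model `"scale-free"` (default) or `"random"`.
#' @param mean_degree Target mean degree; implies `round(p * mean_degree /
#'   2)` edges.
#' @param seed Optional integer seed; identical calls reproduce the
#'   identical edge set.
#' @return An undirected simple igraph network with genes named
#'   `G001, ...`.
#' @export
generate_network <- function(p, model = c("scale-free", "random"),
                             mean_degree = 2, seed = NULL) {
  model <- match.arg(model)
  if (p < 3) stop("`p` must be >= 3")
  m_target <- round(p * mean_degree / 2)
  if (m_target > pair_count(p)) {
    stop(sprintf("mean_degree %g implies %d edges, more than p(p-1)/2 = %d",
                 mean_degree, m_target, pair_count(p)))
  }
  g <- with_seed(seed, {
    if (model == "random") {
      gg <- igraph::sample_gnm(p, m_target, directed = FALSE)
    } else {
      m_pa <- max(1L, ceiling(mean_degree / 2))
      gg <- igraph::sample_pa(p, power = 1, m = m_pa, directed = FALSE)
      gg <- igraph::simplify(gg)
      excess <- igraph::ecount(gg) - m_target
      if (excess > 0) {
        gg <- igraph::delete_edges(gg, sample(igraph::ecount(gg), excess))
      }
    }
    gg
  })
  igraph::V(g)$name <- gene_ids(p)
  igraph::simplify(g)
}

#' Simulate an expression matrix with edge-wise correlation structure
#'
#' Each planted edge carries its own shared latent factor; a gene's
#' expression is the sum of the factors of its incident edges plus
#' independent Gaussian noise, with weights chosen so that for a pair of
#' degree-one genes the population correlation along their edge equals the
#' planted `edge_strength` (hub genes dilute their per-edge correlation by
#' `1/sqrt(degree)`, mirroring how regulatory influence spreads over many
#' partners). Marginal -- not partial -- correlation therefore tracks the
#' planted edges, matching what a marginal-MI inference method can
#' recover. Values are emitted on a log2-like continuous scale (per-gene
#' baselines around 8) with no missing entries.
#'
#' @param truth A [planted_truth()] object (a bare igraph network is
#'   promoted with default strength).
#' @param n_samples Number of samples (columns, >= 3).
#' @param noise_sd Scale of the independent noise component (> 0; at the
#'   default 1 the target edge correlation equals `edge_strength`).
#' @param seed Optional integer seed.
#' @return Numeric matrix, genes x samples.
#' @export
simulate_expression <- function(truth, n_samples, noise_sd = 1,
                                seed = NULL) {
  if (igraph::is_igraph(truth)) truth <- planted_truth(truth)
  if (!inherits(truth, "planted_truth")) stop("`truth` must be a planted_truth")
  if (n_samples < 3) stop("`n_samples` must be >= 3")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  g <- truth$network
  p <- igraph::gorder(g)
  genes <- igraph::V(g)$name
  ne <- igraph::ecount(g)
  s <- truth$edge_strength
  deg <- igraph::degree(g)
  with_seed(seed, {
    x <- matrix(0, nrow = p, ncol = n_samples,
                dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    if (ne > 0) {
      el <- igraph::as_edgelist(g, names = FALSE)
      z <- matrix(rnorm(ne * n_samples), nrow = ne)
      for (e in seq_len(ne)) {
        a <- el[e, 1]
        b <- el[e, 2]
        x[a, ] <- x[a, ] + sqrt(s[e] / deg[a]) * z[e, ]
        x[b, ] <- x[b, ] + sqrt(s[e] / deg[b]) * z[e, ]
      }
    }
    # independent component scaled so total variance stays near 1 per gene
    mean_s <- rep(0, p)
    if (ne > 0) {
      el <- igraph::as_edgelist(g, names = FALSE)
      sums <- rep(0, p)
      for (e in seq_len(ne)) {
        sums[el[e, 1]] <- sums[el[e, 1]] + s[e]
        sums[el[e, 2]] <- sums[el[e, 2]] + s[e]
      }
      mean_s <- ifelse(deg > 0, sums / pmax(deg, 1), 0)
    }
    indep_sd <- noise_sd * sqrt(pmax(1 - mean_s, 0))
    indep_sd[deg == 0] <- noise_sd
    baseline <- rnorm(p, mean = 8, sd = 1)
    x <- x + indep_sd * matrix(rnorm(p * n_samples), nrow = p)
    x + baseline
  })
}

# Genes of one connected neighborhood of `size` vertices grown by BFS from
# `start` (vertex index); padded with uniform random genes if the
# component is smaller than `size`.
neighborhood_genes <- function(network, start, size) {
  ord <- igraph::bfs(network, root = start, order = TRUE,
                     unreachable = FALSE)$order
  ord <- ord[!is.na(ord)]
  picked <- igraph::V(network)$name[as.integer(ord)[seq_len(min(size, length(ord)))]]
  if (length(picked) < size) {
    rest <- setdiff(igraph::V(network)$name, picked)
    picked <- c(picked, sample(rest, size - length(picked)))
  }
  picked
}

#' Generate synthetic term-to-gene annotations
#'
#' Planted terms are drawn from connected neighborhoods of the truth
#' network, guaranteeing an excess of within-term edges; the remaining
#' terms are uniform random gene sets of the same size range, so GPEA has
#' a known positive and a calibrated null.
#'
#' @param truth A [planted_truth()] object or igraph network.
#' @param n_terms Total number of terms.
#' @param size_range Length-2 integer vector of inclusive term sizes.
#' @param n_planted How many of the terms are planted modules.
#' @param seed Optional integer seed.
#' @return A named list of gene-id vectors (GMT-compatible, see
#'   [write_gmt()]) with attributes `description` and `planted` (the
#'   planted term ids).
#' @export
generate_annotations <- function(truth, n_terms = 50, size_range = c(5, 30),
                                 n_planted = 5, seed = NULL) {
  if (igraph::is_igraph(truth)) truth <- planted_truth(truth)
  g <- truth$network
  p <- igraph::gorder(g)
  if (n_planted > n_terms) stop("`n_planted` must not exceed `n_terms`")
  if (size_range[1] < 3 || size_range[2] > p) {
    stop("`size_range` must lie within [3, p]")
  }
  genes <- igraph::V(g)$name
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                    replace = TRUE)
    terms <- vector("list", n_terms)
    ids <- sprintf("T%03d", seq_len(n_terms))
    planted_ids <- if (n_planted > 0) ids[seq_len(n_planted)] else character(0)
    deg <- igraph::degree(g)
    seeds_pool <- which(deg > 0)
    if (length(seeds_pool) == 0 && n_planted > 0) {
      stop("cannot plant modules on an empty network")
    }
    for (i in seq_len(n_terms)) {
      terms[[i]] <- if (i <= n_planted) {
        neighborhood_genes(g, sample(seeds_pool, 1), sizes[i])
      } else {
        sample(genes, sizes[i])
      }
    }
    names(terms) <- ids
    attr(terms, "description") <- stats::setNames(
      ifelse(ids %in% planted_ids, "planted module", "random gene set"), ids)
    attr(terms, "planted") <- planted_ids
    terms
  })
}

#' Generate a synthetic gene catalog
#'
#' Every gene is assigned exactly one chromosome; chromosome sizes are
#' uneven (linearly decreasing weights, mimicking the uneven gene content
#' of real chromosomes), but -- as in a real genome -- every chromosome
#' receives at least one gene whenever enough genes are available. The
#' `census` column is initialised to 0; combine
#' with [generate_census()] via `catalog$census <-
#' as.integer(catalog$gene %in% census)`.
#'
#' @param genes Character vector of gene ids.
#' @param n_chrom Number of chromosomes to use, 2..24; labels are taken in
#'   order from 1-22, X, Y.
#' @param seed Optional integer seed.
#' @return A catalog data frame (`gene`, `chromosome`, `census`).
#' @export
generate_catalog <- function(genes, n_chrom = 24, seed = NULL) {
  if (n_chrom < 2 || n_chrom > 24) stop("`n_chrom` must be in 2..24")
  labels <- CHROMOSOMES[seq_len(n_chrom)]
  with_seed(seed, {
    w <- rev(seq_len(n_chrom))
    chrom <- sample(labels, length(genes), replace = TRUE, prob = w / sum(w))
    if (length(genes) >= n_chrom) {
      # guarantee coverage: one random gene pinned to each chromosome
      chrom[sample.int(length(genes), n_chrom)] <- sample(labels)
    }
    data.frame(gene = as.character(genes), chromosome = chrom,
               census = 0L, stringsAsFactors = FALSE)
  })
}

#' Draw a synthetic census gene set
#'
#' Without a bias the census set is a uniform draw without replacement;
#' with `bias_genes` supplied, those genes receive `bias_weight`-fold
#' sampling weight, emulating a curated cancer-gene list concentrated in a
#' functional module.
#'
#' @param genes Character vector of gene ids.
#' @param n_census Number of census genes to draw (<= `length(genes)`).
#' @param bias_genes Optional character vector of genes to over-sample.
#' @param bias_weight Relative weight of biased genes (default 5).
#' @param seed Optional integer seed.
#' @return Character vector of census gene ids.
#' @export
generate_census <- function(genes, n_census, bias_genes = NULL,
                            bias_weight = 5, seed = NULL) {
  genes <- as.character(genes)
  if (n_census > length(genes)) {
    stop("`n_census` exceeds the number of genes")
  }
  with_seed(seed, {
    w <- rep(1, length(genes))
    if (!is.null(bias_genes)) {
      w[genes %in% bias_genes] <- bias_weight
    }
    sample(genes, n_census, prob = w)
  })
}

#' Plant a cooperating chromosome pair into a network
#'
#' Rewires a fraction of edges, chosen at random, to connect a random gene
#' on chromosome `pair[1]` with a random gene on chromosome `pair[2]`,
#' giving the chromosome-cooperation permutation test a known positive
#' while leaving the edge count unchanged.
#'
#' @param network Undirected igraph network with named vertices.
#' @param catalog Gene catalog covering the network's genes.
#' @param pair Length-2 vector of chromosome labels.
#' @param fraction Fraction of edges to rewire (default 0.2).
#' @param seed Optional integer seed.
#' @return The rewired network (simple, same edge count up to collisions).
#' @export
plant_cooperation <- function(network, catalog, pair, fraction = 0.2,
                              seed = NULL) {
  assert_network(network)
  if (length(pair) != 2 || !all(pair %in% CHROMOSOMES)) {
    stop("`pair` must be two chromosome labels from 1-22, X, Y")
  }
  chrom <- stats::setNames(catalog$chromosome, catalog$gene)
  genes <- igraph::V(network)$name
  if (any(!genes %in% names(chrom))) {
    stop("catalog does not cover all network genes")
  }
  g1 <- genes[chrom[genes] == pair[1]]
  g2 <- genes[chrom[genes] == pair[2]]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("no genes on one of the requested chromosomes")
  }
  ne <- igraph::ecount(network)
  n_rewire <- round(fraction * ne)
  if (n_rewire == 0) return(network)
  with_seed(seed, {
    drop <- sample(ne, n_rewire)
    g <- igraph::delete_edges(network, drop)
    a <- sample(g1, n_rewire, replace = TRUE)
    b <- sample(g2, n_rewire, replace = TRUE)
    keep <- a != b
    g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
    igraph::simplify(g)
  })
}

#' Simulate a complete synthetic study
#'
#' One call produces every artifact the downstream pipeline consumes: a
#' planted network, an expression matrix with edge-wise correlation, term
#' annotations with planted modules, a chromosome catalog (optionally with
#' a planted cooperating pair) and a census gene list biased toward the
#' first planted module. The defaults are the package's reference study
#' conditions: 100 genes at mean degree 1.5, edge strength 0.8 and 300
#' samples.
#'
#' @param p,mean_degree,model Arguments of [generate_network()].
#' @param edge_strength Planted per-edge correlation magnitude.
#' @param n_samples,noise_sd Arguments of [simulate_expression()].
#' @param n_terms,size_range,n_planted Arguments of
#'   [generate_annotations()].
#' @param n_chrom Chromosome count for [generate_catalog()].
#' @param n_census Census list size for [generate_census()].
#' @param coop_pair Optional chromosome pair for [plant_cooperation()].
#' @param coop_fraction Fraction of edges rewired toward `coop_pair`.
#' @param seed Integer seed driving all stages.
#' @return A list with elements `truth` ([planted_truth()]), `expression`,
#'   `annotations`, `catalog`, `census`.
#' @examples
#' study <- simulate_study(p = 30, n_samples = 50, seed = 1)
#' dim(study$expression)
#' @export
simulate_study <- function(p = 100, mean_degree = 1.5,
                           model = "scale-free", edge_strength = 0.8,
                           n_samples = 300, noise_sd = 1,
                           n_terms = 50, size_range = c(5, 20),
                           n_planted = 5, n_chrom = 24,
                           n_census = 20, coop_pair = NULL,
                           coop_fraction = 0.2, seed = 1) {
  net <- generate_network(p, model = model, mean_degree = mean_degree,
                          seed = seed)
  catalog <- generate_catalog(igraph::V(net)$name, n_chrom = n_chrom,
                              seed = seed + 1L)
  if (!is.null(coop_pair)) {
    net <- plant_cooperation(net, catalog, coop_pair,
                             fraction = coop_fraction, seed = seed + 2L)
  }
  truth <- planted_truth(net, edge_strength = edge_strength,
                         coop_pairs = if (is.null(coop_pair)) NULL else list(coop_pair))
  expr <- simulate_expression(truth, n_samples = n_samples,
                              noise_sd = noise_sd, seed = seed + 3L)
  ann <- generate_annotations(truth, n_terms = n_terms,
                              size_range = size_range,
                              n_planted = n_planted, seed = seed + 4L)
  truth$module_terms <- attr(ann, "planted")
  census <- generate_census(igraph::V(net)$name, n_census = n_census,
                            bias_genes = if (length(attr(ann, "planted")) > 0)
                              ann[[attr(ann, "planted")[1]]] else NULL,
                            seed = seed + 5L)
  catalog$census <- as.integer(catalog$gene %in% census)
  list(truth = truth, expression = expr, annotations = ann,
       catalog = catalog, census = census)
}
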