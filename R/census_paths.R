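#' First-degree-neighbor subnetwork of a set of seed genes
#'
#' The induced subgraph on the seed genes together with all of their
#' direct neighbors.
#'
#' @param network Undirected igraph network with named vertices.
#' @param seeds Character vector of seed gene ids (must be present in the
#'   network).
#' @return An igraph network.
#' @export
first_degree_subnetwork <- function(network, seeds) {
  assert_network(network)
  missing <- setdiff(seeds, igraph::V(network)$name)
  if (length(missing) > 0) {
    stop("seed gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  nb <- unique(unlist(lapply(
    igraph::ego(network, order = 1, nodes = seeds),
    function(v) v$name)))
  igraph::induced_subgraph(network, union(seeds, nb))
}

#' Pairwise shortest-path table for a set of genes
#'
#' Unit-weight shortest-path lengths between all unordered pairs of the
#' given genes; pairs in different components are reported as `Inf`.
#'
#' @param network Undirected igraph network with named vertices.
#' @param genes Character vector of gene ids present in the network.
#' @return Data frame with columns `gene1`, `gene2`, `distance`.
#' @export
pairwise_path_table <- function(network, genes) {
  assert_network(network)
  missing <- setdiff(genes, igraph::V(network)$name)
  if (length(missing) > 0) {
    stop("gene(s) not in network: ", paste(missing, collapse = ", "))
  }
  d <- igraph::distances(network, v = genes, to = genes)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                    distance = d[idx], stringsAsFactors = FALSE)
  out[order(out$distance, out$gene1, out$gene2), , drop = FALSE]
}

#' Distribution of all pairwise shortest-path distances
#'
#' The multiset of unit-weight shortest-path lengths over all unordered
#' vertex pairs of the network -- the null distribution of the empirical
#' closeness test. For disconnected networks, compute it on the giant
#' component first.
#'
#' @param network Undirected igraph network.
#' @return Numeric vector of length `n(n-1)/2` (may contain `Inf` when
#'   the network is disconnected).
#' @export
pair_distance_distribution <- function(network) {
  assert_network(network)
  d <- igraph::distances(network)
  d[upper.tri(d)]
}

#' Empirical closeness test for census gene pairs
#'
#' Tests whether pairs of census genes sit closer in the network than
#' typical gene pairs. The null distribution is the multiset of
#' shortest-path distances over *all* unordered gene pairs of the giant
#' component (census pairs included); a census pair at distance `d` gets
#' the empirical p-value `#\{null < d\} / #null` (strict inequality, as
#' the literal definition; `smooth = TRUE` switches to the
#' `(x + 1)/(n + 1)` pseudo-count form, which is stochastically valid for
#' downstream FDR use). Benjamini-Hochberg correction is applied over all
#' census pairs. Census genes outside the giant component are excluded
#' from testing and reported in the `excluded` attribute.
#'
#' @param network Undirected igraph network with named vertices.
#' @param census Character vector of >= 2 census gene ids.
#' @param alpha Significance level for the BH flag (default 0.05).
#' @param smooth Use pseudo-count p-values (default `FALSE`).
#' @return Data frame with columns `gene1`, `gene2`, `distance`,
#'   `p_value`, `p_adjusted`, `significant`, sorted by p-value;
#'   attributes `excluded` (genes outside the GCC) and `null_size`.
#' @export
closeness_test <- function(network, census, alpha = 0.05, smooth = FALSE) {
  assert_network(network)
  census <- unique(census)
  if (length(census) < 2) stop("need >= 2 census genes")
  gcc <- giant_component(network)
  in_gcc <- intersect(census, igraph::V(gcc)$name)
  excluded <- setdiff(census, in_gcc)
  if (length(in_gcc) < 2) stop("fewer than 2 census genes in the giant component")
  null_d <- pair_distance_distribution(gcc)
  n_null <- length(null_d)
  # distances are small integers: use cumulative counts for O(1) lookup
  tab <- tabulate(as.integer(null_d) + 1L)     # counts of distance 0,1,2,...
  below <- cumsum(c(0, tab))                   # below[d+1] = #{null < d}
  d <- igraph::distances(gcc, v = in_gcc, to = in_gcc)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  dist_pair <- d[idx]
  n_below <- below[pmin(dist_pair, length(below) - 1L) + 1L]
  pv <- if (smooth) (n_below + 1) / (n_null + 1) else n_below / n_null
  out <- data.frame(gene1 = in_gcc[idx[, 1]], gene2 = in_gcc[idx[, 2]],
                    distance = dist_pair, p_value = pv,
                    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_value, out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "null_size") <- n_null
  out
}

#' Components of directly connected census genes
#'
#' Connected-component sizes of the subgraph induced on the census genes:
#' clusters of census genes that are directly wired to each other.
#'
#' @param network Undirected igraph network with named vertices.
#' @param census Character vector of census gene ids.
#' @return Integer vector of component sizes, decreasing.
#' @export
census_components <- function(network, census) {
  assert_network(network)
  present <- intersect(unique(census), igraph::V(network)$name)
  if (length(present) == 0) return(integer(0))
  comp <- igraph::components(igraph::induced_subgraph(network, present))
  sort(as.integer(comp$csize), decreasing = TRUE)
}

#' All-census-pair shortest-path union network
#'
#' The union of every vertex and edge lying on at least one shortest path
#' between some pair of census genes (all shortest paths per pair, so the
#' degree ranking is well defined and not an artifact of arbitrary path
#' tie-breaking). Nodes are ranked by their degree in the union network.
#'
#' @param network Undirected igraph network with named vertices.
#' @param census Character vector of census gene ids.
#' @return A list of class `census_path_union`: `network` (the union
#'   igraph, whose vertex set always includes the census genes present in
#'   the input network) and `ranking` (data frame `gene`, `degree`,
#'   `census`, sorted by degree descending, ties by gene id).
#' @export
census_path_union <- function(network, census) {
  assert_network(network)
  cens <- intersect(unique(census), igraph::V(network)$name)
  edges <- character(0)
  if (length(cens) >= 2) {
    for (i in seq_len(length(cens) - 1)) {
      targets <- cens[(i + 1):length(cens)]
      asp <- suppressWarnings(
        igraph::all_shortest_paths(network, from = cens[i], to = targets,
                                   mode = "all"))
      for (path in asp$vpaths) {
        nm <- path$name
        if (length(nm) >= 2) {
          edges <- c(edges,
                     edge_keys(nm[-length(nm)], nm[-1]))
        }
      }
      edges <- unique(edges)
    }
  }
  if (length(edges) > 0) {
    parts <- do.call(rbind, strsplit(edges, "|", fixed = TRUE))
    verts <- union(cens, unique(as.vector(parts)))
    gu <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
    igraph::V(gu)$name <- verts
    gu <- igraph::add_edges(gu, rbind(parts[, 1], parts[, 2]))
    gu <- igraph::simplify(gu)
  } else {
    gu <- igraph::make_empty_graph(n = length(cens), directed = FALSE)
    igraph::V(gu)$name <- cens
  }
  deg <- igraph::degree(gu)
  ranking <- data.frame(gene = names(deg), degree = as.integer(deg),
                        census = names(deg) %in% cens,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$degree, ranking$gene), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(network = gu, ranking = ranking),
            class = "census_path_union")
}
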