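#' Hypergeometric p-value for gene-pair (edge) enrichment
#'
#' Of the `N = p(p-1)/2` gene pairs a network over `p` genes could
#' connect, `m_go` lie within a given annotation term (`m_go =
#' p_go(p_go-1)/2` for a term of `p_go` genes). If the network has `n`
#' edges of which `k` fall within the term, the enrichment p-value is the
#' upper-tail hypergeometric probability of observing `k` or more
#' within-term edges when the `n` edges are drawn at random from the `N`
#' pairs.
#'
#' @param N Total pair capacity of the network's gene universe.
#' @param m_go Pair capacity of the term.
#' @param n Number of network edges.
#' @param k Observed within-term edges.
#' @return The upper-tail probability `P(X >= k)`.
#' @examples
#' gpea_pvalue(N = 10, m_go = 3, n = 3, k = 3) # 1/120
#' @export
gpea_pvalue <- function(N, m_go, n, k) {
  if (m_go < 0 || m_go > N || n < 0 || n > N) {
    stop("need 0 <= m_go <= N and 0 <= n <= N")
  }
  if (k < 0 || k > min(m_go, n)) {
    stop("need 0 <= k <= min(m_go, n)")
  }
  phyper(k - 1, m = m_go, n = N - m_go, k = n, lower.tail = FALSE)
}

#' Gene-level hypergeometric enrichment of a census set in a term
#'
#' Upper-tail hypergeometric test for the number of census genes found in
#' an annotation term, drawing `|term|` genes from a universe containing
#' `|census|` census genes.
#'
#' @param term_genes Character vector of the term's genes (within the
#'   universe).
#' @param census Character vector of census gene ids (subset of the
#'   universe).
#' @param universe Character vector: the gene universe.
#' @return The upper-tail probability of the observed census count.
#' @export
census_term_enrichment <- function(term_genes, census, universe) {
  if (length(universe) == 0) stop("empty universe")
  term_genes <- intersect(term_genes, universe)
  census <- intersect(census, universe)
  q <- length(intersect(term_genes, census))
  phyper(q - 1, m = length(census),
         n = length(universe) - length(census),
         k = length(term_genes), lower.tail = FALSE)
}

#' Gene-pair enrichment analysis (GPEA) of a network
#'
#' Tests every annotation term for an excess of network edges among its
#' genes. Terms are first intersected with the network's gene set (genes
#' absent from the network cannot form edges) and filtered to the
#' inclusive size window \[`size_min`, `size_max`\]; each surviving term
#' is scored with [gpea_pvalue()] using the network's gene count for `N`
#' and edge count for `n`, and a Bonferroni correction over the tested
#' terms is applied. When a census gene set is supplied, each term is
#' additionally scored for gene-level census enrichment.
#'
#' @param network Undirected igraph network with named vertices.
#' @param annotations Named list of gene-id vectors (see [read_gmt()]).
#' @param size_min,size_max Inclusive term-size bounds after intersection
#'   (defaults 3 and 999).
#' @param alpha Significance level for the Bonferroni-adjusted flag
#'   (default 0.05).
#' @param census Optional character vector of census gene ids.
#' @return A data frame sorted by p-value (ties by term id) with columns
#'   `term`, `description`, `size`, `pairs`, `edges`, `p_value`,
#'   `p_adjusted`, `significant`, and -- when `census` is given --
#'   `census_count`, `census_p`.
#' @export
run_gpea <- function(network, annotations, size_min = 3, size_max = 999,
                     alpha = 0.05, census = NULL) {
  assert_network(network)
  genes <- igraph::V(network)$name
  p <- length(genes)
  N <- pair_count(p)
  n <- igraph::ecount(network)
  desc <- attr(annotations, "description")
  trimmed <- lapply(annotations, intersect, y = genes)
  sizes <- lengths(trimmed)
  keep <- sizes >= size_min & sizes <= size_max
  if (!any(keep)) stop("no annotation term within the size window")
  trimmed <- trimmed[keep]
  sizes <- sizes[keep]
  k <- vapply(trimmed, function(tg) {
    igraph::ecount(igraph::induced_subgraph(network, tg))
  }, numeric(1))
  m_go <- pair_count(sizes)
  pv <- vapply(seq_along(trimmed), function(i) {
    gpea_pvalue(N, m_go[i], n, k[i])
  }, numeric(1))
  nt <- length(trimmed)
  out <- data.frame(
    term = names(trimmed),
    description = if (is.null(desc)) names(trimmed) else
      unname(desc[names(trimmed)]),
    size = as.integer(sizes),
    pairs = m_go,
    edges = as.integer(k),
    p_value = pv,
    p_adjusted = pmin(1, pv * nt),
    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted <= alpha
  if (!is.null(census)) {
    census <- intersect(census, genes)
    out$census_count <- vapply(trimmed, function(tg) {
      length(intersect(tg, census))
    }, integer(1))
    out$census_p <- vapply(trimmed, census_term_enrichment,
                           numeric(1), census = census, universe = genes)
  }
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
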