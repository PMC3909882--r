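# Chromosome vector for the network's genes, validated against the
# catalog; errors name any uncovered gene.
network_chromosomes <- function(network, catalog) {
  assert_network(network)
  validate_catalog(catalog)
  genes <- igraph::V(network)$name
  chrom <- stats::setNames(catalog$chromosome, catalog$gene)[genes]
  if (any(is.na(chrom))) {
    stop("gene(s) missing from catalog: ",
         paste(genes[is.na(chrom)], collapse = ", "))
  }
  unname(chrom)
}

#' Fraction of intra-chromosome (cis) interactions
#'
#' The fraction of network edges whose two endpoint genes lie on the same
#' chromosome; the complement is the inter-chromosome (trans) fraction.
#'
#' @param network Undirected igraph network with named vertices.
#' @param catalog Gene catalog covering all network genes.
#' @return A number in \[0, 1\].
#' @export
intra_fraction <- function(network, catalog) {
  chrom <- network_chromosomes(network, catalog)
  if (igraph::ecount(network) == 0) stop("network has no edges")
  el <- igraph::as_edgelist(network, names = FALSE)
  mean(chrom[el[, 1]] == chrom[el[, 2]])
}

# (i, j) -> single canonical index over the 24x24 unordered grid.
chrom_pair_key <- function(ci, cj) {
  i <- pmin(ci, cj)
  j <- pmax(ci, cj)
  (i - 1L) * 24L + j
}

#' Chromosome-pair interaction counts
#'
#' The symmetric 24 x 24 table of edge counts between (and within)
#' chromosomes: entry (i, j) is the number of network edges joining a
#' gene on chromosome i to a gene on chromosome j; the diagonal holds
#' within-chromosome counts. Each edge is counted exactly once, so the
#' diagonal plus the upper triangle sums to the edge count.
#'
#' @param network Undirected igraph network with named vertices.
#' @param catalog Gene catalog covering all network genes.
#' @return A 24 x 24 symmetric integer matrix with chromosome dimnames.
#' @export
chrom_pair_counts <- function(network, catalog) {
  chrom <- network_chromosomes(network, catalog)
  ci <- match(chrom, CHROMOSOMES)
  m <- matrix(0L, 24, 24, dimnames = list(CHROMOSOMES, CHROMOSOMES))
  if (igraph::ecount(network) > 0) {
    el <- igraph::as_edgelist(network, names = FALSE)
    counts <- tabulate(chrom_pair_key(ci[el[, 1]], ci[el[, 2]]),
                       nbins = 576L)
    for (i in 1:24) {
      for (j in i:24) {
        m[i, j] <- m[j, i] <- counts[(i - 1L) * 24L + j]
      }
    }
  }
  m
}

# p-value from the count of replicates at or above the observation,
# optionally with a (x + 1) / (E + 1) pseudo-count.
perm_pvalue <- function(exceed, E, smooth = FALSE) {
  if (smooth) (exceed + 1) / (E + 1) else exceed / E
}

#' Permutation test for chromosome-pair interaction enrichment
#'
#' Tests, for each of the 300 unordered chromosome pairs (the 276
#' off-diagonal pairs plus the 24 self-pairs), whether the observed
#' interaction count `s_ij` exceeds what random gene placement would
#' give. Each of the `E` replicates permutes the gene-to-chromosome
#' assignment uniformly over the network's genes while the graph itself
#' is untouched -- conserving the total interaction count, the degree
#' structure, and the uneven chromosome sizes -- and recounts every pair,
#' so each pair is judged against its own sampling distribution. The
#' p-value is the right-tail replicate fraction
#' `sum(s_e >= s_obs) / E` (so 0 is attainable when the observation
#' strictly exceeds every replicate; `smooth = TRUE` uses the
#' `(x + 1)/(E + 1)` pseudo-count form), followed by Benjamini-Hochberg
#' correction over all 300 pairs.
#'
#' Replicates tying the observed count are counted into the tail, as an
#' empirical p-value requires: with the tie excluded, any pair whose
#' observed count equals its maximum attainable value (for instance two
#' single-gene chromosomes joined by their only possible edge, or an
#' unpopulated chromosome stuck at zero) would receive p = 0 under the
#' null and the test would not be calibrated.
#'
#' @param network Undirected igraph network with named vertices.
#' @param catalog Gene catalog covering all network genes.
#' @param E Number of permutation replicates (>= 1; default 10000).
#' @param seed Optional integer seed.
#' @param alpha Significance level for the BH flag (default 0.05).
#' @param smooth Use pseudo-count p-values (default `FALSE`).
#' @return Data frame of 300 rows: `chrom_i`, `chrom_j`, `s`, `exceed`,
#'   `p_value`, `p_adjusted`, `significant`, ordered by chromosome pair.
#' @export
chrom_permutation_test <- function(network, catalog, E = 10000,
                                   seed = NULL, alpha = 0.05,
                                   smooth = FALSE) {
  if (E < 1) stop("`E` must be >= 1")
  chrom <- network_chromosomes(network, catalog)
  ci <- match(chrom, CHROMOSOMES)
  p <- length(ci)
  el <- igraph::as_edgelist(network, names = FALSE)
  if (nrow(el) == 0) stop("network has no edges")
  a <- el[, 1]
  b <- el[, 2]
  s_obs <- tabulate(chrom_pair_key(ci[a], ci[b]), nbins = 576L)
  exceed <- integer(576L)
  with_seed(seed, {
    for (e in seq_len(E)) {
      cp <- ci[sample.int(p)]
      s_e <- tabulate(chrom_pair_key(cp[a], cp[b]), nbins = 576L)
      exceed <- exceed + (s_e >= s_obs)
    }
  })
  ii <- rep(1:24, times = 24:1)
  jj <- unlist(lapply(1:24, function(i) i:24))
  key <- (ii - 1L) * 24L + jj
  pv <- perm_pvalue(exceed[key], E, smooth = smooth)
  out <- data.frame(
    chrom_i = CHROMOSOMES[ii], chrom_j = CHROMOSOMES[jj],
    s = s_obs[key], exceed = exceed[key],
    p_value = pv,
    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
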