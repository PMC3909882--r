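# Independent oracles and small graph builders shared across tests.
# The oracles deliberately avoid the code paths they check: tail
# probabilities by direct summation of binomial coefficients, distances
# by a hand-rolled breadth-first search on adjacency lists.

# Build a named undirected graph from "A-B" edge strings.
g_from_edges <- function(edges, isolated = character(0)) {
  parts <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
  verts <- union(unique(as.vector(parts)), isolated)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  igraph::add_edges(g, rbind(parts[, 1], parts[, 2]))
}

# Path graph over the given vertex names.
g_path <- function(names) {
  g_from_edges(paste(names[-length(names)], names[-1], sep = "-"))
}

# Upper-tail hypergeometric P(X >= k) by direct enumeration of the mass.
bf_hyper_tail <- function(N, m, n, k) {
  hi <- min(m, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# Upper-tail binomial P(X >= k) by direct summation.
bf_binom_tail <- function(k, B, p0) {
  if (k > B) return(0)
  i <- k:B
  sum(choose(B, i) * p0^i * (1 - p0)^(B - i))
}

# All-pairs shortest-path distances of a named graph via hand-rolled BFS.
bf_all_pair_distances <- function(g) {
  verts <- igraph::V(g)$name
  n <- length(verts)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs_from <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (!is.finite(d[w])) {
          d[w] <- d[v] + 1
          q <- c(q, w)
        }
      }
    }
    d
  }
  dmat <- t(vapply(seq_len(n), bfs_from, numeric(n)))
  dmat[upper.tri(dmat)]
}

# Numerical mutual information of a bivariate Gaussian with correlation
# rho: MI = E[log f(X,Y) - log fx(X) - log fy(Y)], evaluated by tensor
# Gauss-Hermite quadrature in independent coordinates (X = Z1,
# Y = rho Z1 + sqrt(1 - rho^2) Z2 with Z1, Z2 iid standard normal).
bf_gaussian_mi_numeric <- function(rho, n_nodes = 60) {
  if (rho == 0) return(0)
  gh <- pracma::gaussHermite(n_nodes)
  z1 <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  g <- outer(z1, z1, function(a, b) {
    x <- a
    y <- rho * a + sqrt(1 - rho^2) * b
    q <- (x^2 - 2 * rho * x * y + y^2) / (1 - rho^2)
    logf <- -q / 2 - log(2 * pi * sqrt(1 - rho^2))
    logf - dnorm(x, log = TRUE) - dnorm(y, log = TRUE)
  })
  as.numeric(t(w) %*% g %*% w)
}
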