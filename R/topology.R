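#' Giant connected component of a network
#'
#' Returns the induced subgraph on the largest connected vertex set; if
#' several components tie for the largest size, the one containing the
#' lexicographically smallest gene id wins.
#'
#' @param network Undirected igraph network with named vertices.
#' @return An igraph network (induced subgraph).
#' @export
giant_component <- function(network) {
  assert_network(network)
  if (igraph::gorder(network) == 0) stop("network is empty")
  comp <- igraph::components(network)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(ci) {
      min(igraph::V(network)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(firsts)][1]
  }
  igraph::induced_subgraph(network,
                           which(comp$membership == cand[1]))
}

#' Edge density of a simple graph
#'
#' The fraction of realizable gene pairs that carry an edge,
#' \eqn{|E| / (n(n-1)/2)}.
#'
#' @param network Undirected igraph network with >= 2 vertices.
#' @return A number in \[0, 1\].
#' @export
edge_density <- function(network) {
  assert_network(network)
  n <- igraph::gorder(network)
  if (n < 2) stop("need >= 2 vertices")
  igraph::ecount(network) / pair_count(n)
}

#' Average shortest-path length over the giant component
#'
#' Mean unit-weight shortest-path (breadth-first / Dijkstra) distance over
#' all unordered vertex pairs of the network's giant connected component;
#' disconnected pairs are excluded by construction.
#'
#' @param network Undirected igraph network.
#' @return A number >= 1 (equal to 1 only for complete graphs).
#' @export
average_shortest_path <- function(network) {
  gcc <- giant_component(network)
  if (igraph::gorder(gcc) < 2) stop("giant component has < 2 vertices")
  igraph::mean_distance(gcc, directed = FALSE, unconnected = FALSE)
}

# Hurwitz zeta sum(k^-alpha, k = xmin..Inf): direct summation plus an
# integral tail correction beyond K.
hurwitz_zeta <- function(alpha, xmin, K = 20000L) {
  k <- xmin:K
  sum(k^(-alpha)) + (K + 0.5)^(1 - alpha) / (alpha - 1)
}

#' Discrete maximum-likelihood power-law fit of a degree sequence
#'
#' Fits the exponent of \eqn{P(k) \propto k^{-\alpha}} on degrees
#' `>= xmin`. The default `"exact"` method maximizes the discrete (zeta)
#' log-likelihood
#' \eqn{\ell(\alpha) = -n\,\ln \zeta(\alpha, x_{min}) - \alpha \sum_i \ln k_i}
#' numerically, with the standard error taken from the observed Fisher
#' information; this is the estimator of standard power-law fitting
#' practice and is reliable down to `xmin = 1`. The `"approximate"`
#' method is the continuity-corrected closed form
#' \eqn{\hat\alpha = 1 + n / \sum_i \ln(k_i / (x_{min} - 1/2))} with
#' \eqn{SE = (\hat\alpha - 1)/\sqrt{n}}; it agrees with the exact MLE
#' for moderately large `xmin` but is badly biased near `xmin = 1` and is
#' provided for comparison only. Optionally scans `xmin` by minimizing
#' the Kolmogorov-Smirnov distance between the data tail and the fitted
#' model.
#'
#' @param degrees Integer vector of vertex degrees.
#' @param xmin Minimal degree included in the fit (default 1).
#' @param method `"exact"` (default) or `"approximate"`, see above.
#' @param scan_xmin If `TRUE`, candidate `xmin` values (unique degrees
#'   leaving >= 50 tail points) are scanned and the KS-optimal one is
#'   returned.
#' @return An object of class `power_law_fit`: list with `alpha`, `xmin`,
#'   `n_tail`, `se`, and `ks` when scanned.
#' @export
fit_power_law <- function(degrees, xmin = 1,
                          method = c("exact", "approximate"),
                          scan_xmin = FALSE) {
  method <- match.arg(method)
  degrees <- degrees[is.finite(degrees)]
  if (xmin < 1) stop("`xmin` must be >= 1")
  if (scan_xmin) {
    cands <- sort(unique(degrees[degrees >= 1]))
    cands <- cands[vapply(cands, function(x) sum(degrees >= x) >= 50,
                          logical(1))]
    if (length(cands) == 0) cands <- xmin
    fits <- lapply(cands, function(x) {
      f <- try(fit_power_law(degrees, xmin = x, method = method,
                             scan_xmin = FALSE), silent = TRUE)
      if (inherits(f, "try-error")) NULL else f
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits) == 0) stop("no admissible xmin candidate")
    ks <- vapply(fits, function(f) powerlaw_ks(degrees, f), numeric(1))
    best <- fits[[which.min(ks)]]
    best$ks <- min(ks)
    return(best)
  }
  tail_deg <- degrees[degrees >= xmin]
  n <- length(tail_deg)
  if (n < 2) stop("need >= 2 degrees >= xmin")
  if (length(unique(tail_deg)) == 1) {
    stop("all tail degrees are equal; the MLE is undefined")
  }
  if (method == "approximate") {
    alpha <- 1 + n / sum(log(tail_deg / (xmin - 0.5)))
    se <- (alpha - 1) / sqrt(n)
  } else {
    slk <- sum(log(tail_deg))
    nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slk
    alpha <- stats::optimize(nll, c(1.000001, 25))$minimum
    h <- 1e-4 # observed information by central difference
    d2 <- (nll(alpha + h) - 2 * nll(alpha) + nll(alpha - h)) / h^2
    se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else
      (alpha - 1) / sqrt(n)
  }
  structure(list(alpha = alpha, xmin = xmin, n_tail = n, se = se),
            class = "power_law_fit")
}

# KS distance between the empirical tail CDF and the fitted discrete
# power law (normalized by direct summation over the support).
powerlaw_ks <- function(degrees, fit) {
  tail_deg <- sort(degrees[degrees >= fit$xmin])
  kmax <- max(tail_deg)
  support <- fit$xmin:max(kmax, fit$xmin + 1)
  pk <- support^(-fit$alpha)
  pk <- pk / sum(pk)
  model_cdf <- cumsum(pk)
  emp_cdf <- vapply(support, function(k) mean(tail_deg <= k), numeric(1))
  max(abs(emp_cdf - model_cdf))
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: alpha = %.3f (SE %.3f), xmin = %d, n_tail = %d\n",
              x$alpha, x$se, as.integer(x$xmin), x$n_tail))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Draws from \eqn{P(k) \propto k^{-\alpha}} on the support
#' `xmin..kmax` by inverse-transform sampling (the mass beyond a large
#' `kmax` is negligible for the exponents of interest).
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Smallest value (default 1).
#' @param kmax Support cutoff (default 1e6).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1, kmax = 1e6, seed = NULL) {
  if (alpha <= 1) stop("`alpha` must be > 1")
  support <- xmin:kmax
  w <- support^(-alpha)
  cdf <- cumsum(w) / sum(w)
  with_seed(seed, {
    u <- runif(n)
    support[findInterval(u, cdf, left.open = TRUE) + 1L]
  })
}

#' One-row topology summary of a network
#'
#' @param network Undirected igraph network.
#' @param xmin,scan_xmin Passed to [fit_power_law()]; the fit is skipped
#'   (NA) when the degree sequence is degenerate.
#' @return A one-row data frame: `n`, `edges`, `gcc_size`, `density`,
#'   `avg_path`, `alpha`, `alpha_se`, `xmin`, `n_tail`.
#' @export
network_summary <- function(network, xmin = 1, scan_xmin = FALSE) {
  assert_network(network)
  gcc <- giant_component(network)
  fit <- try(fit_power_law(igraph::degree(network), xmin = xmin,
                           scan_xmin = scan_xmin), silent = TRUE)
  bad <- inherits(fit, "try-error")
  data.frame(
    n = as.integer(igraph::gorder(network)),
    edges = as.integer(igraph::ecount(network)),
    gcc_size = as.integer(igraph::gorder(gcc)),
    density = edge_density(network),
    avg_path = if (igraph::gorder(gcc) >= 2)
      average_shortest_path(network) else NA_real_,
    alpha = if (bad) NA_real_ else fit$alpha,
    alpha_se = if (bad) NA_real_ else fit$se,
    xmin = if (bad) NA_integer_ else as.integer(fit$xmin),
    n_tail = if (bad) NA_integer_ else fit$n_tail)
}
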