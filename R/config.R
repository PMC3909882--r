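#' Pipeline configuration
#'
#' Bundles the tunable parameters of the inference and testing pipeline so
#' a whole run is reproducible from one object. All stochastic stages draw
#' their seeds from `rng_seed`; a run with a fixed configuration is
#' bit-reproducible.
#'
#' @param bootstrap_count Number of bootstrap resamples `B` used by the
#'   ensemble (default 100).
#' @param edge_alpha Per-member significance level for the mutual-information
#'   test inside each bootstrap network (default 0.05; Bonferroni-corrected
#'   over the gene count).
#' @param ensemble_alpha Significance level of the binomial aggregation test
#'   that turns edge frequencies into the final network (default 0.05).
#' @param gpea_alpha Level for the Bonferroni-corrected gene-pair enrichment
#'   analysis (default 0.05).
#' @param perm_E Number of gene-label permutations for the chromosome
#'   cooperation test (default 100000).
#' @param rng_seed Integer seed for all randomness.
#' @param term_size_min,term_size_max Inclusive annotation-term size window
#'   used by GPEA (defaults 3 and 999).
#' @param null_size Size of the pooled permutation null used to assign
#'   empirical p-values to mutual-information estimates (default 100000).
#' @param p0 Optional fixed success probability for the binomial edge test;
#'   `NULL` (default) estimates it from the ensemble's mean edge frequency.
#' @param smooth_p Logical; if `TRUE`, empirical permutation p-values use
#'   the (x + 1) / (E + 1) pseudo-count form instead of the literal strict
#'   fraction (default `FALSE`).
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config(bootstrap_count = 20, rng_seed = 7)
#' cfg$bootstrap_count
#' @export
pipeline_config <- function(bootstrap_count = 100L,
                            edge_alpha = 0.05,
                            ensemble_alpha = 0.05,
                            gpea_alpha = 0.05,
                            perm_E = 100000L,
                            rng_seed = 1L,
                            term_size_min = 3L,
                            term_size_max = 999L,
                            null_size = 100000L,
                            p0 = NULL,
                            smooth_p = FALSE) {
  cfg <- list(
    bootstrap_count = as.integer(bootstrap_count),
    edge_alpha = edge_alpha,
    ensemble_alpha = ensemble_alpha,
    gpea_alpha = gpea_alpha,
    perm_E = as.integer(perm_E),
    rng_seed = as.integer(rng_seed),
    term_size_min = as.integer(term_size_min),
    term_size_max = as.integer(term_size_max),
    null_size = as.integer(null_size),
    p0 = p0,
    smooth_p = isTRUE(smooth_p)
  )
  for (nm in c("edge_alpha", "ensemble_alpha", "gpea_alpha")) {
    a <- cfg[[nm]]
    if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
      stop(sprintf("`%s` must be a single number in (0, 1)", nm))
    }
  }
  if (cfg$bootstrap_count < 1) stop("`bootstrap_count` must be >= 1")
  if (cfg$perm_E < 1) stop("`perm_E` must be >= 1")
  if (cfg$null_size < 100) stop("`null_size` must be >= 100")
  if (cfg$term_size_min > cfg$term_size_max) {
    stop("`term_size_min` must not exceed `term_size_max`")
  }
  if (!is.null(cfg$p0) &&
      (!is.numeric(cfg$p0) || cfg$p0 <= 0 || cfg$p0 >= 1)) {
    stop("`p0` must be NULL or a number in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  bootstraps B       : %d\n", x$bootstrap_count))
  cat(sprintf("  edge alpha         : %g\n", x$edge_alpha))
  cat(sprintf("  ensemble alpha     : %g\n", x$ensemble_alpha))
  cat(sprintf("  GPEA alpha         : %g\n", x$gpea_alpha))
  cat(sprintf("  permutations E     : %d\n", x$perm_E))
  cat(sprintf("  MI null pool size  : %d\n", x$null_size))
  cat(sprintf("  term size window   : [%d, %d]\n",
              x$term_size_min, x$term_size_max))
  cat(sprintf("  seed               : %d\n", x$rng_seed))
  invisible(x)
}
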