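#' Quantile-normalize a probe or gene expression matrix
#'
#' Forces every column (sample) onto the identical empirical
#' distribution: the vector of row means of the column-sorted matrix.
#' Tied values within a column receive the reference value interpolated
#' at their average rank, so equal inputs map to equal outputs. Row and
#' column identifiers are preserved and the operation is idempotent on
#' tie-free data.
#'
#' @param m Numeric matrix (rows = probes or genes, columns = samples)
#'   with no missing values.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (ncol(m) < 1) stop("`m` needs at least one column")
  if (any(is.na(m))) stop("`m` contains missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probe-level rows to gene-level medians
#'
#' Multiple probes can measure the same gene; per sample, a gene's value
#' is the median over its probes. Probes with no mapping are excluded.
#'
#' @param m Numeric probe x sample matrix with probe rownames.
#' @param probe_to_gene Mapping from probe id to gene id: either a named
#'   character vector (names = probes) or a two-column data frame
#'   (`probe`, `gene`).
#' @return Numeric gene x sample matrix, genes sorted by id.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  if (!is.matrix(m) || is.null(rownames(m))) {
    stop("`m` must be a matrix with probe rownames")
  }
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2]]),
                           as.character(probe_to_gene[[1]]))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0) stop("empty probe-to-gene mapping: no genes would remain")
  mapped <- rownames(m) %in% names(map)
  if (!any(mapped)) stop("no probe of `m` is present in the mapping")
  m <- m[mapped, , drop = FALSE]
  gene_of <- map[rownames(m)]
  idx <- split(seq_len(nrow(m)), gene_of)
  out <- t(vapply(idx, function(i) {
    apply(m[i, , drop = FALSE], 2, median)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  out[order(rownames(out)), , drop = FALSE]
}
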