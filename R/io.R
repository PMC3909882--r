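#' Read a gene expression matrix from TSV
#'
#' The expected layout is a header row of sample identifiers, a first
#' column of gene identifiers, and tab-separated numeric expression values
#' (log2-scale intensities in typical use). Gene identifiers must be
#' unique and every cell must be a finite number.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample column")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf(
          "non-numeric value '%s' at row %d (gene %s), column '%s'",
          v[bad[1]], bad[1], genes[bad[1]], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene %s, sample '%s'",
                 genes[idx[1]], colnames(m)[idx[2]]))
  }
  message(sprintf("read_expression: %d genes x %d samples from %s",
                  nrow(m), ncol(m), path))
  m
}

#' Write a gene expression matrix to TSV
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Each line is `term-id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Gene lists are deduplicated; terms left with no genes are skipped with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term id -> gene ids), with a
#'   `description` attribute (named character vector).
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 60))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) < 1) {
      warning("GMT term ", f[1], " has no genes; skipped")
      next
    }
    terms[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(terms, "description") <- desc
  terms
}

#' Write gene-set annotations in GMT format
#'
#' @param annotations Named list of character vectors; an optional
#'   `description` attribute supplies the second GMT column.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotations, path) {
  desc <- attr(annotations, "description")
  lines <- vapply(names(annotations), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else id
    paste(c(id, d, annotations[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene catalog (chromosome and census membership)
#'
#' The catalog is a TSV with columns `gene`, `chromosome` (one of 1-22, X,
#' Y) and `census` (0/1 flag for membership in a curated cancer-gene list).
#'
#' @param path Path to a tab-separated file.
#' @return A data frame with character columns `gene`, `chromosome` and an
#'   integer `census` column.
#' @seealso [write_catalog()]
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "census")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  df$gene <- as.character(df$gene)
  df$chromosome <- as.character(df$chromosome)
  validate_catalog(df)
  df[need]
}

validate_catalog <- function(catalog) {
  bad_chr <- setdiff(unique(catalog$chromosome), CHROMOSOMES)
  if (length(bad_chr) > 0) {
    stop("invalid chromosome label(s): ", paste(bad_chr, collapse = ", "),
         " (allowed: 1-22, X, Y)")
  }
  if (!all(catalog$census %in% c(0L, 1L))) {
    stop("`census` column must be 0/1")
  }
  dup <- unique(catalog$gene[duplicated(catalog$gene)])
  if (length(dup) > 0) {
    stop("duplicate gene(s) in catalog: ", paste(dup, collapse = ", "))
  }
  invisible(catalog)
}

#' Write a gene catalog to TSV
#'
#' @param catalog Data frame with columns `gene`, `chromosome`, `census`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network to an edge-list TSV or GraphML file
#'
#' The canonical on-disk format is a two-column tab-separated edge list
#' with the lexicographically smaller gene first and rows sorted, so that
#' files are diff-able and deterministic. GraphML is offered for
#' interoperability with external tools.
#'
#' @param network Undirected igraph network with named vertices.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return Invisibly, `path`.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  assert_network(network)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  if (igraph::ecount(network) > 0) {
    el <- igraph::as_edgelist(network, names = TRUE)
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    df <- data.frame(gene1 = a[o], gene2 = b[o], stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene1 = character(0), gene2 = character(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network from an edge-list TSV or GraphML file
#'
#' Multi-edges are collapsed and self-loops dropped (with a warning), so a
#' valid file round-trips losslessly and no self-loop is ever introduced.
#' Note the edge-list format carries no isolated vertices.
#'
#' @param path Input file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return An undirected simple igraph network with named vertices.
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("edge list needs two columns")
    df[[1]] <- as.character(df[[1]])
    df[[2]] <- as.character(df[[2]])
    g <- igraph::graph_from_data_frame(df[1:2], directed = FALSE)
  }
  if (any(igraph::which_loop(g))) {
    warning("self-loop(s) in ", path, " dropped")
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read / write a plain gene list (one id per line)
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector of unique ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(x[nzchar(x)])
}

#' @param genes Character vector of gene ids.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
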