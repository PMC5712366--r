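# Co-expression module: pairwise Pearson correlation over periodic genes,
# thresholded into an undirected network.

#' Pairwise Pearson correlation matrix over gene series
#'
#' @param series a [series_matrix()] (genes x time points, >= 3 points).
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(series) {
  m <- unclass(series)
  if (ncol(m) < 3) stopf("at least 3 time points are required")
  sds <- apply(m, 1, sd_pop)
  if (any(sds < 1e-12)) {
    stopf("constant gene has no defined correlation: %s",
          rownames(m)[which(sds < 1e-12)[1]])
  }
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Build a co-expression network from a correlation matrix
#'
#' An edge joins genes i < j when `r(i, j) >= cutoff` — a signed
#' threshold, as for the diel data anti-correlated gene pairs (peaks 12 h
#' apart) are the opposite phase, not co-expression.  `absolute = TRUE`
#' thresholds `|r|` instead.  The node set is the genes incident to at
#' least one edge.
#'
#' @param pcc symmetric correlation matrix (from [pcc_matrix()]).
#' @param cutoff correlation threshold in (0, 1].
#' @param absolute threshold on `|r|` rather than signed r.
#' @return object of class `coexpression_network`: `edges` (data.frame
#'   `gene_a`, `gene_b`, `pcc`), `nodes`, `cutoff`.
#' @export
build_gcn <- function(pcc, cutoff = 0.7, absolute = FALSE) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must be in (0, 1]")
  if (!isSymmetric(unname(pcc), tol = 1e-8)) stopf("pcc must be symmetric")
  ids <- rownames(pcc) %||% as.character(seq_len(nrow(pcc)))
  v <- if (absolute) abs(pcc) else pcc
  keep <- which(upper.tri(v) & v >= cutoff, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[keep[, 1]], gene_b = ids[keep[, 2]],
                      pcc = pcc[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes, cutoff = cutoff,
                 absolute = absolute),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (PCC >= %g%s)\n",
              length(x$nodes), nrow(x$edges), x$cutoff,
              if (x$absolute) ", absolute" else ""))
  invisible(x)
}

#' Node, edge and degree statistics of a co-expression network
#'
#' @param network a `coexpression_network`.
#' @return list with `n_nodes`, `n_edges`, and `degree` (named integer
#'   vector over the network's nodes).
#' @export
gcn_stats <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                      levels = network$nodes))
  list(n_nodes = length(network$nodes), n_edges = nrow(network$edges),
       degree = stats::setNames(as.integer(deg), names(deg)))
}

#' Write a co-expression network edge list as TSV
#' @param network a `coexpression_network`.
#' @param path output path.
#' @export
write_gcn_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
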