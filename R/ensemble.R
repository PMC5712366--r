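# Ensemble module: replicate-resampled network estimates, per-edge
# confidence counting, thresholded edge calling and summaries.

#' Resample one series matrix from replicate measurements
#'
#' One replicate index is drawn uniformly per time point and applied to
#' every gene (a replicate is one library; per-gene resampling would
#' destroy inter-gene covariance).  Time order is preserved, so the
#' temporal structure the ARX model relies on is intact.  This is the
#' same sampling scheme as [permutation_series()]; the two entry points
#' exist because the periodicity screen and the network ensemble use it
#' with different downstream contracts.
#'
#' @param tensor an [expr_tensor()] (2 or more replicates; with a single
#'   replicate the latent series is returned unchanged, with a warning).
#' @param seed integer seed.
#' @return a [series_matrix()] with attribute `selection`.
#' @export
resample_series <- function(tensor, seed = 1L) {
  permutation_series(tensor, seed = seed)
}

#' Ensemble of directed networks from replicate resamples
#'
#' Draws `M` resampled series matrices (seeds `base_seed + 1 ..
#' base_seed + M`), z-scores each gene series, and runs
#' [infer_network_single()] on each.  A trial is dropped (with a warning)
#' only if more than 10% of its targets failed; per-target failures
#' within a kept trial leave `NA` columns that count as absent edges.
#'
#' @param tensor an [expr_tensor()].
#' @param p ARX order.
#' @param M ensemble size (default 30).
#' @param base_seed integer base seed.
#' @param ... passed to [infer_network_single()].
#' @return list of `binary_network` matrices (length <= M), attribute
#'   `dropped_trials`.
#' @export
ensemble_infer <- function(tensor, p, M = 30, base_seed = 1L, ...) {
  stopifnot(inherits(tensor, "expr_tensor"))
  if (!is_count(M)) stopf("M must be a positive integer")
  nets <- vector("list", M)
  dropped <- integer(0)
  for (m in seq_len(M)) {
    sm <- resample_series(tensor, seed = base_seed + m)
    z <- suppressWarnings(zscore_genes(sm))
    B <- infer_network_single(z, p = p, ...)
    failed <- attr(B, "failed_targets")
    if (length(failed) > 0.1 * nrow(B)) {
      warning(sprintf("trial %d dropped: %d of %d targets failed",
                      m, length(failed), nrow(B)), call. = FALSE)
      dropped <- c(dropped, m)
    } else {
      nets[[m]] <- B
    }
  }
  nets <- nets[!vapply(nets, is.null, logical(1))]
  attr(nets, "dropped_trials") <- dropped
  nets
}

#' Per-edge confidence counts over an ensemble of networks
#'
#' @param networks list of G x G binary matrices with identical gene
#'   order (`NA` entries from failed targets count as 0).
#' @return object of class `confidence_matrix`: integer matrix `B` with
#'   `B[i, j]` = number of ensemble networks containing edge i -> j, and
#'   `M` = ensemble size.
#' @export
confidence_matrix <- function(networks) {
  if (length(networks) == 0) stopf("empty ensemble")
  dims <- vapply(networks, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("networks differ in shape")
  ids <- rownames(networks[[1]])
  for (net in networks) {
    if (!identical(rownames(net), ids)) stopf("networks differ in gene order")
  }
  B <- Reduce(`+`, lapply(networks, function(x) {
    x[is.na(x)] <- 0L
    unclass(x)
  }))
  structure(list(B = B, M = length(networks)), class = "confidence_matrix")
}

#' @export
print.confidence_matrix <- function(x, ...) {
  cat(sprintf("<confidence_matrix> %d genes, M = %d trials, max count %d\n",
              nrow(x$B), x$M, max(x$B)))
  invisible(x)
}

#' Call edges whose confidence strictly exceeds a threshold
#'
#' Edge i -> j is called when `B[i, j] > threshold` (strict exceedance:
#' a count equal to the threshold is not called).  Self-loops are
#' excluded from the called edge set and reported separately.
#'
#' @param B a [confidence_matrix()].
#' @param threshold integer in (0, M].
#' @return object of class `directed_network`: `edges` (data.frame
#'   `source`, `target`, `confidence`), `parents`, `children`, `nodes`,
#'   `self_loops`, `threshold`, `M`, `genes` (all genes in the matrix).
#' @export
call_edges <- function(B, threshold = 20) {
  stopifnot(inherits(B, "confidence_matrix"))
  if (threshold <= 0 || threshold > B$M) {
    stopf("threshold must be in (0, M = %d]", B$M)
  }
  m <- B$B
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(m > threshold & row(m) != col(m), arr.ind = TRUE)
  edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                      confidence = m[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  self_idx <- which(diag(m) > threshold)
  structure(list(
    edges = edges,
    parents = sort(unique(edges$source)),
    children = sort(unique(edges$target)),
    nodes = sort(unique(c(edges$source, edges$target))),
    self_loops = data.frame(gene = ids[self_idx],
                            confidence = diag(m)[self_idx],
                            stringsAsFactors = FALSE),
    threshold = threshold, M = B$M, genes = ids
  ), class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d edges (confidence > %d/%d): %d parents -> %d children\n",
              nrow(x$edges), x$threshold, x$M, length(x$parents),
              length(x$children)))
  invisible(x)
}

#' Summary statistics of a called directed network
#'
#' @param net a `directed_network` from [call_edges()].
#' @param peak_times optional named vector of peak times (h); when given,
#'   a cross-tabulation of parent peak times over 4 h bins is included.
#' @param hub_min_children hubs are parents with out-degree strictly
#'   greater than this (default 50).
#' @return list with `n_edges`, `n_parents`, `n_children`, `n_genes`
#'   (nodes with at least one edge), `hubs` (named out-degrees),
#'   `out_degree`, `in_degree` (named vectors over parents/children),
#'   and optionally `parent_peak_bins`.
#' @export
network_summary <- function(net, peak_times = NULL, hub_min_children = 50) {
  stopifnot(inherits(net, "directed_network"))
  out_deg <- table(factor(net$edges$source, levels = net$parents))
  in_deg <- table(factor(net$edges$target, levels = net$children))
  out_deg <- stats::setNames(as.integer(out_deg), names(out_deg))
  in_deg <- stats::setNames(as.integer(in_deg), names(in_deg))
  hubs <- out_deg[out_deg > hub_min_children]
  res <- list(n_edges = nrow(net$edges),
              n_parents = length(net$parents),
              n_children = length(net$children),
              n_genes = length(net$nodes),
              hubs = hubs[order(-hubs)],
              out_degree = out_deg, in_degree = in_deg)
  if (!is.null(peak_times) && length(net$parents) > 0) {
    pt <- peak_times[net$parents]
    res$parent_peak_bins <- table(cut(pt %% 24, breaks = seq(0, 24, by = 4),
                                      include.lowest = TRUE, right = FALSE))
  }
  res
}

#' Out-degree distribution with a descriptive log-log slope
#'
#' Histogram of positive out-degrees; when at least 5 distinct positive
#' out-degrees are present, the least-squares slope of log frequency
#' against log degree is reported descriptively (scale-free-like networks
#' show a negative slope; no hypothesis test is performed).
#'
#' @param net a `directed_network`, or a named vector of out-degrees.
#' @return list with `degrees` (table of positive out-degrees) and
#'   `slope` (`NA` when the support is too small).
#' @export
degree_distribution_fit <- function(net) {
  out_deg <- if (inherits(net, "directed_network")) {
    as.integer(table(factor(net$edges$source, levels = net$parents)))
  } else {
    as.integer(net)
  }
  out_deg <- out_deg[out_deg > 0]
  if (length(out_deg) == 0) {
    return(list(degrees = table(integer(0)), slope = NA_real_))
  }
  tab <- table(out_deg)
  if (length(tab) < 5) return(list(degrees = tab, slope = NA_real_))
  deg <- as.numeric(names(tab))
  slope <- unname(stats::coef(stats::lm(log(as.numeric(tab)) ~ log(deg)))[2])
  list(degrees = tab, slope = slope)
}

#' Write a confidence matrix / called network as coordinate TSV
#'
#' @param B a [confidence_matrix()].
#' @param net a `directed_network`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_confidence_tsv <- function(B, path) {
  stopifnot(inherits(B, "confidence_matrix"))
  m <- B$B
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                   confidence = m[idx], stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confidence_tsv
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Precision and recall of an inferred edge set against a truth adjacency
#'
#' Diagonal (self-loop) entries are ignored on both sides.
#'
#' @param inferred binary G x G matrix, `binary_network`, or
#'   `directed_network`.
#' @param truth_adjacency binary G x G matrix (regulator x target), same
#'   gene order.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
edge_recovery <- function(inferred, truth_adjacency) {
  G <- nrow(truth_adjacency)
  ids <- rownames(truth_adjacency) %||% as.character(seq_len(G))
  pred <- matrix(0L, G, G, dimnames = list(ids, ids))
  if (inherits(inferred, "directed_network")) {
    if (nrow(inferred$edges) > 0) {
      pred[cbind(match(inferred$edges$source, ids),
                 match(inferred$edges$target, ids))] <- 1L
    }
  } else {
    pred <- unclass(inferred)
    pred[is.na(pred)] <- 0L
  }
  off <- row(pred) != col(pred)
  tp <- sum(pred == 1 & truth_adjacency == 1 & off)
  fp <- sum(pred == 1 & truth_adjacency == 0 & off)
  fn <- sum(pred == 0 & truth_adjacency == 1 & off)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
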