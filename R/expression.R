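# Expression module: count -> RPM normalisation, expressed-gene filtering,
# replicate collapse, per-gene standardisation, and TSV readers/writers.

#' Reads-per-million normalisation
#'
#' `rpm(g, s) = count(g, s) / library_size(s) * 1e6`, with samples arranged
#' into the (time point, replicate) grid described by the metadata.  Gene
#' length is deliberately ignored (RPM, not RPKM/TPM).  The grid must be
#' complete: every (day, hour, replicate) cell present exactly once.
#'
#' @param counts a [count_matrix()].
#' @return an [expr_tensor()] of RPM values.
#' @examples
#' g <- design_grid(n_reps = 2)
#' sim <- generate_periodic_tensor(3, g, noise_sd = 0, seed = 1)
#' cm <- generate_counts(sim$tensor, 1e6, seed = 2)
#' rpm <- compute_rpm(cm)
#' @export
compute_rpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  meta <- counts$metadata
  key <- paste(meta$day, meta$hour, meta$replicate, sep = "_")
  dup <- duplicated(key)
  if (any(dup)) {
    stopf("duplicate (time point, replicate) sample: %s",
          meta$sample_id[dup][1])
  }
  days <- sort(unique(meta$day))
  hod <- sort(unique(meta$hour))
  reps <- sort(unique(meta$replicate))
  full <- expand.grid(day = days, hour = hod, replicate = reps)
  full_key <- paste(full$day, full$hour, full$replicate, sep = "_")
  missing <- setdiff(full_key, key)
  if (length(missing) > 0) {
    stopf("incomplete sampling grid: no sample for (day_hour_replicate) %s",
          missing[1])
  }
  grid <- design_grid(hours_of_day = hod, n_days = length(days),
                      n_reps = length(reps))
  rpm <- sweep(counts$counts, 2, counts$library_size, "/") * 1e6
  ng <- nrow(rpm); nt <- length(grid$hours); nr <- grid$n_reps
  vals <- array(NA_real_, dim = c(ng, nt, nr),
                dimnames = list(rownames(rpm), NULL, NULL))
  for (j in seq_len(ncol(rpm))) {
    di <- match(meta$day[j], days)  # grid days are indexed 1..n_days
    ti <- match(paste(di, meta$hour[j]), paste(grid$day, grid$hour_of_day))
    ri <- match(meta$replicate[j], reps)
    vals[, ti, ri] <- rpm[, j]
  }
  expr_tensor(vals, grid)
}

#' Expressed-gene filter
#'
#' A gene is called expressed if at least one sampling time has expression
#' at or above `min_rpm` in *all* replicates (boundary inclusive).
#'
#' @param tensor an [expr_tensor()] of RPM values.
#' @param min_rpm threshold (default 1 RPM).
#' @return character vector of expressed gene ids.
#' @export
filter_expressed <- function(tensor, min_rpm = 1) {
  stopifnot(inherits(tensor, "expr_tensor"))
  ok_tp <- apply(tensor$values >= min_rpm, c(1, 2), all)  # gene x time
  keep <- apply(ok_tp, 1, any)
  rownames(tensor$values)[keep]
}

#' Average replicates into one series per gene
#'
#' @param tensor an [expr_tensor()].
#' @return a [series_matrix()] of replicate means.
#' @export
replicate_mean <- function(tensor) {
  stopifnot(inherits(tensor, "expr_tensor"))
  m <- apply(tensor$values, c(1, 2), mean)
  series_matrix(m, tensor$grid$hours)
}

#' Standardise each gene series to mean 0, sd 1
#'
#' Uses the population sd (denominator n), matching the plug-in
#' correlations used downstream.  Constant genes cannot be standardised;
#' they are excluded and reported in the `excluded` attribute with a
#' warning rather than silently dropped.
#'
#' @param series a [series_matrix()].
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` before
#'   standardising (useful for raw RPM with heavy dynamic range).
#' @return a [series_matrix()] of z-scores (possibly fewer rows), with
#'   attribute `excluded` listing constant genes.
#' @export
zscore_genes <- function(series, log2_transform = FALSE) {
  m <- unclass(series)
  hours <- series_hours(series)
  if (log2_transform) {
    if (any(m < 0)) stopf("log2 transform requires non-negative values")
    m <- log2(m + 1)
  }
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  excluded <- character(0)
  for (i in seq_len(nrow(m))) {
    zi <- zscore_vec(m[i, ])
    if (is.null(zi)) excluded <- c(excluded, rownames(m)[i] %||% as.character(i))
    else z[i, ] <- zi
  }
  if (length(excluded) > 0) {
    warning(sprintf("%d constant gene(s) excluded from standardisation: %s",
                    length(excluded),
                    paste(utils::head(excluded, 5), collapse = ", ")),
            call. = FALSE)
    z <- z[!(rownames(z) %in% excluded), , drop = FALSE]
  }
  out <- series_matrix(z, hours)
  attr(out, "excluded") <- excluded
  out
}

#' Subset a tensor to a set of genes
#' @param tensor an [expr_tensor()].
#' @param gene_ids gene ids to keep (order preserved as given).
#' @return an [expr_tensor()].
#' @export
subset_genes <- function(tensor, gene_ids) {
  stopifnot(inherits(tensor, "expr_tensor"))
  miss <- setdiff(gene_ids, rownames(tensor$values))
  if (length(miss) > 0) stopf("unknown gene id: %s", miss[1])
  expr_tensor(tensor$values[gene_ids, , , drop = FALSE], tensor$grid)
}

# ---- TSV interfaces --------------------------------------------------------

#' Write / read a count matrix with metadata as TSV
#'
#' Counts: genes as rows, first column `gene_id`, one column per sample.
#' Metadata: 4 columns (`sample_id`, `day`, `hour`, `replicate`), plus an
#' optional `library_size` column; without it, library sizes are computed
#' as column sums on read.
#'
#' @param counts a [count_matrix()].
#' @param counts_path,metadata_path output/input TSV paths.
#' @param library_size_column write/read library sizes as a metadata
#'   column (`TRUE`) or recompute them as column sums (`FALSE`).
#' @return `read_counts_tsv` returns a [count_matrix()];
#'   `write_counts_tsv` returns the paths invisibly.
#' @export
write_counts_tsv <- function(counts, counts_path, metadata_path,
                             library_size_column = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- counts$metadata
  if (library_size_column) meta$library_size <- counts$library_size
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, metadata_path,
                            library_size_column = TRUE) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- utils::read.delim(metadata_path)
  lib <- if (library_size_column && "library_size" %in% names(meta)) {
    stats::setNames(meta$library_size, meta$sample_id)[colnames(m)]
  } else {
    NULL
  }
  count_matrix(m, meta, lib)
}

#' Write / read a series matrix as TSV (genes x time points)
#'
#' First column `gene_id`; remaining columns are labelled `h<hour>` with
#' the absolute sampling hour.
#' @param series a [series_matrix()].
#' @param path TSV path.
#' @return `read_series_tsv` returns a [series_matrix()].
#' @export
write_series_tsv <- function(series, path) {
  hours <- series_hours(series)
  df <- data.frame(gene_id = rownames(series) %||% seq_len(nrow(series)),
                   unclass(series), check.names = FALSE)
  names(df)[-1] <- sprintf("h%g", hours)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  hours <- as.numeric(sub("^h", "", colnames(m)))
  series_matrix(m, hours)
}
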