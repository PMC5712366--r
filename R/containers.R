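#' Sampling design for a diel time course
#'
#' Describes the sampling grid of the experiment: hours of day sampled on
#' each day, number of days, and biological replicates per time point.  The
#' default reproduces a two-day course sampled every 4 h at hours
#' 2, 6, 10, 14, 18, 22 (absolute hours 2..46) with three replicates.
#'
#' @param hours_of_day sampling hours within one day, strictly increasing,
#'   equally spaced.
#' @param n_days number of consecutive days sampled.
#' @param n_reps biological replicates per time point (>= 1).
#' @return An object of class `design_grid` with fields `hours` (absolute
#'   hours across days), `hour_of_day`, `day`, `dt` (sampling interval, h)
#'   and `n_reps`.
#' @examples
#' g <- design_grid()
#' g$hours     # 2  6 10 ... 46
#' @export
design_grid <- function(hours_of_day = c(2, 6, 10, 14, 18, 22),
                        n_days = 2, n_reps = 3) {
  if (!is_count(n_days) || !is_count(n_reps)) {
    stopf("n_days and n_reps must be positive integers")
  }
  if (length(hours_of_day) < 2 || any(diff(hours_of_day) <= 0)) {
    stopf("hours_of_day must be strictly increasing")
  }
  dts <- diff(hours_of_day)
  if (length(unique(dts)) != 1L) stopf("hours_of_day must be equally spaced")
  dt <- dts[1]
  # spacing must also hold across the day boundary
  if (hours_of_day[1] + 24 - hours_of_day[length(hours_of_day)] != dt && n_days > 1) {
    stopf("sampling interval is not constant across the day boundary")
  }
  day <- rep(seq_len(n_days), each = length(hours_of_day))
  hod <- rep(hours_of_day, times = n_days)
  hours <- hod + 24 * (day - 1)
  structure(
    list(hours = hours, hour_of_day = hod, day = day, dt = dt,
         n_reps = as.integer(n_reps)),
    class = "design_grid"
  )
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("<design_grid> %d time points (dt = %g h, %d day(s)), %d replicate(s)\n",
              length(x$hours), x$dt, max(x$day), x$n_reps))
  cat("  absolute hours:", paste(x$hours, collapse = " "), "\n")
  invisible(x)
}

#' Gene x time point x replicate expression tensor
#'
#' The pipeline's central container: a 3-d numeric array of expression
#' values (RPM or simulated units) with explicit time metadata.
#'
#' @param values numeric array `genes x timepoints x replicates`; rownames
#'   are gene ids (generated if missing).
#' @param grid a [design_grid()] whose time points and replicate count match
#'   `values`.
#' @return An object of class `expr_tensor` with fields `values` and `grid`.
#' @export
expr_tensor <- function(values, grid) {
  stopifnot(inherits(grid, "design_grid"))
  if (length(dim(values)) != 3L) stopf("values must be a 3-d array")
  if (dim(values)[2] != length(grid$hours)) {
    stopf("tensor has %d time points but the grid has %d",
          dim(values)[2], length(grid$hours))
  }
  if (dim(values)[3] != grid$n_reps) {
    stopf("tensor has %d replicates but the grid declares %d",
          dim(values)[3], grid$n_reps)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene_%04d", seq_len(dim(values)[1]))
  }
  structure(list(values = values, grid = grid), class = "expr_tensor")
}

#' @export
print.expr_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<expr_tensor> %d genes x %d time points x %d replicates\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.expr_tensor <- function(x) dim(x$values)

genes <- function(x) UseMethod("genes")
#' @export
genes.expr_tensor <- function(x) rownames(x$values)
#' @export
genes.default <- function(x) rownames(x)

#' Construct a series matrix (genes x time points)
#'
#' A plain numeric matrix carrying the sampling hours as an attribute; the
#' working form consumed by the periodicity, co-expression and network
#' stages (one series per gene, replicates already collapsed or resampled).
#'
#' @param m numeric matrix, genes in rows.
#' @param hours absolute sampling hours, one per column.
#' @return `m` with class `series_matrix` and attribute `hours`.
#' @export
series_matrix <- function(m, hours) {
  m <- as.matrix(m)
  if (ncol(m) != length(hours)) stopf("ncol(m) != length(hours)")
  if (anyNA(m)) stopf("series matrix must not contain missing values")
  if (any(diff(hours) <= 0)) stopf("hours must be strictly increasing")
  attr(m, "hours") <- as.numeric(hours)
  class(m) <- c("series_matrix", class(m))
  m
}

#' Sampling hours of a series matrix or tensor
#' @param x a `series_matrix` or `expr_tensor`.
#' @return numeric vector of absolute hours.
#' @export
series_hours <- function(x) {
  if (inherits(x, "expr_tensor")) return(x$grid$hours)
  h <- attr(x, "hours")
  if (is.null(h)) stopf("object carries no sampling hours")
  h
}

#' Count matrix with per-sample metadata
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns (colnames are sample ids).
#' @param metadata data.frame with columns `sample_id`, `day`, `hour`,
#'   `replicate`, one row per sample.
#' @param library_size per-sample mapped-read totals; if `NULL`, column
#'   sums of `counts` are used.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, metadata, library_size = NULL) {
  counts <- as.matrix(counts)
  need <- c("sample_id", "day", "hour", "replicate")
  if (!all(need %in% names(metadata))) {
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(colnames(counts))) colnames(counts) <- metadata$sample_id
  if (!setequal(colnames(counts), metadata$sample_id) ||
      ncol(counts) != nrow(metadata)) {
    stopf("count columns and metadata sample ids do not match")
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (is.null(library_size)) library_size <- colSums(counts)
  library_size <- as.numeric(library_size)
  if (length(library_size) != ncol(counts)) {
    stopf("library_size must have one entry per sample")
  }
  if (any(library_size <= 0)) stopf("library sizes must be positive")
  names(library_size) <- colnames(counts)
  structure(list(counts = counts, metadata = metadata,
                 library_size = library_size),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d day(s), %d replicate(s))\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$metadata$day)),
              length(unique(x$metadata$replicate))))
  invisible(x)
}
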