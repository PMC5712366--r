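# Small in-code fixtures shared across test files.

# tensor with given per-gene replicate values: vals is gene x time matrix,
# replicated identically unless `jitter` adds per-replicate offsets
toy_tensor <- function(vals, n_reps = 3, hours_of_day = c(2, 6, 10, 14, 18, 22),
                       n_days = 2) {
  grid <- design_grid(hours_of_day, n_days, n_reps)
  a <- array(rep(as.matrix(vals), n_reps),
             dim = c(nrow(vals), ncol(vals), n_reps))
  rownames(a) <- rownames(vals) %||% paste0("g", seq_len(nrow(vals)))
  expr_tensor(a, grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless cosine series matrix on the standard grid
cosine_series <- function(phases, amplitude = 1, baseline = 0) {
  g <- design_grid()
  m <- t(vapply(phases, function(ph) {
    baseline + amplitude * cos(2 * pi * (g$hours - ph) / 24)
  }, numeric(length(g$hours))))
  rownames(m) <- sprintf("cos_%02d", seq_along(phases))
  series_matrix(m, g$hours)
}

# count matrix on a small complete grid
toy_counts <- function(counts, n_reps = 1, hours_of_day = c(2, 6, 10, 14, 18, 22),
                       n_days = 2, library_size = NULL) {
  grid <- design_grid(hours_of_day, n_days, n_reps)
  nt <- length(grid$hours)
  meta <- data.frame(
    sample_id = sprintf("d%d_h%02d_r%d", rep(grid$day, times = n_reps),
                        rep(grid$hour_of_day, times = n_reps),
                        rep(seq_len(n_reps), each = nt)),
    day = rep(grid$day, times = n_reps),
    hour = rep(grid$hour_of_day, times = n_reps),
    replicate = rep(seq_len(n_reps), each = nt))
  colnames(counts) <- meta$sample_id
  count_matrix(counts, meta, library_size)
}

# independent-SCAD scalar oracle: brute-force grid bracket of the global
# minimum of 0.5 (z - b)^2 + p_{lambda,a}(b), refined by optimize()
scad_oracle <- function(z, lambda, a, grid_step = 1e-4) {
  pen <- function(b) {
    ifelse(b <= lambda, lambda * b,
           ifelse(b <= a * lambda,
                  (2 * a * lambda * b - b^2 - lambda^2) / (2 * (a - 1)),
                  lambda^2 * (a + 1) / 2))
  }
  obj <- function(b) 0.5 * (z - b)^2 + pen(b)
  bs <- seq(0, z + 2 * lambda + 1, by = grid_step)
  i <- which.min(obj(bs))
  lo <- bs[max(1, i - 1)]
  hi <- bs[min(length(bs), i + 1)]
  if (lo == hi) return(lo)
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  if (obj(0) < opt$objective) 0 else opt$minimum
}
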