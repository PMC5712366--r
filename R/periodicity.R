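# Periodicity screen: replicate-permutation consensus over surrogate
# p-values for 24 h Morlet power, plus harmonic-regression peak times.

#' Draw one series per gene by resampling replicates per time point
#'
#' At each time point one replicate index is drawn uniformly and applied
#' to every gene: a biological replicate is one library, so the whole
#' sample is taken together and inter-gene covariance is preserved.  Time
#' order is untouched.
#'
#' @param tensor an [expr_tensor()].
#' @param seed integer seed.
#' @return a [series_matrix()] (genes x time points) with attribute
#'   `selection` (the replicate index drawn per time point).
#' @export
permutation_series <- function(tensor, seed = 1L) {
  stopifnot(inherits(tensor, "expr_tensor"))
  nr <- tensor$grid$n_reps
  nt <- length(tensor$grid$hours)
  if (nr < 2) {
    warning("only one replicate: permutation series is the identity mapping",
            call. = FALSE)
    sel <- rep(1L, nt)
  } else {
    sel <- with_seed(seed, sample.int(nr, nt, replace = TRUE))
  }
  m <- matrix(NA_real_, dim(tensor$values)[1], nt,
              dimnames = list(rownames(tensor$values), NULL))
  for (t in seq_len(nt)) m[, t] <- tensor$values[, t, sel[t]]
  out <- series_matrix(m, tensor$grid$hours)
  attr(out, "selection") <- sel
  out
}

#' Consensus periodicity screen over replicate permutations
#'
#' For each of `n_perm` replicate-resampled series ([permutation_series()])
#' a surrogate p-value for 24 h Morlet power is computed per gene; a gene
#' is called periodic only if *all* `n_perm` p-values fall below `alpha`.
#' The white-noise null distribution depends on the data only through the
#' series length, so one surrogate draw per permutation is shared across
#' genes.  Peak times are estimated on the replicate-mean series by
#' first-harmonic regression ([estimate_peak_time()]) for every gene.
#'
#' @param tensor an [expr_tensor()].
#' @param n_perm number of replicate permutations (default 30).
#' @param alpha per-permutation significance level (default 0.01).
#' @param n_surrogates white-noise surrogates per permutation (>= 300).
#' @param seed integer base seed; permutation m uses `seed + m` for the
#'   replicate draw and `seed + n_perm + m` for its surrogate null.
#' @param target_period tested period (h).
#' @param omega0 Morlet parameter.
#' @param boundary wavelet boundary treatment, see [morlet_power()].
#' @return data.frame with columns `gene_id`, `min_p`, `max_p`,
#'   `is_periodic`, `peak_time` (h in `[0, 24)`, `NA` if undefined), and
#'   attribute `p_values` (genes x n_perm matrix).
#' @export
consensus_periodicity <- function(tensor, n_perm = 30, alpha = 0.01,
                                  n_surrogates = 1000, seed = 1L,
                                  target_period = 24, omega0 = 6,
                                  boundary = c("circular", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(tensor, "expr_tensor"))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (n_surrogates < 300) stopf("n_surrogates must be >= 300")
  dt <- tensor$grid$dt
  ng <- dim(tensor$values)[1]
  nt <- length(tensor$grid$hours)
  pvals <- matrix(NA_real_, ng, n_perm,
                  dimnames = list(rownames(tensor$values), NULL))
  for (m in seq_len(n_perm)) {
    sm <- permutation_series(tensor, seed = seed + m)
    Z <- matrix(NA_real_, ng, nt)
    const <- logical(ng)
    for (i in seq_len(ng)) {
      zi <- zscore_vec(sm[i, ])
      if (is.null(zi)) const[i] <- TRUE else Z[i, ] <- zi
    }
    null <- surrogate_null(nt, dt, target_period, n_surrogates,
                           seed = seed + n_perm + m, omega0 = omega0,
                           boundary = boundary)
    if (any(!const)) {
      obs <- cwt_power_core(Z[!const, , drop = FALSE], dt, target_period,
                            omega0, boundary = boundary)$mean_power[, 1]
      pvals[!const, m] <- (1 + vapply(obs, function(o) sum(null >= o),
                                      numeric(1))) / (1 + n_surrogates)
    }
    pvals[const, m] <- 1  # constant draw: no evidence of rhythm
  }
  mean_series <- replicate_mean(tensor)
  peak <- vapply(seq_len(ng), function(i) {
    estimate_peak_time(mean_series[i, ], hours = series_hours(mean_series),
                       period = target_period, quiet = TRUE)
  }, numeric(1))
  res <- data.frame(
    gene_id = rownames(tensor$values),
    min_p = unname(apply(pvals, 1, min)),
    max_p = unname(apply(pvals, 1, max)),
    is_periodic = unname(apply(pvals < alpha, 1, all)),
    peak_time = peak,
    stringsAsFactors = FALSE
  )
  attr(res, "p_values") <- pvals
  res
}

#' Peak time by first-harmonic regression
#'
#' Least-squares fit of `a*cos(2*pi*t/period) + b*sin(2*pi*t/period) + c`;
#' the fitted curve peaks at `(period / 2 pi) * atan2(b, a) mod period`.
#' Exact on noiseless sinusoids and equivariant under time shifts.
#'
#' @param series numeric vector of expression values.
#' @param hours absolute sampling hours (same length as `series`).
#' @param period period of the fitted harmonic (h, default 24).
#' @param quiet return `NA` silently (instead of with a warning) when the
#'   harmonic amplitude is exactly zero and the peak is undefined.
#' @return peak hour of day in `[0, period)`, or `NA` if undefined.
#' @examples
#' t <- seq(2, 46, by = 4)
#' estimate_peak_time(cos(2 * pi * (t - 10) / 24), t)  # 10
#' @export
estimate_peak_time <- function(series, hours, period = 24, quiet = FALSE) {
  if (length(series) != length(hours)) stopf("series/hours length mismatch")
  if (diff(range(hours)) < period - 1e-9) {
    stopf("series must cover at least one full period")
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * hours), sin(w * hours))
  cf <- qr.coef(qr(X), series)
  a <- cf[2]; b <- cf[3]
  if (sqrt(a^2 + b^2) < 1e-10 * max(abs(series), 1)) {
    if (!quiet) warning("zero harmonic amplitude: peak time undefined",
                        call. = FALSE)
    return(NA_real_)
  }
  pt <- ((period / (2 * pi)) * atan2(b, a)) %% period
  if (period - pt < 1e-9) pt <- 0  # roundoff just below the wrap point
  unname(pt)
}

#' Fraction of periodic genes peaking in the dark window
#'
#' @param records output of [consensus_periodicity()] (only rows with
#'   `is_periodic` are used) or a numeric vector of peak times.
#' @param dark_window `c(start, end)` hours of day of the dark period; a
#'   window wrapping midnight (start > end) is handled, e.g. the default
#'   `c(22, 2)` for a 20 h light / 4 h dark cycle.  Start inclusive, end
#'   exclusive.
#' @return fraction of peak times falling in the dark window.
#' @export
peak_time_bins <- function(records, dark_window = c(22, 2)) {
  peaks <- if (is.data.frame(records)) {
    records$peak_time[records$is_periodic]
  } else {
    as.numeric(records)
  }
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) == 0) stopf("no periodic genes with defined peak times")
  h <- peaks %% 24
  lo <- dark_window[1] %% 24; hi <- dark_window[2] %% 24
  in_dark <- if (lo < hi) h >= lo & h < hi else h >= lo | h < hi
  mean(in_dark)
}
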