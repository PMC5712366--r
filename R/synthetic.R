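# Synthetic-data module: diel expression tensors with known ground truth.
# Three gene classes mirror what the analysis assumes about real data:
# 24 h sinusoids (periodic genes), sparse ARX(p) systems (regulatory
# structure), and autocorrelated background noise (null genes).

#' Generate sinusoidal periodic genes with known phase
#'
#' Each gene follows `baseline + A * cos(2*pi*(t - phase)/24)` on the
#' sampling grid, with independent Gaussian measurement noise per
#' (gene, time point, replicate).  Baselines are drawn large enough that
#' noiseless values are non-negative.
#'
#' @param n_genes number of genes.
#' @param grid a [design_grid()].
#' @param amplitude_range interval from which amplitudes are drawn
#'   uniformly (expression units).
#' @param baseline_range interval for uniform baselines; the lower end is
#'   raised to `max(amplitude)` so the noiseless signal stays >= 0.
#' @param noise_sd replicate measurement noise sd (>= 0).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with `tensor` (an [expr_tensor()]) and `truth`
#'   (data.frame `gene_id`, `amplitude`, `phase`, `baseline`; phase in h,
#'   in `[0, 24)`).
#' @examples
#' out <- generate_periodic_tensor(5, design_grid(), seed = 1)
#' out$truth
#' @export
generate_periodic_tensor <- function(n_genes, grid = design_grid(),
                                     amplitude_range = c(4, 12),
                                     baseline_range = c(5, 20),
                                     noise_sd = 0.5, seed = 1L) {
  if (!is_count(n_genes)) stopf("n_genes must be a positive integer")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  stopifnot(inherits(grid, "design_grid"))
  with_seed(seed, {
    A <- stats::runif(n_genes, amplitude_range[1], amplitude_range[2])
    phase <- stats::runif(n_genes, 0, 24)
    lo <- pmax(baseline_range[1], A)  # keep noiseless signal non-negative
    baseline <- lo + stats::runif(n_genes) * pmax(baseline_range[2] - lo, 0)
    t_h <- grid$hours
    latent <- baseline + A * cos(outer(phase, t_h, function(p, t) 2 * pi * (t - p) / 24))
    vals <- array(rep(latent, grid$n_reps),
                  dim = c(n_genes, length(t_h), grid$n_reps))
    if (noise_sd > 0) {
      vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim = dim(vals))
    }
    rownames(vals) <- sprintf("per_%04d", seq_len(n_genes))
    truth <- data.frame(gene_id = rownames(vals), amplitude = A,
                        phase = phase %% 24, baseline = baseline,
                        stringsAsFactors = FALSE)
    list(tensor = expr_tensor(vals, grid), truth = truth)
  })
}

#' Generate non-periodic background genes (AR(1) latent series)
#'
#' Null genes for type-I-error testing of the periodicity screen: each
#' gene's latent series is a stationary AR(1) process; independent
#' replicate noise is added around it.
#'
#' @param n_genes number of genes.
#' @param grid a [design_grid()].
#' @param ar_coefficient AR(1) coefficient, `|phi| < 1`.
#' @param noise_sd sd of the AR innovations and of the replicate noise.
#' @param baseline constant added to every series (expression units).
#' @param seed integer seed.
#' @return an [expr_tensor()].
#' @export
generate_nonperiodic_tensor <- function(n_genes, grid = design_grid(),
                                        ar_coefficient = 0.3, noise_sd = 1,
                                        baseline = 10, seed = 1L) {
  if (!is_count(n_genes)) stopf("n_genes must be a positive integer")
  if (abs(ar_coefficient) >= 1) stopf("|ar_coefficient| must be < 1 (stationarity)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  with_seed(seed, {
    nt <- length(grid$hours)
    latent <- matrix(0, n_genes, nt)
    if (noise_sd > 0) {
      # stationary start, then the recursion
      latent[, 1] <- stats::rnorm(n_genes, 0, noise_sd / sqrt(1 - ar_coefficient^2))
      if (nt > 1) {
        for (t in 2:nt) {
          latent[, t] <- ar_coefficient * latent[, t - 1] +
            stats::rnorm(n_genes, 0, noise_sd)
        }
      }
    }
    vals <- array(rep(baseline + latent, grid$n_reps),
                  dim = c(n_genes, nt, grid$n_reps))
    if (noise_sd > 0) {
      vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim = dim(vals))
    }
    rownames(vals) <- sprintf("bkg_%04d", seq_len(n_genes))
    expr_tensor(vals, grid)
  })
}

# Companion matrix of an order-p VAR with coefficient list C (each G x G).
companion_matrix <- function(C) {
  p <- length(C)
  G <- nrow(C[[1]])
  comp <- matrix(0, G * p, G * p)
  for (l in seq_len(p)) comp[seq_len(G), (l - 1) * G + seq_len(G)] <- C[[l]]
  if (p > 1) {
    comp[G + seq_len(G * (p - 1)), seq_len(G * (p - 1))] <-
      diag(G * (p - 1))
  }
  comp
}

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

#' Simulate a sparse ARX(p) gene system with known regulatory truth
#'
#' Builds a random sparse directed network (`n_parents` regulators, each
#' with `children_per_parent` distinct targets), assigns each edge a
#' coefficient of random sign and magnitude drawn from `coef_magnitude` at
#' one of the `order` lags, and simulates
#' `x(t) = sum_l C_l x(t-l) + e(t)` with Gaussian innovations after a
#' discarded burn-in.  Coefficient matrices are rescaled if needed so the
#' companion-matrix spectral radius is at most 0.95 (stationarity).
#' Optionally, replicate measurement noise is added around the latent
#' trajectory to emulate biological replicates.
#'
#' @param n_genes number of genes.
#' @param n_parents number of regulator genes.
#' @param children_per_parent targets per regulator (edges are distinct,
#'   no self-edges).
#' @param order ARX order p (1, 2 or 3).
#' @param coef_magnitude interval for |coefficient|.
#' @param innovation_sd sd of the process innovations.
#' @param grid_or_length a [design_grid()] (series length = number of time
#'   points) or a plain series length.
#' @param n_reps replicates (used when `grid_or_length` is a length;
#'   a grid supplies its own).
#' @param obs_noise_sd replicate measurement noise sd around the latent
#'   series (0 = replicates identical to the latent trajectory).
#' @param burn_in steps discarded before recording (>= 100).
#' @param seed integer seed.
#' @return list with `tensor` (an [expr_tensor()]), `truth` (list with
#'   binary `adjacency` regulator x target, `coefficients` array
#'   `G x G x p`, `order`), and `latent` (the noise-free series matrix).
#' @export
generate_arx_tensor <- function(n_genes, n_parents, children_per_parent,
                                order = 1, coef_magnitude = c(0.4, 0.8),
                                innovation_sd = 0.1,
                                grid_or_length = 100, n_reps = 1,
                                obs_noise_sd = 0, burn_in = 100,
                                seed = 1L) {
  if (!is_count(n_genes)) stopf("n_genes must be a positive integer")
  if (!order %in% 1:3) stopf("order must be 1, 2 or 3")
  if (burn_in < 100) stopf("burn_in must be at least 100 steps")
  n_edges <- n_parents * children_per_parent
  if (n_edges > n_genes^2 - n_genes) {
    stopf("%d edges requested but only %d distinct off-diagonal pairs exist",
          n_edges, n_genes^2 - n_genes)
  }
  if (children_per_parent > n_genes - 1) {
    stopf("children_per_parent exceeds the number of possible targets")
  }
  if (inherits(grid_or_length, "design_grid")) {
    grid <- grid_or_length
    nt <- length(grid$hours)
    n_reps <- grid$n_reps
  } else {
    nt <- as.integer(grid_or_length)
    if (nt < order + 1) stopf("series length must exceed the order")
    grid <- NULL
  }
  with_seed(seed, {
    adj <- matrix(0L, n_genes, n_genes)
    coefs <- array(0, dim = c(n_genes, n_genes, order))
    if (n_parents > 0 && children_per_parent > 0) {
      parents <- sample.int(n_genes, n_parents)
      for (pg in parents) {
        cand <- setdiff(seq_len(n_genes), pg)
        kids <- cand[sample.int(length(cand), children_per_parent)]
        adj[pg, kids] <- 1L
        for (kid in kids) {
          lag <- if (order == 1) 1L else sample.int(order, 1L)
          mag <- stats::runif(1, coef_magnitude[1], coef_magnitude[2])
          coefs[pg, kid, lag] <- sample(c(-1, 1), 1) * mag
        }
      }
    }
    # C_l[target, regulator] for the recursion x(t) = sum_l C_l x(t-l) + e
    C <- lapply(seq_len(order), function(l) t(coefs[, , l]))
    rho <- spectral_radius(companion_matrix(C))
    if (rho > 0.95) {
      shrink <- 0.95 / rho
      C <- lapply(seq_along(C), function(l) C[[l]] * shrink^l)
      for (l in seq_len(order)) coefs[, , l] <- t(C[[l]])
      rho2 <- spectral_radius(companion_matrix(C))
      if (rho2 > 0.95 + 1e-8) {  # lag-power shrinkage can undershoot; be safe
        C <- lapply(C, function(m) m * 0.95 / rho2)
        for (l in seq_len(order)) coefs[, , l] <- C[[l]] * 0  # recompute below
        for (l in seq_len(order)) coefs[, , l] <- t(C[[l]])
      }
    }
    total <- burn_in + nt
    x <- matrix(0, n_genes, total)
    for (t in seq_len(total)) {
      xt <- stats::rnorm(n_genes, 0, innovation_sd)
      for (l in seq_len(order)) {
        if (t - l >= 1) xt <- xt + C[[l]] %*% x[, t - l]
      }
      x[, t] <- xt
    }
    latent <- x[, burn_in + seq_len(nt), drop = FALSE]
    rownames(latent) <- sprintf("arx_%04d", seq_len(n_genes))
    dimnames(adj) <- list(rownames(latent), rownames(latent))
    vals <- array(rep(latent, n_reps), dim = c(n_genes, nt, n_reps))
    if (obs_noise_sd > 0) {
      vals <- vals + array(stats::rnorm(length(vals), 0, obs_noise_sd),
                           dim = dim(vals))
    }
    rownames(vals) <- rownames(latent)
    if (is.null(grid)) {
      grid <- design_grid(hours_of_day = seq_len(nt),
                          n_days = 1, n_reps = n_reps)
      # plain-length mode: unit spacing, hours 1..nt
      grid$hours <- as.numeric(seq_len(nt)); grid$hour_of_day <- grid$hours
      grid$day <- rep(1L, nt); grid$dt <- 1
    }
    hrs <- grid$hours
    lat_sm <- series_matrix(latent, hrs)
    list(tensor = expr_tensor(vals, grid),
         truth = list(adjacency = adj, coefficients = coefs, order = order),
         latent = lat_sm)
  })
}

#' Poisson read counts from an expression tensor
#'
#' Inverse of the RPM transform: `count(g, sample) ~ Poisson(rpm *
#' library_size / 1e6)` per sample (one sample = one (time point,
#' replicate) cell).
#'
#' @param tensor an [expr_tensor()] with non-negative values (RPM scale).
#' @param library_sizes per-sample mapped-read totals: either one number
#'   recycled, or a vector of length `timepoints * replicates` in
#'   column-major (time fastest) sample order.
#' @param seed integer seed.
#' @return a [count_matrix()] whose sample metadata reproduces the grid.
#' @export
generate_counts <- function(tensor, library_sizes = 2e7, seed = 1L) {
  stopifnot(inherits(tensor, "expr_tensor"))
  if (any(tensor$values < 0)) {
    stopf("expression values must be non-negative to generate counts")
  }
  grid <- tensor$grid
  nt <- length(grid$hours); nr <- grid$n_reps; ng <- nrow(tensor$values)
  n_samp <- nt * nr
  if (length(library_sizes) == 1L) library_sizes <- rep(library_sizes, n_samp)
  if (length(library_sizes) != n_samp) {
    stopf("library_sizes must have length 1 or %d", n_samp)
  }
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  meta <- data.frame(
    sample_id = sprintf("d%d_h%02d_r%d", rep(grid$day, times = nr),
                        rep(grid$hour_of_day, times = nr),
                        rep(seq_len(nr), each = nt)),
    day = rep(grid$day, times = nr),
    hour = rep(grid$hour_of_day, times = nr),
    replicate = rep(seq_len(nr), each = nt),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    counts <- matrix(0L, ng, n_samp,
                     dimnames = list(rownames(tensor$values), meta$sample_id))
    k <- 0L
    for (r in seq_len(nr)) {
      for (t in seq_len(nt)) {
        k <- k + 1L
        mu <- tensor$values[, t, r] * library_sizes[k] / 1e6
        counts[, k] <- stats::rpois(ng, mu)
      }
    }
    count_matrix(counts, meta, library_sizes)
  })
}
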