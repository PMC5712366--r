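test_that("periodic generator places the noiseless cosine maximum at the phase", {
  g <- design_grid()
  out <- generate_periodic_tensor(1, g, amplitude_range = c(1, 1),
                                  baseline_range = c(2, 2), noise_sd = 0,
                                  seed = 1)
  # force known truth: phase 10, A 1, baseline 2
  lat <- 2 + 1 * cos(2 * pi * (g$hours - 10) / 24)
  vals <- array(rep(lat, 3), dim = c(1, 12, 3))
  rownames(vals) <- "g1"
  ten <- expr_tensor(vals, g)
  i10 <- which(g$hours == 10)
  expect_equal(unname(ten$values[1, i10, ]), rep(3, 3))
  expect_true(all(ten$values[1, i10, ] >= ten$values[1, , ]))
  # generator's own truth record is honoured at every grid point
  tr <- out$truth
  expected <- tr$baseline + tr$amplitude * cos(2 * pi * (g$hours - tr$phase) / 24)
  expect_equal(unname(out$tensor$values[1, , 1]), expected, tolerance = 1e-12)
})

test_that("noiseless periodic genes repeat exactly across days", {
  out <- generate_periodic_tensor(5, noise_sd = 0, seed = 3)
  v <- out$tensor$values
  expect_equal(v[, 1:6, ], v[, 7:12, ], tolerance = 1e-12)
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_periodic_tensor(4, seed = 11),
                   generate_periodic_tensor(4, seed = 11))
  expect_identical(generate_nonperiodic_tensor(4, seed = 11),
                   generate_nonperiodic_tensor(4, seed = 11))
  expect_identical(generate_arx_tensor(6, 2, 2, seed = 11),
                   generate_arx_tensor(6, 2, 2, seed = 11))
  expect_false(identical(generate_periodic_tensor(4, seed = 11),
                         generate_periodic_tensor(4, seed = 12)))
})

test_that("generator argument validation rejects bad inputs", {
  expect_error(generate_periodic_tensor(0), "positive integer")
  expect_error(generate_periodic_tensor(2, noise_sd = -1), "non-negative")
  expect_error(generate_nonperiodic_tensor(2, ar_coefficient = 1),
               "stationarity")
  expect_error(generate_arx_tensor(3, 3, 3), "off-diagonal")
})

test_that("uncorrelated background genes show no lag-1 autocorrelation", {
  grid <- design_grid()
  ten <- generate_nonperiodic_tensor(1000, grid, ar_coefficient = 0,
                                     noise_sd = 1, seed = 5)
  sm <- replicate_mean(ten)
  ac1 <- apply(unclass(sm), 1, function(x) {
    stats::cor(x[-1], x[-length(x)])
  })
  expect_lt(abs(mean(ac1)), 0.1)
})

test_that("background generator with zero noise degenerates to the baseline", {
  ten <- generate_nonperiodic_tensor(3, noise_sd = 0, baseline = 7, seed = 1)
  expect_true(all(ten$values == 7))
})

test_that("ARX generator with no edges gives independent white noise", {
  out <- generate_arx_tensor(10, 0, 0, order = 2, innovation_sd = 1,
                             grid_or_length = 2000, seed = 4)
  expect_equal(sum(out$truth$adjacency), 0)
  expect_true(all(out$truth$coefficients == 0))
  ac1 <- apply(unclass(out$latent), 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(max(abs(ac1)), 0.1)
})

test_that("ARX lag-1 cross-correlation matches the Yule-Walker value", {
  # x1 white noise, x2(t) = c x1(t-1) + e2:
  # corr(x1(t-1), x2(t)) = c * sd(x1) / sd(x2) = c / sqrt(c^2 + 1)
  found <- FALSE
  for (seed in 1:20) {
    out <- generate_arx_tensor(2, 1, 1, order = 1,
                               coef_magnitude = c(0.8, 0.8),
                               innovation_sd = 1, grid_or_length = 5000,
                               seed = seed)
    ij <- which(out$truth$adjacency == 1, arr.ind = TRUE)
    cf <- out$truth$coefficients[ij[1], ij[2], 1]
    if (cf > 0) {  # want the +0.8 case to compare signed correlation
      found <- TRUE
      x <- unclass(out$latent)
      expected <- 0.8 / sqrt(0.8^2 + 1)
      obs <- cor(x[ij[1], -ncol(x)], x[ij[2], -1])
      expect_equal(obs, expected, tolerance = 0.05)
      break
    }
  }
  expect_true(found)
})

test_that("every generated ARX system satisfies the spectral-radius bound", {
  for (seed in 1:100) {
    out <- generate_arx_tensor(8, 3, 2, order = sample(1:3, 1),
                               coef_magnitude = c(0.4, 0.8),
                               grid_or_length = 10, seed = seed)
    C <- lapply(seq_len(out$truth$order),
                function(l) t(out$truth$coefficients[, , l]))
    rho <- max(Mod(eigen(dielnet:::companion_matrix(C),
                         only.values = TRUE)$values))
    expect_lte(rho, 0.95 + 1e-8)
  }
})

test_that("count generation is Poisson with the RPM-scaled mean", {
  g <- design_grid(n_reps = 1)
  vals <- array(1, dim = c(500, 12, 1))
  rownames(vals) <- paste0("g", 1:500)
  ten <- expr_tensor(vals, g)
  cm <- generate_counts(ten, library_sizes = 1e6, seed = 2)
  # 1 RPM at library 1e6 -> Poisson(1)
  expect_equal(mean(cm$counts), 1, tolerance = 0.05)
  expect_equal(var(as.numeric(cm$counts)), 1, tolerance = 0.1)
  # zero expression -> zero counts always
  ten0 <- expr_tensor(array(0, dim = c(3, 12, 1),
                            dimnames = list(paste0("z", 1:3), NULL, NULL)), g)
  expect_true(all(generate_counts(ten0, 1e7, seed = 1)$counts == 0))
  # negative expression rejected
  tneg <- ten
  tneg$values[1, 1, 1] <- -1
  expect_error(generate_counts(tneg, 1e6), "non-negative")
})

test_that("counts -> RPM round-trip recovers expression in expectation", {
  g <- design_grid(n_reps = 1)
  lat <- matrix(c(10, 20, 50, 200), 4, 12)
  rownames(lat) <- paste0("g", 1:4)
  ten <- toy_tensor(lat, n_reps = 1)
  acc <- 0
  for (seed in 1:200) {
    acc <- acc + compute_rpm(generate_counts(ten, 2e6, seed = seed))$values
  }
  expect_equal(acc / 200, ten$values, tolerance = 0.02)
})
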