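test_that("wavelet power of a pure 24 h tone peaks at 24 h", {
  t <- design_grid()$hours
  ps <- morlet_power(cos(2 * pi * t / 24), dt = 4)
  expect_equal(ps$periods[which.max(ps$mean_power)], 24)
  expect_true(all(ps$power >= 0))
  expect_true(24 %in% ps$periods)
})

test_that("wavelet power rejects degenerate inputs", {
  expect_error(morlet_power(rep(1, 12), dt = 4), "constant")
  expect_error(morlet_power(rnorm(6), dt = 4), "at least 8")
  expect_error(morlet_power(rnorm(12), dt = 4, periods = 96),
               "too short")
})

test_that("white noise shows no systematic power excess at 24 h", {
  # two-sided sign test of mean power at 24 h against both neighbours
  periods <- default_periods()
  i24 <- which(periods == 24)
  nbr <- periods[c(i24 - 1, i24 + 1)]
  set.seed(31)
  diffs <- replicate(500, {
    x <- rnorm(12)
    mp <- morlet_power(x, dt = 4, periods = c(nbr[1], 24, nbr[2]))$mean_power
    c(mp[2] - mp[1], mp[2] - mp[3])
  })
  for (k in 1:2) {
    bt <- binom.test(sum(diffs[k, ] > 0), ncol(diffs), p = 0.5)
    expect_gt(bt$p.value, 0.01)
  }
})

test_that("a noiseless 24 h cosine attains the minimal surrogate p-value", {
  t <- design_grid()$hours
  p <- surrogate_pvalue(cos(2 * pi * t / 24), dt = 4, n_surrogates = 1000,
                        seed = 5)
  expect_equal(p, 1 / 1001)
  expect_lt(p, 0.01)
  # same seed, same p
  x <- rnorm(12)
  expect_identical(surrogate_pvalue(x, dt = 4, seed = 9),
                   surrogate_pvalue(x, dt = 4, seed = 9))
  expect_error(surrogate_pvalue(x, dt = 4, n_surrogates = 100), ">= 300")
})

test_that("surrogate p-values are calibrated under the white-noise null", {
  set.seed(77)
  n <- 2000
  hits <- 0
  for (i in seq_len(n)) {
    p <- surrogate_pvalue(rnorm(12), dt = 4, n_surrogates = 300,
                          seed = 10000 + i)
    if (p < 0.01) hits <- hits + 1
  }
  # achievable rejection level with 300 surrogates is 3/301
  level <- 3 / 301
  ci <- qbinom(c(0.005, 0.995), n, level)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("permutation series resamples whole samples per time point", {
  set.seed(2)
  a <- array(rnorm(5 * 12 * 3), dim = c(5, 12, 3),
             dimnames = list(paste0("g", 1:5), NULL, NULL))
  ten <- expr_tensor(a, design_grid())
  s1 <- permutation_series(ten, seed = 4)
  s2 <- permutation_series(ten, seed = 4)
  expect_identical(s1, s2)
  sel <- attr(s1, "selection")
  expect_length(sel, 12)
  for (t in 1:12) expect_equal(unname(s1[, t]), unname(a[, t, sel[t]]))

  # identical replicates: any draw equals the replicate mean
  ten_id <- toy_tensor(matrix(rnorm(24), 2))
  expect_equal(unclass(permutation_series(ten_id, seed = 1)),
               unclass(replicate_mean(ten_id)), ignore_attr = TRUE)

  one <- toy_tensor(matrix(rnorm(12), 1), n_reps = 1)
  expect_warning(s0 <- permutation_series(one, seed = 1), "one replicate")
  expect_equal(unname(s0[1, ]), unname(one$values[1, , 1]))
})

test_that("consensus screen flags noiseless cosines and not white noise", {
  g <- design_grid()
  lat <- rbind(cos1 = 5 + 2 * cos(2 * pi * (g$hours - 3) / 24),
               cos2 = 5 + 2 * cos(2 * pi * (g$hours - 15) / 24),
               wn1 = 5 + rnorm(12), wn2 = 5 + rnorm(12), wn3 = 5 + rnorm(12))
  ten <- toy_tensor(lat)
  res <- consensus_periodicity(ten, n_perm = 5, n_surrogates = 300, seed = 8)
  expect_true(all(res$is_periodic[1:2]))
  expect_equal(res$peak_time[1], 3, tolerance = 1e-6)
  expect_equal(res$peak_time[2], 15, tolerance = 1e-6)
  expect_true(all(res$min_p >= 0 & res$max_p <= 1))
  pv <- attr(res, "p_values")
  expect_equal(dim(pv), c(5, 5))
  expect_equal(res$is_periodic, unname(apply(pv < 0.01, 1, all)))
})

test_that("a single permutation reduces the consensus to one test", {
  ten <- toy_tensor(matrix(rnorm(36), 3))
  res <- consensus_periodicity(ten, n_perm = 1, n_surrogates = 300, seed = 3)
  pv <- attr(res, "p_values")
  expect_equal(ncol(pv), 1)
  expect_equal(res$min_p, res$max_p)
  expect_equal(res$is_periodic, unname(pv[, 1] < 0.01))
})

test_that("harmonic regression recovers phases exactly on pure tones", {
  t <- design_grid()$hours
  for (ph in c(0, 6, 10, 23.999)) {
    expect_equal(estimate_peak_time(cos(2 * pi * (t - ph) / 24), t),
                 ph, tolerance = 1e-9)
  }
  # quadrature case: sin peaks at 6 h
  expect_equal(estimate_peak_time(sin(2 * pi * t / 24), t), 6,
               tolerance = 1e-9)
  expect_warning(out <- estimate_peak_time(rep(3, length(t)) + 0 * t, t),
                 "undefined")
  expect_true(is.na(out))
  expect_error(estimate_peak_time(rnorm(3), c(0, 4, 8)), "full period")
})

test_that("peak time is equivariant under time shifts and amplitude", {
  t <- design_grid()$hours
  set.seed(14)
  x <- 2 * cos(2 * pi * (t - 7) / 24) + rnorm(12, 0, 0.3)
  base <- estimate_peak_time(x, t)
  for (shift in c(4, 8, 12)) {
    shifted <- estimate_peak_time(x, t + shift)
    expect_equal(shifted, (base + shift) %% 24, tolerance = 1e-9)
  }
  # positive scaling leaves both p-value and peak unchanged
  expect_equal(estimate_peak_time(10 * x, t), base, tolerance = 1e-12)
  expect_identical(surrogate_pvalue(10 * x, dt = 4, seed = 2),
                   surrogate_pvalue(x, dt = 4, seed = 2))
})

test_that("dark-window peak fraction follows the light schedule", {
  expect_equal(peak_time_bins(rep(0, 10), dark_window = c(22, 2)), 1)
  expect_equal(peak_time_bins(c(21.9, 2.1), dark_window = c(22, 2)), 0)
  set.seed(6)
  u <- runif(20000, 0, 24)
  expect_equal(peak_time_bins(u, dark_window = c(22, 2)), 4 / 24,
               tolerance = 0.02)
  expect_error(peak_time_bins(numeric(0)), "no periodic genes")
  # data.frame input uses only periodic rows
  df <- data.frame(gene_id = c("a", "b"), is_periodic = c(TRUE, FALSE),
                   peak_time = c(23, 23))
  expect_equal(peak_time_bins(df), 1)
})
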