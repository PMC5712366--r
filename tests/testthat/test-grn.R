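test_that("SCAD threshold matches its piecewise closed form", {
  expect_equal(scad_threshold(0.5, 1), 0)
  expect_equal(scad_threshold(1, 1), 0)          # boundary: z = lambda
  expect_equal(scad_threshold(1.5, 1), 0.5)      # soft-threshold region
  expect_equal(scad_threshold(5, 1, a = 3.7), 5) # unbiasedness region
  expect_equal(scad_threshold(3, 1, a = 3.7), (2.7 * 3 - 3.7) / 1.7)
  expect_error(scad_threshold(1, 1, a = 2), "exceed 2")
  expect_error(scad_threshold(-1, 1), "non-negative")
})

test_that("SCAD threshold agrees with the brute-force scalar oracle", {
  # small lattice here; the full acceptance lattice lives in the
  # acceptance suite
  for (lam in c(0.5, 2)) {
    for (a in c(2.5, 3.7)) {
      for (z in seq(0, 6, by = 0.25)) {
        expect_equal(scad_threshold(z, lam, a), scad_oracle(z, lam, a),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("the SCAD threshold is continuous in z", {
  for (lam in c(0.5, 1, 2)) {
    for (a in c(2.5, 3.7, 5)) {
      z <- seq(0, 6, by = 1e-3)
      th <- scad_threshold(z, lam, a)
      # steepest segment has slope (a-1)/(a-2); no jumps beyond it
      expect_lt(max(abs(diff(th))), 1.5e-3 * (a - 1) / (a - 2))
    }
  }
})

test_that("lagged designs have the documented shape and contents", {
  hrs <- c(0, 4, 8, 12)
  sm <- series_matrix(rbind(g1 = c(1, 2, 3, 4), g2 = c(10, 20, 30, 40)), hrs)
  d1 <- build_lagged_design(sm, "g1", 1)
  expect_length(d1$y, 3)
  expect_equal(dim(d1$X), c(3, 2))
  expect_equal(d1$groups, c(1, 2))

  d2 <- build_lagged_design(sm, "g1", 2)
  expect_length(d2$y, 2)
  expect_equal(dim(d2$X), c(2, 4))
  expect_equal(d2$groups, c(1, 1, 2, 2))

  # hand-checked lag contents on a 5-point series
  sm5 <- series_matrix(rbind(g1 = 1:5, g2 = 6:10), c(0, 4, 8, 12, 16))
  d <- build_lagged_design(sm5, "g2", 2)
  expect_equal(d$y, c(8, 9, 10), ignore_attr = TRUE)
  expect_equal(unname(d$X),
               cbind(c(2, 3, 4), c(1, 2, 3),    # g1 lag1, lag2
                     c(7, 8, 9), c(6, 7, 8)))   # g2 lag1, lag2
  expect_error(build_lagged_design(sm5, "g1", 3), NA)
  sm3 <- series_matrix(rbind(g1 = 1:3, g2 = 4:6), c(0, 4, 8))
  expect_error(build_lagged_design(sm3, "g1", 3), "must exceed")
})

test_that("lambda = 0 on an overdetermined design recovers least squares", {
  set.seed(21)
  m <- matrix(rnorm(5 * 201), 5, 201, dimnames = list(paste0("g", 1:5), NULL))
  sm <- series_matrix(m, seq_len(201))
  des <- build_lagged_design(sm, "g3", 2)
  fit <- fit_group_scad(des, lambda = 0)
  ols <- qr.coef(qr(cbind(1, des$X)), des$y)
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$intercept), unname(ols[1]), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("lambda at or above lambda_max zeroes every group", {
  set.seed(22)
  m <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(paste0("g", 1:6), NULL))
  sm <- series_matrix(m, seq_len(40))
  des <- build_lagged_design(sm, "g1", 1)
  prep <- dielnet:::prepare_design(des)
  lmax <- max(abs(crossprod(prep$Xt, prep$yc) / prep$n))
  fit <- fit_group_scad(des, lambda = lmax * 1.0000001)
  expect_true(all(fit$coefficients == 0))
  expect_equal(sum(fit$selected), 0)
})

test_that("a single orthonormal group solves in one SCAD threshold", {
  set.seed(23)
  n <- 50
  Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  X <- sqrt(n) * Q
  beta_true <- c(0.7, -0.4)
  y <- X %*% beta_true + rnorm(n, 0, 0.1)
  des <- list(y = as.numeric(y), X = X, groups = c(1, 1),
              genes = "g1", target = "g1", p = 2)
  colnames(des$X) <- c("g1.lag1", "g1.lag2")
  class(des) <- "grouped_design"
  prep <- dielnet:::prepare_design(des)
  zn <- sqrt(sum((crossprod(prep$Xt, prep$yc) / prep$n)^2))
  for (lam in c(0.05, 0.3, 0.8)) {
    fit <- fit_group_scad(des, lambda = lam)
    # group_norms live in the orthonormal basis: the single-group solution
    # is exactly one SCAD threshold of the correlation norm
    expect_equal(unname(fit$group_norms), scad_threshold(zn, lam),
                 tolerance = 1e-8)
  }
})

test_that("reported objectives are consistent and descend from zero", {
  set.seed(24)
  m <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(paste0("g", 1:8), NULL))
  sm <- series_matrix(m, seq_len(30))
  des <- build_lagged_design(sm, "g2", 2)
  prep <- dielnet:::prepare_design(des)
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- fit_group_scad(des, lambda = lam)
    obj0 <- sum(prep$yc^2) / (2 * prep$n)  # objective of the zero vector
    expect_lte(fit$objective, obj0 + 1e-12)
    expect_true(fit$converged)
  }
})

test_that("path selection keeps null targets empty and finds strong signals", {
  # pure-noise target: no group should be selected in >= 90% of seeds
  n_sel <- sapply(1:100, function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(10 * 51), 10, 51, dimnames = list(paste0("g", 1:10), NULL))
    sm <- series_matrix(m, seq_len(51))
    sel <- select_lambda(build_lagged_design(sm, "g1", 1))
    sum(sel$fit$selected)
  })
  expect_gte(mean(n_sel == 0), 0.9)

  # one strong regressor: selected in >= 95% of seeds
  hit <- sapply(1:100, function(seed) {
    set.seed(seed)
    driver <- rnorm(101)
    target <- c(0, 0.9 * driver[-101]) + rnorm(101, 0, 0.4)
    m <- rbind(tgt = target, drv = driver,
               matrix(rnorm(8 * 101), 8, 101,
                      dimnames = list(paste0("g", 1:8), NULL)))
    sm <- series_matrix(m, seq_len(101))
    sel <- select_lambda(build_lagged_design(sm, "tgt", 1))
    sel$fit$selected[["drv"]]
  })
  expect_gte(mean(hit), 0.95)

  # the path starts empty at lambda_max
  set.seed(1)
  m <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(paste0("g", 1:6), NULL))
  sel <- select_lambda(build_lagged_design(series_matrix(m, 1:40), "g1", 1))
  expect_equal(sel$path$n_selected[1], 0)
  expect_error(select_lambda(build_lagged_design(series_matrix(m, 1:40),
                                                 "g1", 1), nlambda = 5),
               "at least 30")
})

test_that("single-network inference respects the directional contract", {
  # 2-gene system with strong 1 -> 2 coupling
  hits <- sapply(1:20, function(seed) {
    set.seed(seed)
    x1 <- rnorm(101)
    x2 <- c(0, 0.9 * x1[-101]) + rnorm(101, 0, 0.3)
    sm <- series_matrix(rbind(g1 = x1, g2 = x2), seq_len(101))
    B <- infer_network_single(sm, p = 1)
    c(B["g1", "g2"], B["g2", "g1"])
  })
  expect_gte(mean(hits[1, ] == 1), 0.9)
  expect_gte(mean(hits[2, ] == 0), 0.9)

  set.seed(30)
  m <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("g", 1:5), NULL))
  sm <- series_matrix(m, seq_len(30))
  B <- infer_network_single(sm, p = 2)
  expect_equal(dim(B), c(5, 5))
  expect_false(any(is.na(B)))
  edges <- network_edges(B)
  expect_true(all(edges$source != edges$target))
  expect_error(infer_network_single(
    series_matrix(rbind(m, k = rep(1, 30)), seq_len(30)), p = 1),
    "constant gene")
})

test_that("network inference is equivariant under gene relabelling", {
  sim <- generate_arx_tensor(12, 3, 2, order = 1, innovation_sd = 0.2,
                             grid_or_length = 60, seed = 77)
  z <- zscore_genes(sim$latent)
  B <- infer_network_single(z, p = 1)
  perm <- sample(12)
  zp <- series_matrix(unclass(z)[perm, ], series_hours(z))
  Bp <- infer_network_single(zp, p = 1)
  expect_equal(unclass(Bp), unclass(B)[perm, perm], ignore_attr = TRUE)
})
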