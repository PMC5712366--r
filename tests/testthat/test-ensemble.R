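test_that("replicate resampling is deterministic and sample-level", {
  set.seed(1)
  a <- array(rnorm(4 * 12 * 3), dim = c(4, 12, 3),
             dimnames = list(paste0("g", 1:4), NULL, NULL))
  ten <- expr_tensor(a, design_grid())
  expect_identical(resample_series(ten, seed = 3),
                   resample_series(ten, seed = 3))
  # identical replicates: output independent of the seed
  ten_id <- toy_tensor(matrix(rnorm(24), 2))
  expect_equal(unclass(resample_series(ten_id, seed = 1)),
               unclass(resample_series(ten_id, seed = 999)),
               ignore_attr = TRUE)
})

test_that("replicate draws are uniform per time point", {
  ten <- toy_tensor(matrix(rnorm(12), 1))
  draws <- vapply(seq_len(10000), function(s) {
    attr(resample_series(ten, seed = s), "selection")
  }, integer(12))
  for (t in 1:12) {
    tab <- tabulate(draws[t, ], 3)
    expect_gt(chisq.test(tab)$p.value, 0.001)
  }
})

test_that("noise-free ensembles are idempotent", {
  sim <- generate_arx_tensor(12, 3, 2, order = 1, innovation_sd = 0.2,
                             grid_or_length = 50, n_reps = 3,
                             obs_noise_sd = 0, seed = 5)
  nets <- ensemble_infer(sim$tensor, p = 1, M = 4, base_seed = 7)
  expect_length(nets, 4)
  for (m in 2:4) expect_equal(unclass(nets[[m]]), unclass(nets[[1]]),
                              ignore_attr = TRUE)
  B <- confidence_matrix(nets)
  expect_true(all(B$B %in% c(0L, 4L)))
  # edges called at any threshold below M equal the single-trial network
  called <- call_edges(B, threshold = 2)
  single <- network_edges(nets[[1]])
  expect_equal(called$edges[c("source", "target")],
               single[order(single$source, single$target), ],
               ignore_attr = TRUE)
})

test_that("a one-trial ensemble reduces to a single resample + inference", {
  sim <- generate_arx_tensor(8, 2, 2, order = 1, innovation_sd = 0.2,
                             grid_or_length = 40, n_reps = 3,
                             obs_noise_sd = 0.05, seed = 6)
  nets <- ensemble_infer(sim$tensor, p = 1, M = 1, base_seed = 20)
  direct <- infer_network_single(
    suppressWarnings(zscore_genes(resample_series(sim$tensor, seed = 21))),
    p = 1)
  expect_equal(unclass(nets[[1]]), unclass(direct), ignore_attr = TRUE)
  # and the whole ensemble is deterministic given its base seed
  nets2 <- ensemble_infer(sim$tensor, p = 1, M = 1, base_seed = 20)
  expect_equal(unclass(nets[[1]]), unclass(nets2[[1]]), ignore_attr = TRUE)
})

test_that("confidence counting tallies edges elementwise", {
  ids <- c("a", "b", "c")
  mk <- function(edges) {
    m <- matrix(0L, 3, 3, dimnames = list(ids, ids))
    for (e in edges) m[e[1], e[2]] <- 1L
    m
  }
  n1 <- mk(list(c("a", "b"), c("b", "c")))
  n2 <- mk(list(c("a", "b")))
  n3 <- mk(list(c("c", "a"), c("a", "b")))
  B <- confidence_matrix(list(n1, n2, n3))
  expect_equal(B$M, 3)
  expect_equal(B$B["a", "b"], 3)
  expect_equal(B$B["b", "c"], 1)
  expect_equal(B$B["c", "a"], 1)
  expect_equal(sum(B$B), 5)
  # disjoint single edges
  B2 <- confidence_matrix(list(mk(list(c("a", "b"))), mk(list(c("b", "c")))))
  expect_equal(B2$B["a", "b"], 1)
  expect_equal(B2$B["b", "c"], 1)
  expect_error(confidence_matrix(list(n1, n2[1:2, 1:2])), "shape")
  expect_error(confidence_matrix(list()), "empty")
})

test_that("edge calling uses strict exceedance and nests over thresholds", {
  ids <- c("a", "b", "c")
  m <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  m["a", "b"] <- 20L; m["a", "c"] <- 21L; m["b", "c"] <- 30L
  m["c", "c"] <- 25L  # self-loop
  B <- structure(list(B = m, M = 30L), class = "confidence_matrix")
  net <- call_edges(B, threshold = 20)
  expect_equal(nrow(net$edges), 2)           # 20 is NOT called
  expect_false(any(net$edges$source == "a" & net$edges$target == "b"))
  expect_equal(net$self_loops$gene, "c")     # reported separately
  expect_false("c" %in% net$edges$source & any(net$edges$target == "c" &
                                                 net$edges$source == "c"))
  # threshold = M can never be exceeded
  expect_equal(nrow(call_edges(B, threshold = 30)$edges), 0)
  # nesting
  e15 <- call_edges(B, threshold = 15)$edges
  e25 <- call_edges(B, threshold = 25)$edges
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e25) %in% key(e15)))
  expect_error(call_edges(B, threshold = 31), "threshold")
})

test_that("network summaries count parents, children and hubs", {
  ids <- paste0("g", 1:60)
  m <- matrix(0L, 60, 60, dimnames = list(ids, ids))
  B <- structure(list(B = m, M = 30L), class = "confidence_matrix")
  s0 <- network_summary(call_edges(B, 20))
  expect_equal(s0$n_edges, 0)
  expect_equal(s0$n_parents, 0)
  expect_equal(s0$n_children, 0)

  # star graph 1 -> {2..6}
  m2 <- m; m2["g1", paste0("g", 2:6)] <- 30L
  B2 <- structure(list(B = m2, M = 30L), class = "confidence_matrix")
  s2 <- network_summary(call_edges(B2, 20), hub_min_children = 50)
  expect_equal(s2$n_edges, 5)
  expect_equal(s2$n_parents, 1)
  expect_equal(s2$n_children, 5)
  expect_length(s2$hubs, 0)

  # out-degree 51 makes a hub at the default threshold
  m3 <- m; m3["g1", paste0("g", 2:52)] <- 30L
  B3 <- structure(list(B = m3, M = 30L), class = "confidence_matrix")
  s3 <- network_summary(call_edges(B3, 20), hub_min_children = 50)
  expect_equal(names(s3$hubs), "g1")
  expect_equal(unname(s3$hubs), 51L)
})

test_that("degree distributions flag scale-free-like tails", {
  # regular out-degrees: slope undefined, single bin
  reg <- degree_distribution_fit(rep(4L, 10))
  expect_length(reg$degrees, 1)
  expect_true(is.na(reg$slope))
  expect_true(is.na(degree_distribution_fit(integer(0))$slope))

  skip_if_not_installed("igraph")
  set.seed(12)
  g <- igraph::sample_pa(1000, m = 2, directed = TRUE)
  # preferential attachment: in-degree of sample_pa is heavy-tailed
  deg <- igraph::degree(g, mode = "in")
  fit <- degree_distribution_fit(as.integer(deg))
  expect_lt(fit$slope, 0)
})

test_that("confidence filtering does not hurt precision under replicate noise", {
  sim <- generate_arx_tensor(15, 3, 3, order = 1, innovation_sd = 0.1,
                             grid_or_length = 80, n_reps = 3,
                             obs_noise_sd = 0.05, seed = 9)
  nets <- ensemble_infer(sim$tensor, p = 1, M = 10, base_seed = 40)
  B <- confidence_matrix(nets)
  called <- call_edges(B, threshold = 7)
  ens <- edge_recovery(called, sim$truth$adjacency)
  single <- edge_recovery(nets[[1]], sim$truth$adjacency)
  expect_gte(ens$precision, single$precision)
})
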