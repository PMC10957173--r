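test_that("kernel weights follow the normalized squared-exponential formula", {
  cfg <- kernel_config(length_scale_mm = 5)

  # symmetric target: equal weights
  w <- kernel_weights(rbind(c(5, 0, 0)), rbind(c(0, 0, 0), c(10, 0, 0)), cfg)
  expect_equal(as.vector(w), c(0.5, 0.5), tolerance = 1e-12)

  # direct evaluation of the kernel formula
  w2 <- kernel_weights(rbind(c(2.5, 0, 0)), rbind(c(0, 0, 0), c(10, 0, 0)), cfg)
  raw <- exp(-c(2.5^2, 7.5^2) / (2 * 25))      # (exp(-0.125), exp(-1.125))
  expect_equal(as.vector(w2), raw / sum(raw), tolerance = 1e-12)
  expect_equal(as.vector(w2), c(0.731, 0.269), tolerance = 1e-3)

  # rows sum to one
  set.seed(1)
  W <- suppressWarnings(
    kernel_weights(matrix(rnorm(30, sd = 20), ncol = 3),
                   matrix(rnorm(15, sd = 20), ncol = 3), cfg))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)

  # far target falls back to one-hot on the nearest source, with warning
  expect_warning(
    wf <- kernel_weights(rbind(c(5000, 0, 0)),
                         rbind(c(0, 0, 0), c(10, 0, 0)), cfg),
    "nearest")
  expect_equal(as.vector(wf), c(0, 1))

  expect_error(kernel_weights(rbind(c(NA, 0, 0)), rbind(c(0, 0, 0)), cfg),
               "finite")
})

test_that("interpolation matches a brute-force double-loop oracle", {
  set.seed(7)
  n <- 80; g <- 5
  coords <- matrix(runif(n * 3, 0, 40), ncol = 3)
  expr <- matrix(rnorm(g * n), nrow = g,
                 dimnames = list(paste0("g", 1:g), NULL))
  s <- expression_sample_set(coords, rep("d1", n), paste0("g", 1:g), expr)
  gm <- make_volume(array(1, dim = c(8, 8, 8)), voxel_mm = 5)
  cfg <- kernel_config(length_scale_mm = 5, chunk_size = 37)
  atlas <- interpolate_expression(s, gm, cfg)

  # naive two-loop predictor
  arr_idx <- arrayInd(atlas$voxel_index, gm$dims) - 1
  oracle <- matrix(NA_real_, g, length(atlas$voxel_index))
  for (v in seq_along(atlas$voxel_index)) {
    t_mm <- arr_idx[v, ] * 5
    k <- numeric(n)
    for (j in seq_len(n)) {
      k[j] <- exp(-sum((t_mm - coords[j, ])^2) / (2 * 25))
    }
    w <- k / sum(k)
    for (gg in seq_len(g)) oracle[gg, v] <- sum(w * expr[gg, ])
  }
  expect_lt(max(abs(atlas$values - oracle)), 1e-10)

  # output independent of chunk size
  atlas2 <- interpolate_expression(s, gm, kernel_config(5, chunk_size = 512))
  expect_equal(atlas$values, atlas2$values, tolerance = 1e-14)

  # permuting sample order leaves the atlas unchanged
  perm <- sample(n)
  sp <- expression_sample_set(coords[perm, ], rep("d1", n),
                              paste0("g", 1:g), expr[, perm])
  atlas3 <- interpolate_expression(sp, gm, cfg)
  expect_lt(max(abs(atlas$values - atlas3$values)), 1e-12)
})

test_that("interpolation limits: convexity, constants, single sample, l -> 0 and l -> Inf", {
  set.seed(8)
  n <- 40
  coords <- matrix(runif(n * 3, 0, 30), ncol = 3)
  expr <- matrix(rnorm(2 * n), nrow = 2,
                 dimnames = list(c("a", "b"), NULL))
  expr["b", ] <- 3.14                     # constant gene
  s <- expression_sample_set(coords, rep("d", n), c("a", "b"), expr)
  gm <- make_volume(array(1, dim = c(6, 6, 6)), voxel_mm = 6)

  atlas <- interpolate_expression(s, gm, kernel_config(8))
  # convexity bound per gene
  expect_true(all(atlas$values["a", ] >= min(expr["a", ]) - 1e-12))
  expect_true(all(atlas$values["a", ] <= max(expr["a", ]) + 1e-12))
  # constant gene preserved exactly
  expect_lt(max(abs(atlas$values["b", ] - 3.14)), 1e-12)

  # l -> Inf: every prediction converges to the unweighted sample mean
  big <- interpolate_expression(s, gm, kernel_config(1e6 * 60))
  expect_lt(max(abs(big$values["a", ] - mean(expr["a", ]))), 1e-6)

  # l -> 0+: prediction at a location strictly nearest one sample hits it
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  gap <- min(d)
  tiny <- kernel_config(max(1e-3 * gap, 1e-8))
  w <- suppressWarnings(kernel_weights(coords[1, , drop = FALSE], coords, tiny))
  expect_equal(which.max(w), 1L)
  expect_equal(max(w), 1, tolerance = 1e-9)

  # single sample: atlas equals that sample's profile everywhere
  s1 <- structure(list(coords = coords[1, , drop = FALSE], donor = "d",
                       genes = c("a", "b"),
                       expr = expr[, 1, drop = FALSE], meta = NULL),
                  class = "expression_sample_set")
  a1 <- interpolate_expression(s1, gm, kernel_config(8))
  expect_true(all(a1$values == expr[, 1]))
})

test_that("leave-one-out bandwidth selection penalizes over-smoothing", {
  # smooth 1-gene linear field along x, noiseless
  set.seed(9)
  n <- 30
  coords <- cbind(seq(0, 100, length.out = n), 0, 0)
  expr <- matrix(coords[, 1] * 0.3, nrow = 1, dimnames = list("g1", NULL))
  s <- expression_sample_set(coords, rep("d", n), "g1", expr)
  res <- loo_cv_bandwidth(s, c(0.1, 5, 500))
  tab <- res$table
  expect_gt(tab$mse[tab$length_scale_mm == 500],
            tab$mse[tab$length_scale_mm == 5])
  expect_false(res$best == 500)

  # one candidate is returned as best
  expect_equal(loo_cv_bandwidth(s, 7)$best, 7)

  # identical expression: zero error everywhere, smallest candidate wins
  expr0 <- matrix(2, nrow = 1, dimnames = list("g1", NULL))[, rep(1, n), drop = FALSE]
  s0 <- expression_sample_set(coords, rep("d", n), "g1", expr0)
  r0 <- loo_cv_bandwidth(s0, c(10, 2, 30))
  expect_equal(max(r0$table$mse), 0, tolerance = 1e-20)
  expect_equal(r0$best, 2)
})
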