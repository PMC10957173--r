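test_that("regional means average valid voxels per label", {
  vals <- array(0, dim = c(3, 1, 1))
  vals[, 1, 1] <- c(1, 3, 7)
  lab <- array(0L, dim = c(3, 1, 1))
  lab[, 1, 1] <- c(1L, 1L, 2L)
  lv <- label_volume(make_volume(lab),
                     data.frame(label = 1:2, name = c("r1", "r2")))
  m <- regional_means(make_volume(vals), lv)
  expect_equal(unname(m), c(2, 7))

  # constant map: every region mean equals the constant
  mc <- regional_means(make_volume(array(4, dim = c(3, 1, 1))), lv)
  expect_equal(unname(mc), c(4, 4))

  # fully excluded region comes back missing (and is logged)
  ex <- array(FALSE, dim = c(3, 1, 1)); ex[3, 1, 1] <- TRUE
  expect_message(m2 <- regional_means(make_volume(vals), lv, exclude = ex),
                 "missing")
  expect_true(is.na(m2["r2"]))
  expect_equal(unname(m2["r1"]), 2)

  # grid mismatch instructs to resample
  other <- make_volume(array(0, dim = c(4, 1, 1)))
  expect_error(regional_means(other, lv), "resample")
})

test_that("spearman matches the rank-difference formula and an average-rank oracle", {
  expect_equal(spearman(1:4, 1:4)$rho, 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)

  # tie-free: 1 - 6*sum(d^2)/(n(n^2-1))
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    d <- rank(x) - rank(y)
    expect_equal(spearman(x, y)$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }

  # with ties: brute-force average-rank oracle
  for (i in 1:200) {
    n <- sample(5:25, 1)
    x <- sample(5, n, replace = TRUE); y <- sample(5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
  }

  # rank invariance under strictly increasing transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman(x, y)$rho, spearman(x, exp(y))$rho, tolerance = 1e-12)

  # exact p at small n: matches full permutation enumeration
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  obs <- abs(spearman(x5, y5)$rho)
  perms <- all_permutations(5)
  rhos <- apply(perms, 1, function(pp) oracle_spearman_rho(x5, y5[pp]))
  expect_equal(spearman(x5, y5)$p, mean(abs(rhos) >= obs - 1e-12),
               tolerance = 1e-12)

  expect_error(spearman(1:3, c(2, 2, 2)), "constant")
  expect_error(spearman(1:3, 1:4), "length")
  expect_error(spearman(c(1, 2), c(3, 4)), "at least 3")
})

test_that("BH step-up matches its definition and dominates Bonferroni", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(r1$q, rep(0.04, 4))
  expect_true(all(r1$rejected))

  r2 <- bh_fdr(c(0.005, 0.04, 0.2), alpha = 0.05)
  expect_equal(r2$q, c(0.015, 0.06, 0.2))
  expect_equal(sum(r2$rejected), 1L)

  r3 <- bh_fdr(rep(1, 5))
  expect_true(all(r3$q == 1) && !any(r3$rejected))

  set.seed(11)
  for (i in 1:300) {
    m <- sample(2:40, 1)
    p <- runif(m)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    r <- bh_fdr(p, alpha = 0.05)
    expect_equal(r$q, oracle_bh(p), tolerance = 1e-12)
    # q >= p elementwise; monotone in p
    expect_true(all(r$q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(r$q[o]) >= -1e-15))
    # BH rejections contain Bonferroni rejections
    bonf <- p <= 0.05 / m
    expect_true(all(r$rejected[bonf]))
    # permutation stability
    pe <- sample(m)
    expect_equal(bh_fdr(p[pe])$q, r$q[pe], tolerance = 1e-15)
  }

  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("association matrix joins regions, shapes 6 x 13, finds planted drivers", {
  cfg <- phantom_config(seed = 21)
  p <- generate_phantom(cfg)
  atrophy <- lapply(cfg$atrophy_specs[1:4], function(sp) {
    generate_atrophy(p, sp)
  })
  names(atrophy) <- vapply(cfg$atrophy_specs[1:4], `[[`, "", "name")
  cells_reg <- regional_matrix(p$cell_fields, p$labels)
  atro_reg <- regional_matrix(atrophy, p$labels)
  am <- association_matrix(cells_reg, atro_reg)
  expect_equal(dim(am$rho), c(6, 4))
  expect_equal(am$n_regions, 118)
  expect_true(all(am$rho >= -1 & am$rho <= 1))
  expect_true(all(am$q >= am$p - 1e-15))

  # planted condA on astrocytes: most negative rho in its column, via an
  # independently recomputed column
  oracle_col <- vapply(colnames(cells_reg), function(ct) {
    oracle_spearman_rho(cells_reg[, ct], atro_reg[, "condA"])
  }, numeric(1))
  expect_equal(am$rho[, "condA"], oracle_col, tolerance = 1e-12)
  expect_equal(names(which.min(am$rho[, "condA"])), "astrocyte")
  expect_lt(am$rho["astrocyte", "condA"], 0)

  # a condition equal to a cell column correlates perfectly
  am2 <- association_matrix(cells_reg,
                            cbind(atro_reg, self = cells_reg[, "neuron"]))
  expect_equal(unname(am2$rho["neuron", "self"]), 1)

  # region reordering leaves the result unchanged
  perm <- sample(nrow(cells_reg))
  am3 <- association_matrix(cells_reg[perm, ], atro_reg)
  expect_equal(am3$rho, am$rho, tolerance = 1e-14)

  # too few shared regions
  expect_error(association_matrix(cells_reg[1:2, ], atro_reg[1:2, ]),
               "3 shared")
})
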