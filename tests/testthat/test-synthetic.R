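test_that("phantom generation is deterministic and structurally valid", {
  cfg <- tiny_phantom_config(seed = 5)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$gm_density$values, p2$gm_density$values)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$labels$grid$values, p2$labels$grid$values)

  # truth sums to 1 on every GM voxel
  expect_lt(max(abs(colSums(p1$truth) - 1)), 1e-9)
  # cell fields nonnegative and within [0, 1]
  for (f in p1$cell_fields) {
    expect_true(all(f$values >= 0 & f$values <= 1))
  }
  # labels partition GM into n_regions nonempty regions
  labs <- p1$labels$grid$values[p1$gm_index]
  expect_equal(sort(unique(labs)), seq_len(cfg$n_regions))
  expect_true(all(tabulate(labs, cfg$n_regions) > 0))
  # background is 0 outside GM
  expect_true(all(p1$labels$grid$values[-p1$gm_index] == 0))
})

test_that("a single bump peaks at its center voxel", {
  cfg <- phantom_config(dims = c(16, 16, 16), cell_types = "neuron",
                        bumps_per_type = 1, n_samples = 10, n_regions = 4,
                        markers_per_type = 2,
                        atrophy_specs = list(), seed = 2)
  p <- generate_phantom(cfg)
  f <- p$cell_fields$neuron$values
  peak <- which.max(f)
  expect_equal(f[peak], 1)            # min-max normalized
  expect_true(peak %in% p$gm_index)
})

test_that("default-config regions are all nonempty with the requested count", {
  p <- generate_phantom(phantom_config(seed = 9))
  labs <- p$labels$grid$values[p$gm_index]
  counts <- tabulate(labs, 118)
  expect_equal(length(counts), 118)
  expect_true(all(counts > 0))
})

test_that("bulk sampling follows the noiseless mixture formula", {
  cfg <- tiny_phantom_config(seed = 3, expr_noise_sd = 0)
  p <- generate_phantom(cfg)
  s <- sample_bulk_expression(p, config = cfg)
  truth <- attr(s, "truth")
  mk <- synthetic_markers(cfg)
  # value = signal * truth + background, exactly
  for (i in seq_len(nrow(mk))) {
    expect_equal(unname(s$expr[i, ]),
                 unname(cfg$signature_signal * truth[mk$cell_type[i], ]),
                 tolerance = 1e-12)
  }
  # within a cell type all markers identical across samples; rank 1
  for (ct in cfg$cell_types) {
    sub <- s$expr[mk$gene[mk$cell_type == ct], , drop = FALSE]
    expect_equal(qr(sub)$rank, 1L)
  }
  # determinism of coordinates
  s2 <- sample_bulk_expression(p, config = cfg)
  expect_identical(s$coords, s2$coords)
  expect_identical(s$expr, s2$expr)

  # oversampling is rejected
  cfg_big <- tiny_phantom_config(seed = 3)
  cfg_big$n_samples <- length(p$gm_index) + 1L
  expect_error(sample_bulk_expression(p, config = cfg_big), "exceeds")
})

test_that("planted atrophy is a monotone negative function of its driver", {
  cfg <- tiny_phantom_config(seed = 4)
  p <- generate_phantom(cfg)
  # noiseless single driver: perfect negative rank correlation
  sp <- list(name = "pure", drivers = "astrocyte", beta = 10, noise_sd = 0)
  t_map <- generate_atrophy(p, sp)
  tv <- t_map$values[p$gm_index]
  expect_equal(oracle_spearman_rho(tv, p$truth["astrocyte", ]), -1,
               tolerance = 1e-12)

  # zero slope, zero noise: constant t0
  sp0 <- list(name = "flat", drivers = "astrocyte", beta = 0, noise_sd = 0,
              t0 = 1.5)
  expect_true(all(generate_atrophy(p, sp0)$values[p$gm_index] == 1.5))

  # default condA spec: strongly negative regional association
  spA <- list(name = "condA", drivers = "astrocyte", beta = 8, noise_sd = 1)
  tA <- generate_atrophy(p, spA, seed = 99)
  reg_t <- regional_means(tA, p$labels)
  reg_a <- regional_means(p$cell_fields$astrocyte, p$labels)
  expect_lt(oracle_spearman_rho(reg_t, reg_a), -0.7)

  expect_error(generate_atrophy(p, list(name = "x", drivers = "nope",
                                        beta = 1, noise_sd = 0)), "unknown")
})

test_that("fixtures round-trip through the on-disk dialect", {
  cfg <- tiny_phantom_config(seed = 6)
  p <- generate_phantom(cfg)
  s <- sample_bulk_expression(p, config = cfg)
  at <- list(condA = generate_atrophy(p, cfg$atrophy_specs[[1]]))
  out <- tempfile("fixture_")
  manifest <- write_fixture(p, s, at, out)
  expect_true(file.exists(manifest))
  man <- jsonlite::read_json(manifest)
  # manifest lists every file with a checksum
  expect_true(all(vapply(man$files, function(f) nchar(f$md5) == 32, logical(1))))
  for (f in man$files) expect_true(file.exists(file.path(out, f$path)))

  # expression re-ingests with shape preserved
  s2 <- suppressMessages(
    read_expression_bundle(file.path(out, "expression"), zscore_donor = FALSE))
  expect_equal(ncol(s2$expr), ncol(s$expr))
  expect_equal(sort(s2$genes), sort(s$genes))

  # truth volumes reload within 1e-6
  r <- read_volume(file.path(out, "truth_astrocyte.nii.gz"))
  expect_lt(max(abs(r$values - p$cell_fields$astrocyte$values)), 1e-6)
})
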