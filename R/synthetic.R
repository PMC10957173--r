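#' Configuration for synthetic brain phantoms
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the statistical structure of the real analysis at desk scale: a 32^3 grid
#' of 2 mm voxels, six cell types whose density fields are smooth Gaussian
#' bump mixtures on a gray-matter shell, 200 sparse bulk samples whose
#' marker expression is a proportion-weighted signature mixture plus
#' Gaussian noise, a 118-region parcellation, and atrophy t-maps planted as
#' negative-slope functions of driver cell densities plus noise (so lower t
#' means more atrophy, matching the convention for real t-maps).
#'
#' @param dims Grid dimensions (default `c(32, 32, 32)`).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 2).
#' @param cell_types Cell-type labels (default the six canonical types).
#' @param bumps_per_type Gaussian bumps per cell field (default 4).
#' @param bump_sigma_mm Bump width in mm (default 8).
#' @param signature_signal Marker signature amplitude s: a marker of cell
#'   type c at location v has mean `s * truth_c(v) + b` (default 4).
#' @param signature_background Background offset b (default 0).
#' @param expr_noise_sd Gaussian noise sd on expression (default 0.5).
#' @param n_samples Number of bulk samples drawn on GM (default 200).
#' @param n_regions Parcellation regions (default 118).
#' @param markers_per_type Synthetic markers per cell type (default 15).
#' @param atrophy_specs List of atrophy condition specs, each a list with
#'   `name`, `drivers` (cell types), `beta` (positive slope magnitude),
#'   `noise_sd`, optional `t0`. Default: [default_atrophy_specs()].
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(32L, 32L, 32L), voxel_size_mm = 2,
                           cell_types = braincellmap::cell_types(),
                           bumps_per_type = 4L, bump_sigma_mm = 8,
                           signature_signal = 4, signature_background = 0,
                           expr_noise_sd = 0.5, n_samples = 200L,
                           n_regions = 118L, markers_per_type = 15L,
                           atrophy_specs = default_atrophy_specs(cell_types),
                           seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 4), voxel_size_mm > 0,
            length(cell_types) >= 1L, bumps_per_type >= 1L,
            expr_noise_sd >= 0, n_samples >= 2L, n_regions >= 1L,
            markers_per_type >= 1L)
  for (sp in atrophy_specs) {
    stopifnot(is.character(sp$name), all(is.finite(sp$beta)),
              sp$noise_sd >= 0)
  }
  structure(
    list(dims = as.integer(dims), voxel_size_mm = voxel_size_mm,
         cell_types = cell_types, bumps_per_type = as.integer(bumps_per_type),
         bump_sigma_mm = bump_sigma_mm,
         signature_signal = signature_signal,
         signature_background = signature_background,
         expr_noise_sd = expr_noise_sd, n_samples = as.integer(n_samples),
         n_regions = as.integer(n_regions),
         markers_per_type = as.integer(markers_per_type),
         atrophy_specs = atrophy_specs, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Default planted atrophy conditions
#'
#' Thirteen synthetic conditions (condA..condM), each driven by one cell
#' type (cycling through the supplied types), with slope 8 and unit noise,
#' mirroring the 6 x 13 cell-by-condition design of the real analysis. The
#' first condition, `condA`, is driven by astrocytes.
#'
#' @param cell_types Cell-type labels to cycle through.
#' @param n_conditions Number of conditions (default 13).
#' @param beta Slope magnitude (default 8).
#' @param noise_sd Additive noise sd on the t-map (default 1).
#' @return List of atrophy specs for [phantom_config()].
#' @export
default_atrophy_specs <- function(cell_types = braincellmap::cell_types(),
                                  n_conditions = 13L, beta = 8, noise_sd = 1) {
  # condA deliberately starts at astrocyte so the canonical planted test
  # case (astrocyte-driven condA) holds under defaults.
  start <- match("astrocyte", cell_types)
  if (is.na(start)) start <- 1L
  ord <- c(seq(start, length(cell_types)), seq_len(start - 1L))
  drivers <- rep(cell_types[ord], length.out = n_conditions)
  lapply(seq_len(n_conditions), function(i) {
    list(name = paste0("cond", LETTERS[i]), drivers = drivers[i],
         beta = beta, noise_sd = noise_sd, t0 = 0)
  })
}

# World coordinates of every voxel of a dims/affine grid, as an N x 3 matrix
# in array (column-major) order.
grid_world_coords <- function(dims, affine) {
  ix <- rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3])
  iy <- rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3])
  iz <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  h <- cbind(ix, iy, iz, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Generate a synthetic brain phantom
#'
#' Builds, reproducibly from `config$seed`:
#' * a GM density field: a smooth ellipsoidal shell mask (emulating
#'   cortex-like geometry) times a smooth positive field in (0, 1];
#' * one density field per cell type: a min-max-normalized sum of isotropic
#'   Gaussian bumps centred at random GM voxels;
#' * ground-truth proportions: the cell fields normalized to sum to 1 at
#'   every GM voxel;
#' * a parcellation: seeded k-means on GM voxel world coordinates into
#'   `n_regions` contiguous regions (re-drawn up to 10 times if a region
#'   comes out empty).
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom`: fields `gm_density`, `cell_fields`
#'   (named list of [volume_grid]s), `labels` (a [label_volume]), `truth`
#'   (cell-type x GM-voxel matrix), `gm_index` (linear indices of GM
#'   voxels), `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dims
  vs <- config$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (d - 1) / 2  # grid centred on the world origin

  with_seed(config$seed, {
    w <- grid_world_coords(d, affine)
    center <- c(0, 0, 0)
    radii <- vs * d * 0.42
    r2 <- ((w[, 1] - center[1]) / radii[1])^2 +
      ((w[, 2] - center[2]) / radii[2])^2 +
      ((w[, 3] - center[3]) / radii[3])^2
    r <- sqrt(r2)
    shell <- r >= 0.45 & r <= 1           # ellipsoidal shell, cortex-like
    # smooth positive modulation field on top of the shell
    rough <- volume_grid(array(stats::runif(prod(d), 0.5, 1), dim = d), affine,
                         space = "phantom")
    modul <- smooth_volume(rough, fwhm_mm = 6 * vs)$values
    gm_vals <- array(0, dim = d)
    gm_vals[shell] <- modul[shell]
    gm_vals <- pmin(pmax(gm_vals, 0), 1)
    gm <- volume_grid(array(gm_vals, dim = d), affine, space = "phantom")
    gm_index <- which(gm$values > 0)
    if (length(gm_index) < config$n_regions) {
      stopf("generate_phantom: %d GM voxels < n_regions = %d",
            length(gm_index), config$n_regions)
    }

    # Cell density fields: sums of Gaussian bumps at random GM centers.
    gm_w <- w[gm_index, , drop = FALSE]
    cell_fields <- list()
    truth <- matrix(0, nrow = length(config$cell_types), ncol = length(gm_index),
                    dimnames = list(config$cell_types, NULL))
    for (ct in config$cell_types) {
      centers <- gm_w[sample.int(nrow(gm_w), config$bumps_per_type), ,
                      drop = FALSE]
      f <- numeric(nrow(w))
      for (b in seq_len(nrow(centers))) {
        d2 <- (w[, 1] - centers[b, 1])^2 + (w[, 2] - centers[b, 2])^2 +
          (w[, 3] - centers[b, 3])^2
        f <- f + exp(-d2 / (2 * config$bump_sigma_mm^2))
      }
      fg <- f[gm_index]
      rng <- range(fg)
      fg <- if (diff(rng) > 0) (fg - rng[1]) / diff(rng) else rep(0.5, length(fg))
      vals <- array(0, dim = d)
      vals[gm_index] <- fg
      cell_fields[[ct]] <- volume_grid(vals, affine, space = "phantom")
      truth[ct, ] <- fg
    }
    csum <- colSums(truth)
    zero <- csum <= 0
    if (any(zero)) {          # degenerate voxels get a flat profile
      truth[, zero] <- 1 / nrow(truth)
      csum[zero] <- 1
    }
    truth <- sweep(truth, 2, csum, "/")

    # Parcellation: k-means on GM world coordinates.
    labels_arr <- NULL
    for (attempt in 1:10) {
      km <- suppressWarnings(stats::kmeans(gm_w, centers = config$n_regions,
                                           iter.max = 50, nstart = 1))
      if (all(tabulate(km$cluster, config$n_regions) > 0)) {
        labels_arr <- array(0, dim = d)
        labels_arr[gm_index] <- km$cluster
        break
      }
    }
    if (is.null(labels_arr)) {
      stopf("generate_phantom: empty parcellation region after 10 draws")
    }
    lookup <- data.frame(label = seq_len(config$n_regions),
                         name = sprintf("region_%03d", seq_len(config$n_regions)))
    labels <- label_volume(volume_grid(labels_arr, affine, space = "phantom"),
                           lookup)

    structure(
      list(gm_density = gm, cell_fields = cell_fields, labels = labels,
           truth = truth, gm_index = gm_index, config = config),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %s grid, %d GM voxels, %d cell types, %d regions>\n",
              paste(x$config$dims, collapse = "x"), length(x$gm_index),
              length(x$cell_fields), x$config$n_regions))
  invisible(x)
}

#' Synthetic marker table for a phantom
#'
#' Gene symbols `<CELLTYPE>_MK01..MKk` for each phantom cell type.
#'
#' @param config A [phantom_config()].
#' @return A `marker_table` with `markers_per_type` rows per cell type.
#' @export
synthetic_markers <- function(config = phantom_config()) {
  rows <- do.call(rbind, lapply(config$cell_types, function(ct) {
    data.frame(gene = sprintf("%s_MK%02d", toupper(ct),
                              seq_len(config$markers_per_type)),
               cell_type = ct, rank = seq_len(config$markers_per_type))
  }))
  marker_table(rows, required_types = config$cell_types)
}

#' Draw bulk expression samples from a phantom
#'
#' Draws `n_samples` GM voxel locations without replacement and simulates
#' bulk marker expression as a signature-weighted mixture: the expression of
#' a marker of cell type c at voxel v is
#' `signature_signal * truth_c(v) + signature_background + N(0, expr_noise_sd)`.
#'
#' @param phantom A [generate_phantom()] result.
#' @param markers A `marker_table` covering all phantom cell types (default
#'   [synthetic_markers()]).
#' @param config The [phantom_config()] (defaults to the phantom's own).
#' @param seed Seed for sampling and noise (defaults to `config$seed + 1`).
#' @return An [expression_sample_set] with attribute `voxel_index` (linear
#'   indices of the sampled voxels) and `truth` (cell-type x sample truth).
#' @export
sample_bulk_expression <- function(phantom, markers = NULL, config = NULL,
                                   seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  config <- config %||% phantom$config
  markers <- markers %||% synthetic_markers(config)
  seed <- seed %||% (config$seed + 1L)
  lost <- setdiff(config$cell_types, unique(markers$cell_type))
  if (length(lost)) {
    stopf("sample_bulk_expression: markers missing for cell type(s): %s",
          paste(lost, collapse = ", "))
  }
  if (config$n_samples > length(phantom$gm_index)) {
    stopf("sample_bulk_expression: n_samples = %d exceeds GM voxel count %d",
          config$n_samples, length(phantom$gm_index))
  }
  with_seed(seed, {
    pick <- sort(sample.int(length(phantom$gm_index), config$n_samples))
    vox <- phantom$gm_index[pick]
    truth_s <- phantom$truth[, pick, drop = FALSE]
    d <- phantom$gm_density$dims
    arr_idx <- arrayInd(vox, d) - 1L
    coords <- voxel_to_world(phantom$gm_density, arr_idx)
    expr <- matrix(NA_real_, nrow = nrow(markers), ncol = config$n_samples)
    for (i in seq_len(nrow(markers))) {
      mu <- config$signature_signal * truth_s[markers$cell_type[i], ] +
        config$signature_background
      noise <- if (config$expr_noise_sd > 0) {
        stats::rnorm(config$n_samples, 0, config$expr_noise_sd)
      } else 0
      expr[i, ] <- mu + noise
    }
    out <- expression_sample_set(coords = coords,
                                 donor = rep("synthetic01", config$n_samples),
                                 genes = markers$gene, expr = expr)
    attr(out, "voxel_index") <- vox
    attr(out, "truth") <- truth_s
    out
  })
}

#' Plant an atrophy t-map on a phantom
#'
#' Builds `t(v) = t0 - sum_drivers beta * truth_c(v) + N(0, noise_sd)` on GM
#' voxels (non-GM voxels are `NA`), so larger driver density means lower t,
#' i.e. more atrophy — the sign convention of real atrophy t-maps.
#'
#' @param phantom A [generate_phantom()] result.
#' @param spec One atrophy spec (see [phantom_config()]).
#' @param seed Noise seed (default `config$seed + 101 + spec index hash`).
#' @return A [volume_grid] with the spec stored in attribute `spec`.
#' @export
generate_atrophy <- function(phantom, spec, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  unknown <- setdiff(spec$drivers, rownames(phantom$truth))
  if (length(unknown)) {
    stopf("generate_atrophy: unknown driver cell type(s): %s",
          paste(unknown, collapse = ", "))
  }
  seed <- seed %||% (phantom$config$seed + 101L +
                       sum(utf8ToInt(spec$name)) %% 1000L)
  t0 <- spec$t0 %||% 0
  with_seed(seed, {
    tv <- rep(t0, length(phantom$gm_index))
    for (ct in spec$drivers) {
      tv <- tv - spec$beta * phantom$truth[ct, ]
    }
    if (spec$noise_sd > 0) {
      tv <- tv + stats::rnorm(length(tv), 0, spec$noise_sd)
    }
    vals <- array(NA_real_, dim = phantom$gm_density$dims)
    vals[phantom$gm_index] <- tv
    out <- volume_grid(vals, phantom$gm_density$affine, space = "phantom")
    attr(out, "spec") <- spec
    out
  })
}

#' Write a phantom fixture to disk
#'
#' Serializes a phantom, its samples and atrophy maps into the on-disk
#' layout the real-data loaders expect: NIfTI volumes (GM density, cell
#' fields, labels, atrophy t-maps), one donor folder in the microarray CSV
#' dialect ingestible by [read_expression_bundle()], the marker table and
#' region lookup as TSV, and a JSON manifest listing every file with an md5
#' checksum plus the generating seeds.
#'
#' @param phantom A [generate_phantom()] result.
#' @param samples An [expression_sample_set] from [sample_bulk_expression()].
#' @param atrophy Named list of atrophy [volume_grid]s.
#' @param out_dir Output directory (created if needed).
#' @param markers Marker table to write (default [synthetic_markers()]).
#' @return Path of the JSON manifest, invisibly.
#' @export
write_fixture <- function(phantom, samples, atrophy, out_dir,
                          markers = synthetic_markers(phantom$config)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wv <- function(grid, name) {
    p <- file.path(out_dir, name)
    write_volume(grid, p)
    files <<- c(files, p)
    p
  }
  wv(phantom$gm_density, "gm_density.nii.gz")
  for (ct in names(phantom$cell_fields)) {
    wv(phantom$cell_fields[[ct]], sprintf("truth_%s.nii.gz", ct))
  }
  wv(phantom$labels$grid, "labels.nii.gz")
  for (nm in names(atrophy)) {
    wv(atrophy[[nm]], sprintf("atrophy_%s.nii.gz", nm))
  }

  donor_dir <- file.path(out_dir, "expression", "donor_synthetic01")
  dir.create(donor_dir, recursive = TRUE, showWarnings = FALSE)
  annot <- data.frame(sample_id = seq_len(nrow(samples$coords)),
                      mni_x = samples$coords[, 1],
                      mni_y = samples$coords[, 2],
                      mni_z = samples$coords[, 3])
  f_annot <- file.path(donor_dir, "SampleAnnot.csv")
  utils::write.csv(annot, f_annot, row.names = FALSE)
  probes <- data.frame(probe_id = seq_along(samples$genes),
                       gene_symbol = samples$genes)
  f_probes <- file.path(donor_dir, "Probes.csv")
  utils::write.csv(probes, f_probes, row.names = FALSE)
  f_expr <- file.path(donor_dir, "MicroarrayExpression.csv")
  utils::write.table(cbind(probes$probe_id, samples$expr), f_expr,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  files <- c(files, f_annot, f_probes, f_expr)

  f_mark <- file.path(out_dir, "markers.tsv")
  utils::write.table(as.data.frame(markers), f_mark, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f_look <- file.path(out_dir, "region_lookup.tsv")
  utils::write.table(phantom$labels$lookup, f_look, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f_mark, f_look)

  manifest <- list(
    seed = phantom$config$seed,
    n_samples = ncol(samples$expr),
    n_genes = nrow(samples$expr),
    cell_types = phantom$config$cell_types,
    n_regions = phantom$config$n_regions,
    atrophy_specs = lapply(names(atrophy), function(nm) {
      attr(atrophy[[nm]], "spec") %||% list(name = nm)
    }),
    files = lapply(files, function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}
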