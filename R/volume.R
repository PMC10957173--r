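#' Voxel grids with world-space affines
#'
#' A `volume_grid` is the package's container for any 3-D scalar field living
#' in a stereotaxic space: atrophy t-score maps, gray-matter (GM) probability,
#' cell-type proportion maps, and integer parcellation labels. It couples a
#' numeric 3-D array with the 4x4 affine that maps 0-based voxel indices to
#' world millimetre coordinates (MNI convention for real data). Missing
#' values are carried as `NA`, never silently zero-filled.
#'
#' @param values Numeric 3-D array of voxel values (`NA` = missing).
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @param space Free-text space tag, e.g. `"MNI152"`.
#' @return An object of class `volume_grid` with fields `values`, `affine`,
#'   `dims` and `space`.
#' @export
volume_grid <- function(values, affine = diag(4), space = "unknown") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("volume_grid: 'values' must be a 3-D array")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine))) {
    stopf("volume_grid: 'affine' must be a finite 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps * 64) {
    stopf("volume_grid: affine is singular")
  }
  structure(
    list(
      values = values,
      affine = unname(affine),
      dims = dim(values),
      space = space
    ),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid %s, space '%s', voxel sizes %s mm, %d non-missing voxels>\n",
    paste(x$dims, collapse = "x"), x$space,
    paste(signif(voxel_sizes(x), 4), collapse = "x"),
    sum(!is.na(x$values))
  ))
  invisible(x)
}

#' Per-axis voxel edge lengths in mm
#'
#' Column norms of the affine's 3x3 block; used for smoothing-kernel
#' conversion between mm and voxel units.
#'
#' @param grid A `volume_grid`.
#' @return Numeric length-3 vector of mm per voxel along each axis.
#' @export
voxel_sizes <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Read a NIfTI-1 volume
#'
#' Thin wrapper around [RNifti::readNifti()] that returns a [volume_grid].
#' The format's scl_slope/scl_inter scaling is applied (that is RNifti's
#' behaviour); no other rescaling occurs.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param space Space tag to attach (default `"MNI152"`).
#' @return A [volume_grid].
#' @export
read_volume <- function(path, space = "MNI152") {
  if (!file.exists(path)) stopf("read_volume: file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) {
    stopf("read_volume: expected 3-D volume, got %d-D in %s",
          length(dim(a)), path)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff)) < .Machine$double.eps * 64) {
    stopf("read_volume: singular affine in %s", path)
  }
  storage.mode(a) <- "double"
  volume_grid(a, aff, space = space)
}

#' Write a volume as NIfTI-1
#'
#' @param grid A [volume_grid].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Parcellation label volumes
#'
#' Couples an integer-labelled [volume_grid] with a label -> region-name
#' lookup. Label 0 is reserved for background / non-GM tissue; every nonzero
#' label present in the grid must appear in the lookup.
#'
#' @param grid A [volume_grid] whose values are integer region labels.
#' @param lookup Named character vector or data.frame with columns
#'   `label`, `name`.
#' @return An object of class `label_volume` with fields `grid` and `lookup`
#'   (data.frame `label`, `name`).
#' @export
label_volume <- function(grid, lookup) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.data.frame(lookup)) {
    lk <- data.frame(label = as.integer(lookup$label),
                     name = as.character(lookup$name))
  } else {
    lk <- data.frame(label = as.integer(names(lookup)),
                     name = as.character(lookup))
  }
  if (anyDuplicated(lk$label)) stopf("label_volume: duplicated labels in lookup")
  present <- setdiff(unique(as.integer(grid$values[!is.na(grid$values)])), 0L)
  missing <- setdiff(present, lk$label)
  if (length(missing)) {
    stopf("label_volume: labels in volume missing from lookup: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  structure(list(grid = grid, lookup = lk), class = "label_volume")
}

#' Read a label -> region-name lookup table
#'
#' Expects a TSV with header columns `label` and `name`.
#'
#' @param path Path to the TSV file.
#' @return data.frame with integer `label` and character `name`.
#' @export
read_region_lookup <- function(path) {
  if (!file.exists(path)) stopf("read_region_lookup: file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(df))) {
    stopf("read_region_lookup: need columns 'label' and 'name' in %s", path)
  }
  data.frame(label = as.integer(df$label), name = as.character(df$name))
}

#' Convert world mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds half away from zero to the nearest
#' 0-based integer index. Out-of-bounds coordinates are flagged, not clamped.
#'
#' @param grid A [volume_grid].
#' @param coords n x 3 numeric matrix of world mm coordinates.
#' @return List with `index` (n x 3 integer, 0-based) and `oob`
#'   (logical n, `TRUE` where the index falls outside the grid).
#' @export
world_to_voxel <- function(grid, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  inv <- solve(grid$affine)
  h <- cbind(coords, 1) %*% t(inv)
  idx <- round_half_away(h[, 1:3, drop = FALSE])
  storage.mode(idx) <- "integer"
  oob <- idx[, 1] < 0L | idx[, 1] >= grid$dims[1] |
    idx[, 2] < 0L | idx[, 2] >= grid$dims[2] |
    idx[, 3] < 0L | idx[, 3] >= grid$dims[3]
  list(index = idx, oob = oob)
}

#' Convert voxel indices to world mm coordinates
#'
#' @param grid A [volume_grid].
#' @param index n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 numeric matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  h <- cbind(index, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

# Continuous (unrounded) voxel coordinates of world points.
world_to_voxel_cont <- function(grid, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  inv <- solve(grid$affine)
  h <- cbind(coords, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' Resample a volume onto another grid
#'
#' Samples `src` at the world positions of `target`'s voxel centers, by
#' trilinear interpolation for continuous maps or nearest-neighbour for
#' label volumes. Target voxels falling outside the source grid are set to
#' `NA`.
#'
#' @param src Source [volume_grid] (or [label_volume] with
#'   `mode = "nearest"`).
#' @param target [volume_grid] defining the output geometry.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A [volume_grid] on `target`'s grid.
#' @export
resample_to_grid <- function(src, target, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  is_label <- inherits(src, "label_volume")
  if (is_label) {
    if (mode == "trilinear") {
      stopf("resample_to_grid: trilinear interpolation is invalid for label volumes; use mode = 'nearest'")
    }
    src <- src$grid
  }
  stopifnot(inherits(src, "volume_grid"), inherits(target, "volume_grid"))
  d <- target$dims
  ix <- rep(seq_len(d[1]) - 1L, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  world <- voxel_to_world(target, cbind(ix, iy, iz))
  cont <- world_to_voxel_cont(src, world)
  vals <- sample_volume_at(src$values, cont, mode)
  out <- array(vals, dim = d)
  volume_grid(out, target$affine, space = target$space)
}

# Sample a 3-D array at continuous 0-based voxel coordinates.
sample_volume_at <- function(arr, cont, mode) {
  d <- dim(arr)
  n <- nrow(cont)
  if (mode == "nearest") {
    idx <- round_half_away(cont)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
      idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
      idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- rep(NA_real_, n)
    if (any(ok)) {
      lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
      out[ok] <- arr[lin]
    }
    return(out)
  }
  # trilinear
  ok <- cont[, 1] >= 0 & cont[, 1] <= d[1] - 1 &
    cont[, 2] >= 0 & cont[, 2] <= d[2] - 1 &
    cont[, 3] >= 0 & cont[, 3] <= d[3] - 1
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  p <- cont[ok, , drop = FALSE]
  f0 <- pmin(floor(p), rep(d - 1L, each = nrow(p)) - 1)
  f0 <- pmax(f0, 0)
  fr <- p - f0
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- 1 + (f0[, 1] + dx) + d[1] * ((f0[, 2] + dy) + d[2] * (f0[, 3] + dz))
    acc <- acc + w * arr[lin]
  }
  out[ok] <- acc
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian smoothing with full-width-half-maximum `fwhm_mm`,
#' converted to per-axis voxel sigmas via the affine's scale lengths
#' (sigma = fwhm / (2*sqrt(2*ln 2))). Smoothing is mask-normalized:
#' `smooth(value * mask) / smooth(mask)` with `mask` defaulting to the
#' non-missing voxels, so fields constant on the mask stay constant and
#' edges do not bleed toward zero.
#'
#' @param vol A [volume_grid].
#' @param fwhm_mm Positive FWHM in millimetres.
#' @param mask Optional [volume_grid] (nonzero = inside) restricting the
#'   smoothing support.
#' @return Smoothed [volume_grid]; voxels outside the mask are `NA`.
#' @export
smooth_volume <- function(vol, fwhm_mm, mask = NULL) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0) {
    stopf("smooth_volume: fwhm_mm must be a positive number")
  }
  R <- vol$affine[1:3, 1:3]
  sizes <- sqrt(colSums(R^2))
  # shear check: off-diagonal structure after removing scales
  ortho <- t(R / rep(sizes, each = 3)) %*% (R / rep(sizes, each = 3))
  if (max(abs(ortho - diag(3))) > 1e-6) {
    warnf("smooth_volume: affine has shear/oblique axes; using per-axis scale lengths")
  }
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / sizes

  m <- if (is.null(mask)) {
    array(as.numeric(!is.na(vol$values)), dim = vol$dims)
  } else {
    array(as.numeric(!is.na(mask$values) & mask$values != 0), dim = vol$dims)
  }
  v <- vol$values
  v[is.na(v)] <- 0
  vm <- v * m
  num <- gauss_blur3(vm, sigma_vox)
  den <- gauss_blur3(m, sigma_vox)
  out <- num / den
  out[den <= .Machine$double.eps | m == 0] <- NA_real_
  volume_grid(out, vol$affine, space = vol$space)
}

# Separable 3-D Gaussian blur by per-axis 1-D convolution (zero-padded
# edges; callers renormalize with a blurred mask).
gauss_blur3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# 1-D convolution along one axis of a 3-D array, zero padding.
conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  res <- array(out, dim = da)
  aperm(res, order(perm))
}
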