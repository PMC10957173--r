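#' Z-score atlas genes across voxels
#'
#' Centers each gene row to mean 0 and scales it to unit standard deviation
#' across voxels — the standardization the eigengene decomposition assumes,
#' which also makes the scores invariant to per-gene affine rescaling.
#' Zero-variance rows become all-zero and are flagged.
#'
#' @param atlas An `expression_atlas` (or plain genes x voxels matrix).
#' @return Same shape as the input; attribute `zero_variance` holds the
#'   flagged gene names (on the matrix for matrix input, on `$values` for
#'   atlas input).
#' @export
zscore_genes <- function(atlas) {
  is_atlas <- inherits(atlas, "expression_atlas")
  m <- if (is_atlas) atlas$values else as.matrix(atlas)
  if (ncol(m) < 2L) stopf("zscore_genes: need at least 2 voxels")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flat <- sd == 0 | !is.finite(sd)
  sd[flat] <- 1
  z <- (m - mu) / sd
  z[flat, ] <- 0
  flagged <- rownames(m)[flat] %||% which(flat)
  attr(z, "zero_variance") <- flagged
  if (any(flat)) {
    msgf("zscore_genes: %d zero-variance gene row(s) set to zero", sum(flat))
  }
  if (is_atlas) {
    atlas$values <- z
    atlas
  } else {
    z
  }
}

#' Eigengene surrogate score for one cell type
#'
#' Extracts the marker x voxel submatrix of the z-scored atlas and takes
#' its best rank-1 factorization (first singular triplet). The voxel-side
#' factor, scaled by the singular value, is the cell type's surrogate
#' abundance score. Its sign is aligned so that the score correlates
#' positively with the mean marker profile; an exactly zero correlation
#' keeps the algebraic sign with a warning.
#'
#' @param atlas_z Z-scored `expression_atlas` or genes x voxels matrix
#'   (from [zscore_genes()]).
#' @param markers A `marker_table`.
#' @param cell_type The cell type to score.
#' @return Numeric score vector over voxels (arbitrary affine scale).
#' @export
surrogate_scores <- function(atlas_z, markers, cell_type) {
  m <- if (inherits(atlas_z, "expression_atlas")) atlas_z$values else
    as.matrix(atlas_z)
  genes <- rownames(m)
  if (is.null(genes)) stopf("surrogate_scores: input needs gene rownames")
  mk <- markers$gene[markers$cell_type == cell_type]
  mk <- mk[tolower(mk) %in% tolower(genes)]
  if (!length(mk)) {
    stopf("surrogate_scores: no matched markers for cell type '%s'", cell_type)
  }
  sub <- m[match(tolower(mk), tolower(genes)), , drop = FALSE]
  if (ncol(sub) < 2L) stopf("surrogate_scores: need at least 2 voxels")
  sv <- svd(sub, nu = 1, nv = 1)
  score <- sv$d[1] * sv$v[, 1]
  profile <- colMeans(sub)
  al <- sum(score * profile)  # sign of the covariance suffices
  if (al < 0) {
    score <- -score
  } else if (al == 0) {
    warnf("surrogate_scores: sign of '%s' score undetermined; keeping algebraic sign",
          cell_type)
  }
  score
}

#' Min-max rescale a score vector to [0, 1] over the GM mask
#'
#' Eigengene scores carry an arbitrary affine scale and sign; the
#' proportion normalization needs nonnegative values, so scores are
#' min-max rescaled over GM voxels before sum-normalization. Rank order is
#' preserved.
#'
#' @param scores Numeric vector.
#' @param mask Optional logical vector (same length) restricting the
#'   min/max computation; values outside stay rescaled by the mask's range.
#' @return Vector in `[0, 1]` on the mask.
#' @export
rescale_unit <- function(scores, mask = NULL) {
  v <- if (is.null(mask)) scores else scores[mask]
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stopf("rescale_unit: constant score vector carries no usable signal")
  }
  (scores - rng[1]) / diff(rng)
}

#' Normalize unit scores into GM-scaled proportion maps
#'
#' At every voxel the six unit scores are divided by their sum and the
#' result is multiplied by the GM density, so the six proportions are
#' nonnegative and sum exactly to the GM density at each voxel. Voxels
#' whose scores sum to zero are set to zero for all types and flagged
#' (they are excluded from downstream regional means rather than imputed).
#'
#' @param unit_scores cell-type x voxel matrix of nonnegative scores (rows
#'   named by cell type).
#' @param gm_density Numeric vector of GM density per voxel (same voxel
#'   order).
#' @return List: `proportions` (same shape as `unit_scores`),
#'   `zero_sum` (logical per-voxel flag).
#' @export
normalize_proportions <- function(unit_scores, gm_density) {
  unit_scores <- as.matrix(unit_scores)
  if (any(unit_scores < 0, na.rm = TRUE)) {
    stopf("normalize_proportions: negative scores; run rescale_unit first")
  }
  if (length(gm_density) != ncol(unit_scores)) {
    stopf("normalize_proportions: gm_density length != number of voxels")
  }
  s <- colSums(unit_scores)
  zero <- s == 0
  s[zero] <- 1
  p <- sweep(unit_scores, 2, s, "/")
  p <- sweep(p, 2, gm_density, "*")
  p[, zero] <- 0
  if (any(zero)) {
    msgf("normalize_proportions: %d voxel(s) with all-zero scores set to 0",
         sum(zero))
  }
  list(proportions = p, zero_sum = zero)
}

#' Estimate cell-type proportion maps from an expression atlas
#'
#' Runs the full deconvolution stage: z-scores the atlas genes, computes
#' one eigengene surrogate score per cell type, min-max rescales each to
#' `[0, 1]` over GM, and normalizes across cell types against the GM
#' density. Returns per-voxel maps satisfying the conservation property
#' sum over cell types = GM density at every GM voxel.
#'
#' @param atlas An `expression_atlas` from [interpolate_expression()].
#' @param markers A `marker_table` (already matched to the atlas genes or
#'   matchable case-insensitively).
#' @param gm The GM density [volume_grid] on the atlas grid.
#' @param types Cell types to estimate (default: those in `markers`).
#' @return Object of class `cell_proportion_maps`: `cell_types`, `maps`
#'   (named list of [volume_grid]s, zero outside GM, `NA` never), `scores`
#'   (raw surrogate scores matrix), `proportions` (cell x GM-voxel),
#'   `voxel_index`, `zero_sum`, `gm_density`.
#' @export
estimate_cell_maps <- function(atlas, markers, gm,
                               types = unique(markers$cell_type)) {
  stopifnot(inherits(atlas, "expression_atlas"), inherits(gm, "volume_grid"))
  az <- zscore_genes(atlas)
  nvox <- length(atlas$voxel_index)
  gm_vals <- gm$values[atlas$voxel_index]
  scores <- matrix(NA_real_, nrow = length(types), ncol = nvox,
                   dimnames = list(types, NULL))
  unit <- scores
  for (ct in types) {
    sc <- surrogate_scores(az, markers, ct)
    scores[ct, ] <- sc
    unit[ct, ] <- rescale_unit(sc)
  }
  np <- normalize_proportions(unit, gm_vals)
  maps <- lapply(types, function(ct) {
    vals <- array(0, dim = atlas$grid$dims)
    vals[atlas$voxel_index] <- np$proportions[ct, ]
    volume_grid(vals, atlas$grid$affine, space = atlas$grid$space)
  })
  names(maps) <- types
  structure(
    list(cell_types = types, maps = maps, scores = scores,
         proportions = np$proportions, voxel_index = atlas$voxel_index,
         zero_sum = np$zero_sum, gm_density = gm_vals),
    class = "cell_proportion_maps"
  )
}

#' @export
print.cell_proportion_maps <- function(x, ...) {
  cat(sprintf("<cell_proportion_maps: %d types x %d GM voxels>\n",
              length(x$cell_types), length(x$voxel_index)))
  invisible(x)
}
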