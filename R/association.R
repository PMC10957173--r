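#' Regional means of a voxel map over a parcellation
#'
#' Arithmetic mean of the non-excluded, non-missing voxel values within
#' each nonzero label. Regions with no valid voxels come back as `NA` and
#' are reported.
#'
#' @param map A [volume_grid] on the same grid as `labels` (resample
#'   first otherwise).
#' @param labels A [label_volume].
#' @param exclude Optional logical array/vector (same length as the map)
#'   marking voxels to drop (e.g. zero-sum deconvolution voxels).
#' @return Named numeric vector, one entry per lookup region (names =
#'   region names, in lookup order).
#' @export
regional_means <- function(map, labels, exclude = NULL) {
  stopifnot(inherits(map, "volume_grid"), inherits(labels, "label_volume"))
  if (!all(map$dims == labels$grid$dims) ||
      max(abs(map$affine - labels$grid$affine)) > 1e-6) {
    stopf("regional_means: map and labels are on different grids; resample_to_grid first")
  }
  lab <- as.integer(labels$grid$values)
  val <- as.numeric(map$values)
  keep <- !is.na(val) & !is.na(lab) & lab != 0L
  if (!is.null(exclude)) keep <- keep & !as.logical(exclude)
  lk <- labels$lookup
  sums <- rep(0, nrow(lk)); cnts <- rep(0L, nrow(lk))
  idx <- match(lab[keep], lk$label)
  agg_s <- tapply(val[keep], idx, sum)
  agg_n <- tapply(val[keep], idx, length)
  sums[as.integer(names(agg_s))] <- agg_s
  cnts[as.integer(names(agg_n))] <- agg_n
  out <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
  names(out) <- lk$name
  if (any(cnts == 0)) {
    msgf("regional_means: %d region(s) with no valid voxels reported as missing",
         sum(cnts == 0))
  }
  out
}

#' Build a region x feature matrix from several maps
#'
#' Applies [regional_means()] to each map and binds the results as columns.
#' Regions missing in any feature are dropped listwise (and logged) so all
#' features share one region set.
#'
#' @param maps Named list of [volume_grid]s.
#' @param labels A [label_volume].
#' @param exclude Optional per-voxel exclusion passed to every map.
#' @return Matrix regions x features with region names as rownames.
#' @export
regional_matrix <- function(maps, labels, exclude = NULL) {
  cols <- lapply(maps, regional_means, labels = labels, exclude = exclude)
  m <- do.call(cbind, cols)
  colnames(m) <- names(maps)
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    msgf("regional_matrix: dropping %d region(s) with missing features: %s",
         sum(bad), paste(utils::head(rownames(m)[bad], 5), collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of average-ranked values (average ranks
#' for ties). The p-value comes from [stats::cor.test()]: exact null
#' enumeration for n <= 10 tie-free vectors, the t-approximation with
#' n - 2 degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, non-constant.
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("spearman: length mismatch")
  n <- length(x)
  if (n < 3L) stopf("spearman: need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("spearman: non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("spearman: constant input vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 10))
  )
  list(rho = unname(rho), p = max(ct$p.value, .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Adjusts a family of p-values with the BH step-up rule
#' `q_(i) = min_{j >= i} p_(j) * m / j` (capped at 1) and rejects at
#' `q <= alpha`. The whole cell x condition family is corrected jointly.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param alpha Significance threshold in (0, 1) (default 0.05).
#' @return List with `q` (adjusted values, input order) and `rejected`
#'   (logical).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stopf("bh_fdr: p-values must lie in (0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) stopf("bh_fdr: alpha must lie in (0, 1)")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, rejected = q <= alpha)
}

#' Cell-by-condition Spearman association matrix with FDR
#'
#' Inner-joins the two regional matrices on region names, computes the
#' Spearman rho and p for every (cell type, condition) pair, and adjusts
#' all pairs jointly with [bh_fdr()]. Row order follows the cell matrix's
#' columns, column order the condition matrix's columns.
#'
#' @param cells Regions x cell-types matrix (rownames = region names).
#' @param atrophy Regions x conditions matrix (rownames = region names).
#' @param alpha FDR threshold (default 0.05).
#' @return Object of class `association_result`: matrices `rho`, `p`, `q`,
#'   logical `rejected`, plus `alpha` and `n_regions`.
#' @export
association_matrix <- function(cells, atrophy, alpha = 0.05) {
  cells <- as.matrix(cells); atrophy <- as.matrix(atrophy)
  common <- intersect(rownames(cells), rownames(atrophy))
  dropped <- setdiff(union(rownames(cells), rownames(atrophy)), common)
  if (length(dropped)) {
    msgf("association_matrix: dropping %d region(s) absent from one side",
         length(dropped))
  }
  if (length(common) < 3L) {
    stopf("association_matrix: fewer than 3 shared regions")
  }
  A <- cells[common, , drop = FALSE]
  B <- atrophy[common, , drop = FALSE]
  C <- ncol(A); D <- ncol(B)
  rho <- p <- matrix(NA_real_, C, D,
                     dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(C)) {
    for (j in seq_len(D)) {
      s <- spearman(A[, i], B[, j])
      rho[i, j] <- s$rho
      p[i, j] <- s$p
    }
  }
  fdr <- bh_fdr(as.vector(p), alpha = alpha)
  q <- matrix(fdr$q, C, D, dimnames = dimnames(p))
  rej <- matrix(fdr$rejected, C, D, dimnames = dimnames(p))
  structure(
    list(rho = rho, p = p, q = q, rejected = rej, alpha = alpha,
         n_regions = length(common)),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result: %d cell types x %d conditions over %d regions; %d/%d significant at q <= %g>\n",
    nrow(x$rho), ncol(x$rho), x$n_regions, sum(x$rejected),
    length(x$rejected), x$alpha))
  invisible(x)
}
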