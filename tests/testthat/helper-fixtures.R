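# Shared fixtures: everything is generated in code at test time.

# A small phantom configuration for fast unit tests (defaults stay 32^3).
tiny_phantom_config <- function(seed = 1L, ...) {
  phantom_config(dims = c(16L, 16L, 16L), n_samples = 60L, n_regions = 12L,
                 seed = seed, ...)
}

# Identity-affine volume with given values.
make_volume <- function(values, voxel_mm = 1, origin = c(0, 0, 0)) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- origin
  volume_grid(values, aff)
}

# Write a minimal two-donor microarray bundle (CSV dialect) and return its
# directory: 2 donors x 3 samples x 4 probes over 2 genes.
write_tiny_bundle <- function(dir = tempfile("bundle_")) {
  for (d in c("donorA", "donorB")) {
    dd <- file.path(dir, d)
    dir.create(dd, recursive = TRUE)
    off <- if (d == "donorA") 0 else 50
    annot <- data.frame(sample_id = 1:3,
                        mni_x = c(0, 10, 20) + off,
                        mni_y = c(0, 0, 0), mni_z = c(0, 5, 10))
    write.csv(annot, file.path(dd, "SampleAnnot.csv"), row.names = FALSE)
    probes <- data.frame(probe_id = 101:104,
                         gene_symbol = c("GENE1", "GENE1", "GENE2", "GENE2"))
    write.csv(probes, file.path(dd, "Probes.csv"), row.names = FALSE)
    expr <- cbind(101:104, matrix(c(1, 2, 3,
                                    10, 20, 30,
                                    5, 5, 6,
                                    1, 1, 1) + off / 10, nrow = 4,
                                  byrow = TRUE))
    write.table(expr, file.path(dd, "MicroarrayExpression.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  dir
}

# Independent average-rank computation (does not use base rank()).
avg_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Independent Pearson correlation of average ranks.
oracle_spearman_rho <- function(x, y) {
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Direct BH step-up computation.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force UPGMA: recompute unweighted mean cross-pair distances from the
# original matrix at every step; ties to the smallest (a, b) node-id pair.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  k <- nrow(d)
  clusters <- lapply(seq_len(k), function(i) i)  # leaf sets
  ids <- seq_len(k)
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0),
                       id = integer(0))
  for (step in seq_len(k - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        if (is.null(best) || h < best$h ||
            (h == best$h && (a < best$a || (a == best$a && b < best$b)))) {
          best <- list(h = h, a = a, b = b, i = i, j = j)
        }
      }
    }
    new_id <- k + step
    merges <- rbind(merges, data.frame(a = best$a, b = best$b,
                                       height = best$h, id = new_id))
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    keep <- setdiff(seq_along(clusters), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged))
    ids <- c(ids[keep], new_id)
  }
  merges
}

# All n! permutations of 1:n, enumerated recursively.
all_permutations <- function(n) {
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      out <- rbind(out, cbind(v[i], perm_rec(v[-i])))
    }
    out
  }
  perm_rec(seq_len(n))
}
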