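#' Pairwise Euclidean distances between matrix rows
#'
#' @param rows k x m numeric matrix, k >= 2, finite.
#' @return k x k symmetric distance matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stopf("pairwise_euclidean: need at least 2 rows")
  if (!all(is.finite(rows))) stopf("pairwise_euclidean: non-finite input")
  d <- as.matrix(stats::dist(rows, method = "euclidean"))
  dimnames(d) <- list(rownames(rows), rownames(rows))
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters
#' with the smallest average inter-cluster distance, where the distance
#' between clusters is the unweighted mean over all cross pairs of leaves.
#' Ties are broken deterministically toward the smallest (node-a, node-b)
#' index pair. Average linkage admits no inversions, so merge heights are
#' nondecreasing.
#'
#' @param dist k x k symmetric distance matrix (or `dist` object).
#' @param labels Leaf labels (default rownames of `dist`, else L1..Lk).
#' @return Object of class `dendrogram_ul`: `labels`; `merges`, a
#'   data.frame with columns `a`, `b` (node ids: 1..k are leaves, k+1..
#'   are internal in merge order, `a < b`), `height`, `id` (the new node);
#'   `order`, a display leaf ordering.
#' @export
average_linkage <- function(dist, labels = NULL) {
  d <- as.matrix(dist)
  k <- nrow(d)
  if (k < 2L) stopf("average_linkage: need at least 2 leaves")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stopf("average_linkage: distance matrix not symmetric")
  }
  labels <- labels %||% rownames(d) %||% paste0("L", seq_len(k))

  # active cluster bookkeeping: node id, member leaf count
  id <- seq_len(k)          # node ids of active clusters
  size <- rep(1L, k)
  D <- d
  diag(D) <- Inf
  merges <- data.frame(a = integer(k - 1L), b = integer(k - 1L),
                       height = numeric(k - 1L), id = integer(k - 1L))
  members <- as.list(seq_len(k))  # leaf sets, for display ordering
  node_members <- vector("list", 2L * k - 1L)
  node_members[seq_len(k)] <- as.list(seq_len(k))

  for (step in seq_len(k - 1L)) {
    # locate the minimal entry; ties -> smallest (node-a, node-b) id pair
    best <- NULL
    m <- length(id)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- min(id[i], id[j]); b <- max(id[i], id[j])
        cand <- c(D[i, j], a, b)
        if (is.null(best) ||
            cand[1] < best[1] - 0 ||
            (cand[1] == best[1] && (cand[2] < best[2] ||
                                    (cand[2] == best[2] && cand[3] < best[3])))) {
          best <- cand
          bi <- i; bj <- j
        }
      }
    }
    new_id <- k + step
    h <- D[bi, bj]
    merges$a[step] <- min(id[bi], id[bj])
    merges$b[step] <- max(id[bi], id[bj])
    merges$height[step] <- h
    merges$id[step] <- new_id
    node_members[[new_id]] <- c(node_members[[id[bi]]], node_members[[id[bj]]])

    # Lance-Williams average update: weighted by member counts, which
    # reproduces the unweighted mean over all cross leaf pairs.
    ni <- size[bi]; nj <- size[bj]
    newD <- (ni * D[bi, ] + nj * D[bj, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], Inf))
    id <- c(id[keep], new_id)
    size <- c(size[keep], ni + nj)
  }

  # display order: tighter (lower) child first, leaves in subtree order
  order_of <- function(node) {
    if (node <= k) return(node)
    step <- node - k
    a <- merges$a[step]; b <- merges$b[step]
    ha <- if (a <= k) -Inf else merges$height[a - k]
    hb <- if (b <= k) -Inf else merges$height[b - k]
    if (hb < ha) c(order_of(b), order_of(a)) else c(order_of(a), order_of(b))
  }
  structure(
    list(labels = labels, merges = merges, order = order_of(2L * k - 1L)),
    class = "dendrogram_ul"
  )
}

#' @export
print.dendrogram_ul <- function(x, ...) {
  cat(sprintf("<dendrogram_ul: %d leaves, heights %s>\n",
              length(x$labels),
              paste(signif(x$merges$height, 4), collapse = ", ")))
  invisible(x)
}

#' Serialize a dendrogram as Newick text
#'
#' Uses the midpoint-split ultrametric convention: a node merged at height
#' h sits at elevation h/2, so the cophenetic distance between two leaves
#' equals their merge height; branch lengths are elevation differences
#' (never negative, since average linkage has no inversions).
#'
#' @param dendro A `dendrogram_ul`.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string, terminated by `;`.
#' @export
to_newick <- function(dendro, digits = 10) {
  k <- length(dendro$labels)
  elev <- function(node) {
    if (node <= k) 0 else dendro$merges$height[node - k] / 2
  }
  build <- function(node, parent_elev) {
    bl <- max(parent_elev - elev(node), 0)
    if (node <= k) {
      sprintf("%s:%s", dendro$labels[node], format(bl, digits = digits))
    } else {
      step <- node - k
      sprintf("(%s,%s):%s",
              build(dendro$merges$a[step], elev(node)),
              build(dendro$merges$b[step], elev(node)),
              format(bl, digits = digits))
    }
  }
  root <- 2L * k - 1L
  step <- root - k
  sprintf("(%s,%s);",
          build(dendro$merges$a[step], elev(root)),
          build(dendro$merges$b[step], elev(root)))
}

#' Cluster both axes of an association matrix
#'
#' Clusters cell types (rows) on their condition-profile vectors and
#' conditions (columns) on their cell-profile vectors, each with
#' average-linkage on Euclidean distances — the two dendrograms of the
#' standard clustered heatmap of the cell-by-condition correlation matrix.
#'
#' @param assoc An `association_result` (or plain rho matrix).
#' @param use_abs Cluster on absolute correlation values instead of raw
#'   (default `FALSE`).
#' @return List with `rows` and `cols` (`dendrogram_ul` objects).
#' @export
cluster_association <- function(assoc, use_abs = FALSE) {
  rho <- if (inherits(assoc, "association_result")) assoc$rho else
    as.matrix(assoc)
  if (use_abs) rho <- abs(rho)
  # an axis with a single element has nothing to cluster
  list(
    rows = if (nrow(rho) >= 2) {
      average_linkage(pairwise_euclidean(rho), labels = rownames(rho))
    },
    cols = if (ncol(rho) >= 2) {
      average_linkage(pairwise_euclidean(t(rho)), labels = colnames(rho))
    }
  )
}
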