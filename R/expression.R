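#' Spatially annotated expression sample sets
#'
#' Container for sparse bulk tissue samples: world-space coordinates, donor
#' labels, gene symbols and a genes x samples expression matrix (probes
#' already collapsed to one row per gene).
#'
#' @param coords n x 3 numeric matrix of world mm coordinates.
#' @param donor Character vector of donor identifiers, length n.
#' @param genes Character vector of g gene symbols.
#' @param expr g x n numeric matrix, no missing entries.
#' @param meta Optional data.frame of per-sample annotations.
#' @return An object of class `expression_sample_set`.
#' @export
expression_sample_set <- function(coords, donor, genes, expr, meta = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  expr <- as.matrix(expr)
  n <- nrow(coords)
  g <- length(genes)
  if (n < 2L) stopf("expression_sample_set: need at least 2 samples")
  if (g < 1L) stopf("expression_sample_set: need at least 1 gene")
  if (length(donor) != n) stopf("expression_sample_set: donor length != n")
  if (!all(dim(expr) == c(g, n))) {
    stopf("expression_sample_set: expr must be %d x %d", g, n)
  }
  if (anyNA(expr)) stopf("expression_sample_set: expr contains missing values")
  key <- paste(donor, coords[, 1], coords[, 2], coords[, 3], sep = "|")
  if (anyDuplicated(key)) {
    stopf("expression_sample_set: duplicated (donor, coordinate) pair")
  }
  rownames(expr) <- genes
  structure(
    list(coords = coords, donor = as.character(donor),
         genes = as.character(genes), expr = expr, meta = meta),
    class = "expression_sample_set"
  )
}

#' @export
print.expression_sample_set <- function(x, ...) {
  cat(sprintf("<expression_sample_set: %d genes x %d samples, %d donor(s)>\n",
              length(x$genes), nrow(x$coords), length(unique(x$donor))))
  invisible(x)
}

#' Read a multi-donor microarray bundle (AHBA CSV dialect)
#'
#' Each donor directory must contain `SampleAnnot.csv` (with MNI coordinate
#' columns `mni_x`, `mni_y`, `mni_z`), `Probes.csv` (columns `probe_id`,
#' `gene_symbol`) and `MicroarrayExpression.csv` (no header; probe id in
#' column 1, then one column per sample in annotation row order). Probes are
#' collapsed to one row per gene symbol and donors concatenated.
#'
#' @param dir Directory containing one subdirectory per donor.
#' @param probe_collapse `"max_mean"` (keep the probe with the highest mean
#'   expression across all samples of all donors; default) or `"mean"`
#'   (average probes per gene).
#' @param zscore_donor Z-score each gene within each donor across that
#'   donor's samples before pooling, removing donor batch offsets
#'   (default `TRUE`).
#' @param mirror_missing_hemisphere Reflect the x coordinate of samples from
#'   donors whose samples all lie in one hemisphere, duplicating them into
#'   the other (default `FALSE`).
#' @return An [expression_sample_set]; the parsed sample count is reported
#'   via a message rather than asserted.
#' @export
read_expression_bundle <- function(dir, probe_collapse = c("max_mean", "mean"),
                                   zscore_donor = TRUE,
                                   mirror_missing_hemisphere = FALSE) {
  probe_collapse <- match.arg(probe_collapse)
  if (!dir.exists(dir)) stopf("read_expression_bundle: no such directory: %s", dir)
  donors <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(donors)) stopf("read_expression_bundle: no donor folders under %s", dir)

  per <- lapply(donors, function(dd) {
    annot <- utils::read.csv(file.path(dd, "SampleAnnot.csv"),
                             stringsAsFactors = FALSE)
    probes <- utils::read.csv(file.path(dd, "Probes.csv"),
                              stringsAsFactors = FALSE)
    exprs <- utils::read.csv(file.path(dd, "MicroarrayExpression.csv"),
                             header = FALSE)
    pid <- exprs[[1]]
    mat <- as.matrix(exprs[, -1, drop = FALSE])
    if (ncol(mat) != nrow(annot)) {
      stopf("read_expression_bundle: %s: expression has %d sample columns but annotation has %d rows",
            basename(dd), ncol(mat), nrow(annot))
    }
    miss <- setdiff(pid, probes$probe_id)
    if (length(miss)) {
      stopf("read_expression_bundle: %s: probe id(s) missing from Probes.csv: %s",
            basename(dd), paste(utils::head(miss, 5), collapse = ", "))
    }
    sym <- probes$gene_symbol[match(pid, probes$probe_id)]
    need <- c("mni_x", "mni_y", "mni_z")
    if (!all(need %in% names(annot))) {
      stopf("read_expression_bundle: %s: SampleAnnot.csv lacks %s",
            basename(dd), paste(setdiff(need, names(annot)), collapse = ", "))
    }
    list(donor = basename(dd), probe = pid, symbol = sym, expr = mat,
         coords = as.matrix(annot[, need]))
  })

  all_sym <- sort(unique(unlist(lapply(per, `[[`, "symbol"))))
  all_sym <- all_sym[!is.na(all_sym) & nzchar(all_sym)]
  if (!length(all_sym)) stopf("read_expression_bundle: empty gene set after collapse")

  # Probe choice is made jointly across donors so every donor contributes the
  # same probe per gene.
  if (probe_collapse == "max_mean") {
    sums <- list(); counts <- list()
    for (d in per) {
      for (i in seq_along(d$probe)) {
        p <- as.character(d$probe[i])
        sums[[p]] <- (sums[[p]] %||% 0) + sum(d$expr[i, ])
        counts[[p]] <- (counts[[p]] %||% 0) + ncol(d$expr)
      }
    }
    probe_mean <- vapply(names(sums), function(p) sums[[p]] / counts[[p]],
                         numeric(1))
    sym_of <- unlist(lapply(per, function(d) {
      stats::setNames(d$symbol, as.character(d$probe))
    }))
    sym_of <- sym_of[!duplicated(names(sym_of))]
    best_probe <- vapply(all_sym, function(s) {
      cand <- names(sym_of)[sym_of == s]
      cand[which.max(probe_mean[cand])]
    }, character(1))
  }

  blocks <- lapply(per, function(d) {
    out <- matrix(NA_real_, nrow = length(all_sym), ncol = ncol(d$expr),
                  dimnames = list(all_sym, NULL))
    if (probe_collapse == "max_mean") {
      hit <- best_probe[all_sym] %in% as.character(d$probe)
      ridx <- match(best_probe[all_sym][hit], as.character(d$probe))
      out[which(hit), ] <- d$expr[ridx, , drop = FALSE]
    } else {
      for (s in all_sym) {
        ridx <- which(d$symbol == s)
        if (length(ridx)) {
          out[s, ] <- colMeans(d$expr[ridx, , drop = FALSE])
        }
      }
    }
    out
  })

  donor_vec <- unlist(lapply(per, function(d) rep(d$donor, ncol(d$expr))))
  coords <- do.call(rbind, lapply(per, `[[`, "coords"))
  expr <- do.call(cbind, blocks)
  keep <- rowSums(is.na(expr)) == 0L
  if (!all(keep)) {
    msgf("read_expression_bundle: dropping %d gene(s) not measured in every donor",
         sum(!keep))
    expr <- expr[keep, , drop = FALSE]
  }
  if (!nrow(expr)) stopf("read_expression_bundle: empty gene set after collapse")

  if (mirror_missing_hemisphere) {
    add_expr <- list(); add_coords <- list(); add_donor <- list()
    for (d in unique(donor_vec)) {
      j <- donor_vec == d
      xs <- coords[j, 1]
      if (all(xs <= 0) || all(xs >= 0)) {
        add_expr[[d]] <- expr[, j, drop = FALSE]
        cc <- coords[j, , drop = FALSE]
        cc[, 1] <- -cc[, 1]
        add_coords[[d]] <- cc
        add_donor[[d]] <- rep(paste0(d, "_mirror"), sum(j))
      }
    }
    if (length(add_expr)) {
      expr <- cbind(expr, do.call(cbind, add_expr))
      coords <- rbind(coords, do.call(rbind, add_coords))
      donor_vec <- c(donor_vec, unlist(add_donor))
    }
  }

  if (zscore_donor) {
    for (d in unique(donor_vec)) {
      j <- donor_vec == d
      block <- expr[, j, drop = FALSE]
      mu <- rowMeans(block)
      sd <- apply(block, 1, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      expr[, j] <- (block - mu) / sd
    }
  }

  msgf("read_expression_bundle: parsed %d samples x %d genes from %d donor(s)",
       ncol(expr), nrow(expr), length(unique(donor_vec)))
  expression_sample_set(coords = coords, donor = donor_vec,
                        genes = rownames(expr), expr = expr)
}

#' Canonical brain cell types
#'
#' The six canonical cell types used throughout: neurons, astrocytes,
#' oligodendrocytes, microglia, endothelial cells and oligodendrocyte
#' precursor cells (OPCs).
#' @return Character vector of the six cell-type labels.
#' @export
cell_types <- function() {
  c("neuron", "astrocyte", "oligodendrocyte", "microglia", "endothelial", "OPC")
}

#' Construct / validate a marker table
#'
#' A marker table holds (gene symbol, cell type, rank) triples defining the
#' deconvolution signature set. Ranks within a cell type must be 1..k with
#' no gaps and (gene, cell_type) pairs unique; every cell type in
#' `required_types` must be present.
#'
#' @param df data.frame with columns `gene`, `cell_type`, `rank`.
#' @param required_types Cell types that must each retain at least one
#'   marker (default [cell_types()]).
#' @return Validated data.frame of class `marker_table`.
#' @export
marker_table <- function(df, required_types = cell_types()) {
  stopifnot(all(c("gene", "cell_type", "rank") %in% names(df)))
  df <- data.frame(gene = as.character(df$gene),
                   cell_type = as.character(df$cell_type),
                   rank = as.integer(df$rank))
  if (anyDuplicated(df[, c("gene", "cell_type")])) {
    stopf("marker_table: duplicated (gene, cell_type) pair")
  }
  if (any(df$rank < 1L)) stopf("marker_table: ranks must be positive")
  for (ct in unique(df$cell_type)) {
    r <- sort(df$rank[df$cell_type == ct])
    if (!identical(r, seq_along(r))) {
      stopf("marker_table: ranks for '%s' are not 1..k without gaps", ct)
    }
  }
  lost <- setdiff(required_types, unique(df$cell_type))
  if (length(lost)) {
    stopf("marker_table: cell type(s) with no markers: %s",
          paste(lost, collapse = ", "))
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Read a marker table from TSV
#'
#' @param path TSV with header `gene`, `cell_type`, `rank`.
#' @param required_types Passed to [marker_table()].
#' @return A `marker_table`.
#' @export
read_marker_table <- function(path, required_types = cell_types()) {
  if (!file.exists(path)) stopf("read_marker_table: file not found: %s", path)
  marker_table(utils::read.delim(path, stringsAsFactors = FALSE),
               required_types = required_types)
}

#' Bundled default human brain marker set
#'
#' Fifteen literature marker genes per canonical cell type (90 genes in
#' total), shipped as a plain TSV in `inst/extdata`.
#'
#' @return A `marker_table` with 90 rows.
#' @export
default_markers <- function() {
  read_marker_table(system.file("extdata", "markers_human.tsv",
                                package = "braincellmap"))
}

#' Restrict a marker table to measured genes
#'
#' Keeps the marker rows whose gene symbol matches (case-insensitively) an
#' entry of `gene_symbols`; ranks are preserved as-is. One message is
#' emitted per dropped marker. A cell type losing all of its markers is a
#' hard error, since deconvolution of that type becomes impossible.
#'
#' @param markers A `marker_table`.
#' @param gene_symbols Character vector of measured gene symbols.
#' @return The matched subset, still a `marker_table`.
#' @export
match_markers <- function(markers, gene_symbols) {
  hit <- tolower(markers$gene) %in% tolower(gene_symbols)
  for (g in markers$gene[!hit]) {
    msgf("match_markers: dropping unmeasured marker '%s'", g)
  }
  out <- markers[hit, , drop = FALSE]
  lost <- setdiff(unique(markers$cell_type), unique(out$cell_type))
  if (length(lost)) {
    stopf("match_markers: all markers lost for cell type(s): %s",
          paste(lost, collapse = ", "))
  }
  class(out) <- c("marker_table", "data.frame")
  rownames(out) <- NULL
  out
}
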