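#' Pipeline configuration
#'
#' One object drives the end-to-end run: simulate (synthetic mode) or load
#' (real mode), interpolate, deconvolve, associate, cluster. Every stage
#' can be toggled; all randomness flows from `seed`.
#'
#' @param mode `"synthetic"` (phantom inputs generated in-run) or `"real"`
#'   (paths below must exist).
#' @param out_dir Output directory.
#' @param seed Integer seed (required in synthetic mode).
#' @param phantom A [phantom_config()] (synthetic mode; its `seed` is
#'   overridden by `seed`).
#' @param kernel A [kernel_config()].
#' @param alpha FDR threshold in (0, 1).
#' @param smooth_fwhm_mm Optional FWHM for pre-association smoothing of the
#'   atrophy maps (`NULL` = off); used for kernel-size robustness checks.
#' @param deconvolve_first If `TRUE`, deconvolve the sparse samples first
#'   and interpolate the resulting scores; default `FALSE`
#'   (interpolate-then-deconvolve).
#' @param stages Character subset of
#'   `c("simulate", "interpolate", "deconvolve", "associate", "cluster")`.
#' @param expression_dir,gm_path,atrophy_dir,labels_path,lookup_path,marker_path
#'   Real-mode input paths (multi-donor bundle directory, GM probability
#'   NIfTI, directory of atrophy NIfTIs, parcellation NIfTI, region lookup
#'   TSV, marker TSV; `marker_path = NULL` uses [default_markers()]).
#' @param gm_threshold GM probability cut defining the analysis mask in
#'   real mode (default 0.2).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            out_dir = tempfile("bcm_run_"),
                            seed = 1L,
                            phantom = phantom_config(seed = seed),
                            kernel = kernel_config(),
                            alpha = 0.05,
                            smooth_fwhm_mm = NULL,
                            deconvolve_first = FALSE,
                            stages = c("simulate", "interpolate",
                                       "deconvolve", "associate", "cluster"),
                            expression_dir = NULL, gm_path = NULL,
                            atrophy_dir = NULL, labels_path = NULL,
                            lookup_path = NULL, marker_path = NULL,
                            gm_threshold = 0.2) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (mode == "synthetic" && is.null(seed)) {
    stopf("pipeline_config: synthetic mode requires a seed")
  }
  if (mode == "real") {
    for (p in c(expression_dir, gm_path, atrophy_dir, labels_path, lookup_path)) {
      if (is.null(p) || !file.exists(p)) {
        stopf("pipeline_config: real mode input missing: %s",
              if (is.null(p)) "(unset path)" else p)
      }
    }
  } else {
    phantom$seed <- as.integer(seed)
  }
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         phantom = phantom, kernel = kernel, alpha = alpha,
         smooth_fwhm_mm = smooth_fwhm_mm,
         deconvolve_first = deconvolve_first, stages = stages,
         expression_dir = expression_dir, gm_path = gm_path,
         atrophy_dir = atrophy_dir, labels_path = labels_path,
         lookup_path = lookup_path, marker_path = marker_path,
         gm_threshold = gm_threshold),
    class = "pipeline_config"
  )
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(cell_type = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the whole-brain cell-type vulnerability pipeline
#'
#' Executes the enabled stages in order — simulate/load, interpolate,
#' deconvolve, associate, cluster — and writes rho/p/q CSVs, cell-type
#' proportion maps, regional matrices, Newick dendrograms and a JSON
#' manifest (config echo, seed, stage status and timings, output
#' checksums). Rerunning with an identical config and seed reproduces all
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage products
#'   (`phantom`, `samples`, `atlas`, `cellmaps`, `regional`, `assoc`,
#'   `dendro`) plus `manifest_path`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  t_all <- Sys.time()
  res <- list()
  log <- file.path(config$out_dir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log, append = TRUE)
  }
  fail <- function(stage, err) {
    writeLines(sprintf("FAILED at stage %s: %s", stage,
                       conditionMessage(err)),
               file.path(config$out_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(err))
  }
  stage_on <- function(s) s %in% config$stages
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) fail(stage, e))
    status[[stage]] <<- list(
      status = "completed",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    out
  }

  # ---- stage 1: inputs --------------------------------------------------
  markers <- NULL
  atrophy_maps <- list()
  labels <- NULL
  gm <- NULL
  samples <- NULL
  if (config$mode == "synthetic") {
    if (stage_on("simulate")) {
      say("simulate: phantom seed %d", config$seed)
      sim <- timed("simulate", {
        ph <- generate_phantom(config$phantom)
        mk <- synthetic_markers(config$phantom)
        sm <- sample_bulk_expression(ph, mk)
        at <- list()
        for (i in seq_along(config$phantom$atrophy_specs)) {
          sp <- config$phantom$atrophy_specs[[i]]
          at[[sp$name]] <- generate_atrophy(ph, sp,
                                            seed = config$seed + 1000L + i)
        }
        list(phantom = ph, markers = mk, samples = sm, atrophy = at)
      })
      res$phantom <- sim$phantom
      markers <- sim$markers
      samples <- sim$samples
      atrophy_maps <- sim$atrophy
      labels <- sim$phantom$labels
      gm <- sim$phantom$gm_density
    } else {
      status$simulate <- list(status = "skipped")
      stopf("run_pipeline: synthetic mode requires the simulate stage")
    }
  } else {
    say("load: real-mode inputs")
    loaded <- timed("simulate", {
      gm0 <- read_volume(config$gm_path)
      mask_vals <- gm0$values
      mask_vals[is.na(mask_vals) | mask_vals < config$gm_threshold] <- 0
      gm0$values <- mask_vals
      lk <- read_region_lookup(config$lookup_path)
      lab_grid <- read_volume(config$labels_path)
      lab <- label_volume(resample_to_grid(lab_grid, gm0, "nearest"), lk)
      mk <- if (is.null(config$marker_path)) default_markers() else
        read_marker_table(config$marker_path)
      sm <- read_expression_bundle(config$expression_dir)
      files <- list.files(config$atrophy_dir, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
      at <- lapply(files, function(f) {
        resample_to_grid(read_volume(f), gm0, "trilinear")
      })
      names(at) <- sub("\\.nii(\\.gz)?$", "", basename(files))
      list(gm = gm0, labels = lab, markers = mk, samples = sm, atrophy = at)
    })
    gm <- loaded$gm
    labels <- loaded$labels
    samples <- loaded$samples
    atrophy_maps <- loaded$atrophy
    markers <- match_markers(loaded$markers, samples$genes)
  }
  res$samples <- samples

  if (!is.null(config$smooth_fwhm_mm) && length(atrophy_maps)) {
    say("smoothing atrophy maps, fwhm %.1f mm", config$smooth_fwhm_mm)
    atrophy_maps <- lapply(atrophy_maps, smooth_volume,
                           fwhm_mm = config$smooth_fwhm_mm)
  }

  # ---- stages 2+3: atlas and cell maps ---------------------------------
  cellmaps <- NULL
  if (stage_on("interpolate") || stage_on("deconvolve")) {
    if (!config$deconvolve_first) {
      atlas <- if (stage_on("interpolate")) {
        say("interpolate: %d genes onto %d GM voxels, l = %g mm",
            length(samples$genes), sum(gm$values > 0, na.rm = TRUE),
            config$kernel$length_scale_mm)
        timed("interpolate", interpolate_expression(samples, gm, config$kernel))
      } else {
        status$interpolate <- list(status = "skipped")
        NULL
      }
      res$atlas <- atlas
      if (stage_on("deconvolve") && !is.null(atlas)) {
        say("deconvolve: %d cell types", length(unique(markers$cell_type)))
        cellmaps <- timed("deconvolve", estimate_cell_maps(atlas, markers, gm))
      } else {
        status$deconvolve <- list(status = "skipped")
      }
    } else {
      # deconvolve the sparse samples, then interpolate unit scores
      say("deconvolve-first order")
      cellmaps <- timed("deconvolve", {
        z <- zscore_genes(samples$expr)
        types <- unique(markers$cell_type)
        unit <- do.call(rbind, lapply(types, function(ct) {
          rescale_unit(surrogate_scores(z, markers, ct))
        }))
        rownames(unit) <- types
        score_set <- expression_sample_set(samples$coords, samples$donor,
                                           types, unit)
        atlas <- interpolate_expression(score_set, gm, config$kernel)
        status$interpolate <- list(status = "completed")
        gm_vals <- gm$values[atlas$voxel_index]
        np <- normalize_proportions(pmax(atlas$values, 0), gm_vals)
        maps <- lapply(types, function(ct) {
          vals <- array(0, dim = atlas$grid$dims)
          vals[atlas$voxel_index] <- np$proportions[ct, ]
          volume_grid(vals, atlas$grid$affine, space = atlas$grid$space)
        })
        names(maps) <- types
        structure(list(cell_types = types, maps = maps,
                       scores = atlas$values,
                       proportions = np$proportions,
                       voxel_index = atlas$voxel_index,
                       zero_sum = np$zero_sum, gm_density = gm_vals),
                  class = "cell_proportion_maps")
      })
    }
  }
  res$cellmaps <- cellmaps
  if (!is.null(cellmaps)) {
    for (ct in cellmaps$cell_types) {
      write_volume(cellmaps$maps[[ct]],
                   file.path(config$out_dir,
                             sprintf("cellmap_%s.nii.gz", ct)))
    }
  }

  # ---- stage 4: association --------------------------------------------
  assoc <- NULL
  if (stage_on("associate") && !is.null(cellmaps) && length(atrophy_maps)) {
    say("associate: %d conditions over parcellation", length(atrophy_maps))
    assoc <- timed("associate", {
      exclude <- NULL
      if (any(cellmaps$zero_sum)) {
        ex <- array(FALSE, dim = gm$dims)
        ex[cellmaps$voxel_index[cellmaps$zero_sum]] <- TRUE
        exclude <- ex
      }
      cell_reg <- regional_matrix(cellmaps$maps, labels, exclude = exclude)
      atro_reg <- regional_matrix(atrophy_maps, labels)
      utils::write.table(
        data.frame(region = rownames(cell_reg), cell_reg, check.names = FALSE),
        file.path(config$out_dir, "regional_cells.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(region = rownames(atro_reg), atro_reg, check.names = FALSE),
        file.path(config$out_dir, "regional_atrophy.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      am <- association_matrix(cell_reg, atro_reg, alpha = config$alpha)
      write_matrix_csv(am$rho, file.path(config$out_dir, "rho.csv"))
      write_matrix_csv(am$p, file.path(config$out_dir, "p.csv"))
      write_matrix_csv(am$q, file.path(config$out_dir, "q.csv"))
      res$regional <- list(cells = cell_reg, atrophy = atro_reg)
      am
    })
  } else {
    status$associate <- list(status = "skipped")
  }
  res$assoc <- assoc

  # ---- stage 5: clustering ---------------------------------------------
  dendro <- NULL
  if (stage_on("cluster") && !is.null(assoc)) {
    say("cluster: UPGMA on both axes")
    dendro <- timed("cluster", {
      cl <- cluster_association(assoc)
      if (!is.null(cl$rows)) {
        writeLines(to_newick(cl$rows),
                   file.path(config$out_dir, "cells_dendrogram.nwk"))
        utils::write.table(cl$rows$merges,
                           file.path(config$out_dir, "cells_merges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(cl$cols)) {
        writeLines(to_newick(cl$cols),
                   file.path(config$out_dir, "conditions_dendrogram.nwk"))
        utils::write.table(cl$cols$merges,
                           file.path(config$out_dir, "conditions_merges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      cl
    })
  } else {
    status$cluster <- list(status = "skipped")
  }
  res$dendro <- dendro

  # ---- manifest ---------------------------------------------------------
  outputs <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("braincellmap")),
    mode = config$mode,
    seed = config$seed,
    alpha = config$alpha,
    length_scale_mm = config$kernel$length_scale_mm,
    deconvolve_first = config$deconvolve_first,
    stages = status,
    total_seconds = as.numeric(difftime(Sys.time(), t_all, units = "secs")),
    outputs = lapply(outputs, function(f) {
      p <- file.path(config$out_dir, f)
      list(path = f, md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("done: %s", mpath)
  res$manifest_path <- mpath
  invisible(res)
}
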