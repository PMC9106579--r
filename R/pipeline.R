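# End-to-end pipeline: simulate -> prep -> detect -> reference -> correlate
# -> partition -> fit.

#' Default pipeline configuration
#'
#' Every tunable of every stage is a config key; defaults are the
#' experimental values (windows in um, QC intervals, crop size) or, for
#' synthetic-only knobs, the scene defaults. The QC `area_target` defaults to
#' the nominal pattern constant scaled to the scene's footprint.
#'
#' @param spec a [scene_spec()] for synthetic input.
#' @param n_cells ensemble size.
#' @param seed master seed.
#' @param ... overrides of any config key.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(spec = scene_spec(), n_cells = 12, seed = 1L, ...) {
  cfg <- list(
    spec = spec, n_cells = n_cells, seed = as.integer(seed),
    channels = c("granule", "tubulin"),
    canvas = c(spec$grid_dim[1], spec$grid_dim[2]),
    area_target = scene_footprint_area(spec, nominal = TRUE),
    area_window = c(0.85, 1.10),
    ratio_window = c(0.43, 0.55),
    max_orientation_dev = 3,
    peak_interval = c(2, 4),
    min_batch = 10,
    corner_patch = 10L,
    detect_box = c(30, 30, 5),
    detect_smooth_sigma = 1,
    detect_levels = 101L,
    detect_weights = c(1, 1, 1),
    detect_max_volume = 20000,
    min_quality = 0.8,
    dilation_radius = 3,
    max_centroid_shift = 0.5,
    min_radius_px = 3,
    crop_size = 221L,
    env_radius = 8,
    min_contrast = 2,
    ref_blur_var = 4,
    ref_z_range_um = 1.2,
    min_partition_radius_um = 0.59,
    interface_um = 0.39,
    cytosol_um = 0.52,
    anchor_halfwidth_px = 2,
    min_interior_entries = 3,
    min_cohort = 10,
    fit_realizations = 1000L,
    keep_raw_cells = FALSE,
    out_dir = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

log_stage <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order
#' simulate -> prep -> detect -> reference -> correlate -> partition -> fit,
#' checking stage dependencies before any work, and logging per-stage counts
#' (cells and granules kept/discarded with reasons). With `out_dir` set,
#' tabular results are written as CSV.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages, or `"all"`.
#' @param ensemble optionally, a pre-generated [generate_ensemble()] result
#'   (replaces the simulate stage).
#' @param verbose log progress.
#' @return list with the outputs of every executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         ensemble = NULL, verbose = TRUE) {
  order_all <- c("simulate", "prep", "detect", "reference", "correlate",
                 "partition", "fit")
  if (identical(stages, "all")) stages <- order_all
  stages <- order_all[order_all %in% stages]
  # dependency check before any work
  need <- list(prep = "simulate", detect = "prep", reference = "prep",
               correlate = c("detect", "reference"),
               partition = "correlate", fit = "partition")
  have <- if (is.null(ensemble)) character() else "simulate"
  for (st in stages) {
    deps <- need[[st]]
    missing <- setdiff(deps, c(have, stages))
    if (length(missing))
      stop("stage '", st, "' requires ", paste(missing, collapse = ", "),
           " but it is neither available nor requested")
    have <- c(have, st)
  }
  out <- list(config = config)
  if ("simulate" %in% stages) {
    log_stage(verbose, "simulate: %d cells, seed %d", config$n_cells,
              config$seed)
    ensemble <- generate_ensemble(config$spec, config$n_cells, config$seed)
  }
  out$ensemble <- ensemble
  if ("prep" %in% stages) {
    out$prep <- pipeline_prep(ensemble, config, verbose)
    if (!isTRUE(config$keep_raw_cells)) {
      # raw acquisitions are no longer needed once cells are aligned and
      # normalized; dropping them keeps large ensembles within desk memory
      ensemble$cells <- NULL
      out$ensemble <- ensemble
    }
  }
  if ("detect" %in% stages) {
    out$detect <- pipeline_detect(out$prep, config, verbose)
  }
  if ("reference" %in% stages) {
    log_stage(verbose, "reference: %d cells", length(out$prep$records))
    out$reference <- lapply(
      stats::setNames(config$channels, config$channels),
      function(ch) build_reference(out$prep$records, ch,
                                   blur_var = config$ref_blur_var,
                                   z_range_um = config$ref_z_range_um))
  }
  if ("correlate" %in% stages) {
    out$correlate <- pipeline_correlate(out$prep, out$detect, out$reference,
                                        config, verbose)
  }
  if ("partition" %in% stages) {
    out$partition <- pipeline_partition(out$correlate, config, verbose)
  }
  if ("fit" %in% stages) {
    sc <- out$partition$cohort$scatter
    log_stage(verbose, "fit: %d points, %d realizations", nrow(sc),
              config$fit_realizations)
    out$fit <- fit_a0(sc, seed = config$seed,
                      n_realizations = config$fit_realizations)
  }
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

pipeline_prep <- function(ensemble, config, verbose = TRUE) {
  candidates <- list()
  discarded <- list()
  for (i in seq_along(ensemble$cells)) {
    cell <- ensemble$cells[[i]]
    det <- detect_footprints(cell$stacks[config$channels],
                             cell$stacks$nucleus)
    if (!is.null(det$discard)) {
      discarded[[length(discarded) + 1]] <-
        tibble::tibble(id = i, reason = det$discard)
      next
    }
    det$stacks <- lapply(det$stacks, subtract_corner_background,
                         cell2d = det$cell2d, patch = config$corner_patch)
    bh <- estimate_base_height(det$stacks$tubulin)
    det$z_b <- bh$z_b; det$z_peak <- bh$z_peak
    det$id <- i
    candidates[[length(candidates) + 1]] <- det
  }
  if (!length(candidates)) stop("no candidate cells")
  qa <- qc_and_align(candidates, area_target = config$area_target,
                     area_window = config$area_window,
                     ratio_window = config$ratio_window,
                     max_orientation_dev = config$max_orientation_dev,
                     peak_interval = config$peak_interval,
                     min_batch = config$min_batch, canvas = config$canvas)
  records <- list()
  for (rec in qa$records) {
    norm <- list()
    ok <- TRUE
    for (ch in config$channels) {
      nr <- normalize_channel(rec, ch)
      if (is.null(nr)) { ok <- FALSE; break }
      norm[[ch]] <- nr$stack
      rec[[paste0("I_mean_", ch)]] <- nr$I_mean
    }
    if (!ok) next
    rec$norm <- norm
    rec$stacks <- NULL # raw stacks no longer needed
    records[[length(records) + 1]] <- rec
  }
  log_stage(verbose, "prep: %d/%d cells kept", length(records),
            length(ensemble$cells))
  list(records = records, qc = qa$qc,
       pre_discards = dplyr::bind_rows(discarded),
       batch_orientation = qa$batch_orientation)
}

pipeline_detect <- function(prep, config, verbose = TRUE) {
  tables <- list()
  sweeps <- list()
  for (j in seq_along(prep$records)) {
    rec <- prep$records[[j]]
    sw <- preprocess_and_sweep(rec$norm$granule, box = config$detect_box,
                               smooth_sigma = config$detect_smooth_sigma,
                               n_levels = config$detect_levels,
                               weights = config$detect_weights,
                               max_volume = config$detect_max_volume,
                               min_quality = config$min_quality)
    sw_slim <- sw
    sw_slim$filtered <- NULL
    sweeps[[j]] <- sw_slim
    if (!is.null(sw$discard)) next
    gt <- extract_granules(rec$norm$granule, sw, rec$cell2d, rec$nucleus2d,
                           dilation_radius = config$dilation_radius,
                           max_centroid_shift = config$max_centroid_shift,
                           min_radius_px = config$min_radius_px)
    if (nrow(gt)) {
      gt$cell <- j
      pitch <- rec$norm$granule$pitch_xy
      gt$x_um <- gt$x * pitch
      gt$y_um <- gt$y * pitch
      tables[[length(tables) + 1]] <- gt
    }
  }
  granules <- dplyr::bind_rows(tables)
  if (nrow(granules))
    granules <- bin_granules(granules,
                             pitch = prep$records[[1]]$norm$granule$pitch_xy)
  log_stage(verbose, "detect: %d blobs, %d kept", nrow(granules),
            sum(granules$kept))
  list(granules = granules, sweeps = sweeps)
}

pipeline_correlate <- function(prep, detect, refs, config, verbose = TRUE) {
  granules <- detect$granules[detect$granules$kept, , drop = FALSE]
  n <- nrow(granules)
  crops_g <- crops_t <- shapes <- vector("list", n)
  excl <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- granules[i, ]
    rec <- prep$records[[g$cell]]
    cr <- crop_granule_images(rec, g, size = config$crop_size)
    ref_g <- lookup_reference(refs$granule, rec, cr$origin,
                              size = config$crop_size)
    ref_t <- lookup_reference(refs$tubulin, rec, cr$origin,
                              size = config$crop_size)
    if (is.null(ref_g) || is.null(ref_t)) {
      excl[i] <- "outside reference z-range"
      next
    }
    rel_g <- normalize_granule_image(cr$granule, ref_g)
    rel_t <- normalize_granule_image(cr$tubulin, ref_t)
    if (all(is.na(rel_g))) { excl[i] <- "crop fully invalid"; next }
    cs <- g$cross_section[[1]]
    shp <- matrix(FALSE, config$crop_size, config$crop_size)
    sy <- cs[, 1] - cr$origin["y"] + 1L; sx <- cs[, 2] - cr$origin["x"] + 1L
    oks <- sy >= 1 & sy <= config$crop_size & sx >= 1 & sx <= config$crop_size
    shp[cbind(sy[oks], sx[oks])] <- TRUE
    crops_g[[i]] <- rel_g; crops_t[[i]] <- rel_t; shapes[[i]] <- shp
    attr(crops_g[[i]], "origin") <- cr$origin
  }
  granules$rel_crop <- crops_g
  granules$rel_crop_tub <- crops_t
  granules$crop_shape <- shapes
  granules$reason <- excl
  granules$kept <- is.na(excl)
  keep0 <- granules$kept
  granules <- brightness_filter(granules, env_radius = config$env_radius,
                                min_contrast = config$min_contrast)
  # surface profiles for surviving granules
  gs_sg <- gs_tub <- vector("list", nrow(granules))
  for (i in which(granules$kept)) {
    g <- granules[i, ]
    origin <- attr(g$rel_crop[[1]], "origin")
    gs_sg[[i]] <- surface_profile(g, g$rel_crop[[1]], origin,
                                  pitch = prep$records[[1]]$norm$granule$pitch_xy)
    gs_tub[[i]] <- surface_profile(g, g$rel_crop_tub[[1]], origin,
                                   pitch = prep$records[[1]]$norm$granule$pitch_xy)
  }
  granules$gs_sg <- gs_sg
  granules$gs_tub <- gs_tub
  log_stage(verbose, "correlate: %d/%d granules with profiles",
            sum(granules$kept), length(keep0))
  list(granules = granules, references = refs)
}

pipeline_partition <- function(correlate, config, verbose = TRUE) {
  granules <- correlate$granules
  pitch <- 0.065
  rows <- vector("list", nrow(granules))
  for (i in seq_len(nrow(granules))) {
    g <- granules[i, ]
    if (!g$kept) {
      rows[[i]] <- tibble::tibble(I_s = NA_real_, I_g = NA_real_,
                                  I_c = NA_real_, d_star_um = NA_real_,
                                  eligible = FALSE, reason = g$reason)
      next
    }
    rows[[i]] <- measure_levels(
      g$gs_sg[[1]], g$gs_tub[[1]], g$R_um, pitch = pitch,
      min_radius_um = config$min_partition_radius_um,
      interface_um = config$interface_um, cytosol_um = config$cytosol_um,
      anchor_halfwidth_px = config$anchor_halfwidth_px,
      min_interior_entries = config$min_interior_entries)
  }
  levels <- dplyr::bind_rows(rows)
  levels$cell <- granules$cell
  levels$granule <- granules$granule
  levels$R_um <- granules$R_um
  results <- to_partition_and_affinity(levels)
  cohort <- cohort_statistics(results, min_granules = config$min_cohort)
  log_stage(verbose, "partition: %d eligible granules, <lnkg> = %.4f, <lnks> = %.4f",
            cohort$n, mean(cohort$scatter$lnkg), mean(cohort$scatter$lnks))
  list(results = results, cohort = cohort)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$prep))
    write_results(out$prep$qc, file.path(dir, "cell_qc.csv"))
  if (!is.null(out$detect) && nrow(out$detect$granules)) {
    g <- out$detect$granules
    write_results(
      g[, c("cell", "granule", "x_um", "y_um", "z_plane", "area_um2",
            "R_um", "ellipticity", "orientation", "kept", "reason")],
      file.path(dir, "granules.csv"))
  }
  if (!is.null(out$partition)) {
    r <- out$partition$results
    write_results(
      r[, c("cell", "granule", "R_um", "I_s", "I_g", "I_c", "d_star_um",
            "k_g", "k_s", "lnkg", "lnks", "eligible", "reason")],
      file.path(dir, "partition.csv"))
    write_results(out$partition$cohort$summary,
                  file.path(dir, "cohort_summary.csv"))
  }
  if (!is.null(out$fit)) {
    write_results(glance(out$fit), file.path(dir, "a0_fit.csv"))
  }
  invisible(dir)
}
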