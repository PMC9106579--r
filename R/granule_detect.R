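# Stress-granule detection via a multi-threshold quality-factor sweep.

#' Background-filter a granule channel and sweep detection thresholds
#'
#' A dynamic background (box mean over `box` voxels) is subtracted and the
#' result slightly Gaussian-smoothed. 101 evenly spaced thresholds are probed
#' between the maximum of the per-plane mean intensities and the global
#' maximum. For each level the 3D connected components (26-connectivity) are
#' counted and their mean/median volumes recorded. A quality factor Q in
#' `[0, 1]` combines three absolute criteria with configurable weights:
#' stability of the blob count between neighbouring levels, large mean blob
#' volume, and large median blob volume (volumes saturate at the volume of a
#' diffraction-limited sphere of radius 3 px, giving Q an absolute scale so a
#' minimum-quality cutoff can reject cells with no real granules).
#'
#' @param stack normalized granule-channel [channel_stack()].
#' @param box background box-kernel size c(y, x, z) in voxels.
#' @param smooth_sigma in-plane Gaussian smoothing sigma, px.
#' @param n_levels number of probed thresholds.
#' @param weights weights of the three quality criteria.
#' @param max_volume largest plausible granule volume in voxels; levels whose
#'   mean blob volume exceeds it (e.g. a single percolating component at a
#'   too-low threshold) score zero on the volume criteria.
#' @param min_quality minimum acceptable Q; below it the cell is discarded.
#' @return list of class `threshold_sweep`: per-level tibble, chosen level,
#'   chosen threshold, `q_max`, the filtered array, and a `discard` reason or
#'   `NULL`.
#' @export
preprocess_and_sweep <- function(stack, box = c(30, 30, 5), smooth_sigma = 1,
                                 n_levels = 101L, weights = c(1, 1, 1),
                                 max_volume = 20000, min_quality = 0.8) {
  v <- stack_values(stack)
  d <- dim(v)
  half <- pmax(0L, as.integer(floor(box / 2)))
  bg <- cpp_boxmean3d(v, d, half[1], half[2], half[3])
  filt <- v - bg
  filt <- cpp_gauss3d(filt, d, smooth_sigma, smooth_sigma, 0, TRUE)
  plane_means <- vapply(seq_len(d[3]), function(z) {
    m <- filt[, , z]
    if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  }, 0)
  lo <- max(plane_means, na.rm = TRUE)
  hi <- max(filt, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    return(structure(list(discard = "no granules", q_max = 0), class = "threshold_sweep"))
  levels <- seq(lo, hi, length.out = n_levels)
  nb <- meanv <- medv <- numeric(n_levels)
  for (i in seq_len(n_levels)) {
    bin <- !is.na(filt) & filt > levels[i]
    lab <- cpp_label3d(bin, d)
    nblob <- max(lab)
    nb[i] <- nblob
    if (nblob > 0) {
      vols <- tabulate(lab[lab > 0], nbins = nblob)
      meanv[i] <- mean(vols)
      medv[i] <- median(vols)
    }
  }
  if (all(nb == 0))
    return(structure(list(discard = "no granules", q_max = 0), class = "threshold_sweep"))
  # reference volume: diffraction-limited sphere of radius 3 px
  v_ref <- 4 / 3 * pi * 27
  dn <- abs(c(diff(nb)[1], diff(nb))) + abs(c(diff(nb), diff(nb)[length(nb) - 1]))
  c1 <- 1 / (1 + dn / 2)
  c2 <- ifelse(meanv > max_volume, 0, pmin(1, meanv / v_ref))
  c3 <- ifelse(medv > max_volume, 0, pmin(1, medv / v_ref))
  q <- (weights[1] * c1 + weights[2] * c2 + weights[3] * c3) / sum(weights)
  q[nb == 0] <- 0
  best <- which(q == max(q))
  # tie-break across a quality plateau: granules must be set apart by a sharp
  # intensity gradient, so among equally good levels choose the one whose
  # boundary (voxels at that intensity) sits on the steepest gradient
  if (length(best) > 1) {
    gy <- filt; gy[] <- 0
    gy[-1, , ] <- abs(filt[-1, , , drop = FALSE] -
                        filt[-d[1], , , drop = FALSE])
    gx <- filt; gx[] <- 0
    gx[, -1, ] <- abs(filt[, -1, , drop = FALSE] -
                        filt[, -d[2], , drop = FALSE])
    gm <- sqrt(gy^2 + gx^2)
    band_grad <- vapply(best, function(i) {
      hi_edge <- if (i < n_levels) levels[i + 1] else Inf
      sel <- !is.na(filt) & filt >= levels[i] & filt < hi_edge
      if (!any(sel)) 0 else mean(gm[sel], na.rm = TRUE)
    }, 0)
    # lowest level within the sharp-gradient zone: captures the full granule
    # without overestimating the threshold
    chosen <- best[min(which(band_grad >= 0.9 * max(band_grad)))]
  } else {
    chosen <- best
  }
  sweep <- tibble::tibble(level = levels, n_blobs = nb, mean_volume = meanv,
                          median_volume = medv, quality = q)
  discard <- if (max(q) < min_quality) "quality factor below minimum" else NULL
  structure(list(sweep = sweep, chosen_level = chosen,
                 threshold = levels[chosen], q_max = max(q),
                 filtered = filt, discard = discard),
            class = "threshold_sweep")
}

# 8-connected boundary of a 2D pixel set given as a logical matrix
outline_pixels <- function(cs) {
  ny <- nrow(cs); nx <- ncol(cs)
  idx <- which(cs, arr.ind = TRUE)
  is_b <- vapply(seq_len(nrow(idx)), function(k) {
    y <- idx[k, 1]; x <- idx[k, 2]
    ys <- max(1, y - 1):min(ny, y + 1)
    xs <- max(1, x - 1):min(nx, x + 1)
    (length(ys) * length(xs) < 9) || !all(cs[ys, xs])
  }, TRUE)
  idx[is_b, , drop = FALSE]
}

weighted_centroid <- function(idx, w) {
  ok <- is.finite(w) & w > 0
  if (!any(ok)) return(colMeans(idx))
  w <- w[ok]
  colSums(idx[ok, , drop = FALSE] * w) / sum(w)
}

#' Extract granules at the chosen threshold
#'
#' 3D connected components above the threshold become granule candidates.
#' A blob is discarded if the intensity-weighted centroid of its 3-px-sphere
#' dilation moves by more than 0.5 px from that of the original mask, if its
#' dilation fuses with another blob's, if its centroid lies outside the cell
#' footprint or inside the nucleus footprint, or if its effective radius
#' `R_SG = sqrt(A_SG / pi)` is below the 3-px diffraction floor. Geometry
#' (projected area, effective radius, in-plane principal-axis ratio and
#' orientation) and the centroid-plane outline are recorded per granule.
#'
#' @param stack the normalized granule [channel_stack()] (weights for the
#'   centroids).
#' @param sweep result of [preprocess_and_sweep()].
#' @param cell2d,nucleus2d aligned footprint masks.
#' @param dilation_radius sphere radius for the robustness dilation, px.
#' @param max_centroid_shift centroid displacement tolerance, px.
#' @param min_radius_px diffraction floor for `R_SG`, px.
#' @return tibble of granule records (one row each) with list-columns for the
#'   voxel set, centroid-plane cross-section and outline; discarded blobs are
#'   kept with `kept = FALSE` and a reason.
#' @export
extract_granules <- function(stack, sweep, cell2d, nucleus2d,
                             dilation_radius = 3, max_centroid_shift = 0.5,
                             min_radius_px = 3) {
  pitch <- stack$pitch_xy
  filt <- sweep$filtered
  d <- dim(filt)
  bin <- !is.na(filt) & filt > sweep$threshold
  lab <- cpp_label3d(bin, d)
  nblob <- max(lab)
  if (nblob == 0) return(granule_table_empty())
  w <- stack_values(stack)
  # fusion test: label the dilated union; dilated components holding more
  # than one original blob are fused pairs
  dil_all <- cpp_dilate3d(bin, d, dilation_radius)
  lab_dil <- cpp_label3d(dil_all, d)
  fused_of <- tapply(lab_dil[lab > 0], lab[lab > 0], function(x) x[1])
  fused_count <- table(fused_of)
  rows <- vector("list", nblob)
  for (b in seq_len(nblob)) {
    vox <- which(lab == b)
    idx <- arrayInd(vox, d) # y, x, z
    cen <- weighted_centroid(idx, w[vox])
    # dilated centroid within a padded bounding box
    pad <- ceiling(dilation_radius) + 1
    y0 <- max(1, min(idx[, 1]) - pad); y1 <- min(d[1], max(idx[, 1]) + pad)
    x0 <- max(1, min(idx[, 2]) - pad); x1 <- min(d[2], max(idx[, 2]) + pad)
    z0 <- max(1, min(idx[, 3]) - pad); z1 <- min(d[3], max(idx[, 3]) + pad)
    sub <- array(FALSE, c(y1 - y0 + 1, x1 - x0 + 1, z1 - z0 + 1))
    sub[cbind(idx[, 1] - y0 + 1, idx[, 2] - x0 + 1, idx[, 3] - z0 + 1)] <- TRUE
    sub_dil <- cpp_dilate3d(sub, dim(sub), dilation_radius)
    didx <- which(sub_dil, arr.ind = TRUE)
    didx_g <- cbind(didx[, 1] + y0 - 1, didx[, 2] + x0 - 1, didx[, 3] + z0 - 1)
    wd <- w[cbind(didx_g)]
    cen_dil <- weighted_centroid(didx_g, wd)
    shift <- sqrt(sum((cen - cen_dil)^2))
    # projected footprint
    proj <- matrix(FALSE, d[1], d[2])
    proj[unique(cbind(idx[, 1], idx[, 2]), MARGIN = 1)] <- TRUE
    area_px <- sum(proj)
    R_px <- sqrt(area_px / pi)
    pm <- mask_moments(proj)
    e <- if (is.null(pm)) NA_real_ else {
      r <- pm$axis_ratio
      if (r > 0) 1 / r else NA_real_
    }
    zc <- as.integer(round(cen[3]))
    zc <- min(max(zc, 1L), d[3])
    cs <- matrix(FALSE, d[1], d[2])
    inpl <- idx[, 3] == zc
    cs[idx[inpl, 1:2, drop = FALSE]] <- TRUE
    ol <- outline_pixels(cs)
    cyi <- as.integer(round(cen[1])); cxi <- as.integer(round(cen[2]))
    inside_cell <- cyi >= 1 && cyi <= d[1] && cxi >= 1 && cxi <= d[2] &&
      isTRUE(cell2d[cyi, cxi]) && !isTRUE(nucleus2d[cyi, cxi])
    reason <- NA_character_
    if (shift > max_centroid_shift) reason <- "centroid shift"
    else if (fused_count[as.character(fused_of[as.character(b)])] > 1) reason <- "fused on dilation"
    else if (!inside_cell) reason <- "outside cell mask"
    else if (R_px < min_radius_px) reason <- "below diffraction floor"
    rows[[b]] <- tibble::tibble(
      granule = b,
      y = cen[1], x = cen[2], z = cen[3],
      x_um = NA_real_, y_um = NA_real_,
      z_plane = zc,
      volume_vox = length(vox),
      area_um2 = area_px * pitch^2,
      R_um = R_px * pitch,
      R_px = R_px,
      ellipticity = e,
      orientation = if (is.null(pm)) NA_real_ else pm$theta,
      centroid_shift = shift,
      kept = is.na(reason),
      reason = reason,
      voxels = list(idx),
      cross_section = list(which(cs, arr.ind = TRUE)),
      outline = list(ol)
    )
  }
  out <- dplyr::bind_rows(rows)
  out
}

granule_table_empty <- function() {
  tibble::tibble(
    granule = integer(), y = numeric(), x = numeric(), z = numeric(),
    x_um = numeric(), y_um = numeric(), z_plane = integer(),
    volume_vox = integer(), area_um2 = numeric(), R_um = numeric(),
    R_px = numeric(), ellipticity = numeric(), orientation = numeric(),
    centroid_shift = numeric(), kept = logical(), reason = character(),
    voxels = list(), cross_section = list(), outline = list()
  )
}

#' Crop per-channel images centred on a granule
#'
#' Crops of odd size `size` x `size` centred on the granule's rounded
#' centroid pixel at the plane nearest the centroid z; out-of-field regions
#' and voxels outside the cell or inside the nucleus are masked (`NA`).
#'
#' @param record aligned cell (with normalized stacks in `record$norm`).
#' @param granule one row of the granule table.
#' @param size odd crop edge length, px (221 px is about 14 um x 14 um).
#' @return named list of matrices, one per channel, plus the crop origin.
#' @export
crop_granule_images <- function(record, granule, size = 221L) {
  stopifnot(size %% 2 == 1)
  half <- (size - 1L) / 2L
  cy <- as.integer(round(granule$y)); cx <- as.integer(round(granule$x))
  z <- granule$z_plane
  out <- list()
  for (nm in names(record$norm)) {
    v <- stack_values(record$norm[[nm]])
    d <- dim(v)
    m <- matrix(NA_real_, size, size)
    ys <- (cy - half):(cy + half); xs <- (cx - half):(cx + half)
    oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]
    if (any(oky) && any(okx) && z >= 1 && z <= d[3])
      m[which(oky), which(okx)] <- v[ys[oky], xs[okx], z]
    out[[nm]] <- m
  }
  out$origin <- c(y = cy - half, x = cx - half, z = z)
  out
}

#' Brightness filter on reference-normalized granule crops
#'
#' The local environment of a granule is its shape dilated with a disc of
#' radius `env_radius` px minus the shape itself. Granules whose mean relative
#' intensity is not at least `min_contrast` times that of their environment
#' are discarded, as are positive outliers brighter than the ensemble mean
#' plus one standard deviation.
#'
#' @param granules granule tibble with a `rel_crop` list-column of
#'   reference-normalized granule-channel crops and a `crop_shape` list-column
#'   of in-crop cross-section masks.
#' @param env_radius disc radius for the environment, px.
#' @param min_contrast granule/environment contrast floor.
#' @return the tibble with updated `kept`/`reason` and columns
#'   `rel_granule`, `rel_env`.
#' @export
brightness_filter <- function(granules, env_radius = 8, min_contrast = 2) {
  n <- nrow(granules)
  if (n == 0) return(granules)
  rg <- re <- rep(NA_real_, n)
  reason <- granules$reason
  for (i in seq_len(n)) {
    if (!granules$kept[i]) next
    crop <- granules$rel_crop[[i]]
    shape <- granules$crop_shape[[i]]
    arr3 <- array(shape, c(dim(shape), 1))
    env <- cpp_dilate3d(arr3, dim(arr3), env_radius)[, , 1] & !shape
    gvals <- crop[shape]
    evals <- crop[env]
    if (all(is.na(evals))) {
      reason[i] <- "environment fully masked"
      next
    }
    rg[i] <- mean(gvals, na.rm = TRUE)
    re[i] <- mean(evals, na.rm = TRUE)
    if (!is.finite(rg[i]) || !is.finite(re[i]) || rg[i] < min_contrast * re[i])
      reason[i] <- "not twice as bright as environment"
  }
  granules$rel_granule <- rg
  granules$rel_env <- re
  granules$kept <- is.na(reason)
  granules$reason <- reason
  # positive outliers: mean relative intensity above ensemble mean + 1 SD
  ok <- granules$kept & is.finite(granules$rel_granule)
  if (sum(ok) >= 3) {
    mu <- mean(granules$rel_granule[ok]); s <- sd(granules$rel_granule[ok])
    out <- ok & granules$rel_granule > mu + s
    granules$reason[out] <- "positive outlier"
    granules$kept[out] <- FALSE
  }
  granules
}
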