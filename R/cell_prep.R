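# Cell detection, background correction, QC, alignment and intensity
# normalization.

# mask moments: centroid, orientation (deg, major axis vs x, mod 180),
# principal-axis ratio (short/long), area in px
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  dy <- idx[, 1] - cy; dx <- idx[, 2] - cx
  cxx <- mean(dx^2); cyy <- mean(dy^2); cxy <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  l1 <- tr / 2 + sqrt(pmax(0, tr^2 / 4 - det))
  l2 <- tr / 2 - sqrt(pmax(0, tr^2 / 4 - det))
  list(cx = cx, cy = cy, theta = theta,
       axis_ratio = sqrt(max(l2, 0) / max(l1, 1e-12)), area_px = n)
}

max_projection <- function(stack) {
  v <- stack_values(stack)
  apply(v, c(1, 2), function(p) if (all(is.na(p))) NA_real_ else max(p, na.rm = TRUE))
}

unsharp2d <- function(im, sigma = 2, amount = 1) {
  arr <- array(im, c(dim(im), 1))
  bl <- cpp_gauss3d(arr, dim(arr), sigma, sigma, 0, TRUE)[, , 1]
  im + amount * (im - bl)
}

#' Detect the cell footprint and nucleus of one acquisition
#'
#' The footprint is the largest connected component of the sharpened,
#' Otsu-thresholded overlay of the per-channel maximum projections along z;
#' the nucleus mask comes from the nucleus channel. All stacks are cropped
#' around the detected cell with a background rim.
#'
#' @param stacks named list of [channel_stack()]s (signal channels).
#' @param nucleus_stack the nucleus-marker [channel_stack()].
#' @param min_area_um2 minimum footprint area; smaller components mean no
#'   cell was found.
#' @param rim background rim kept around the cell, px.
#' @return list with cropped `stacks`, `cell2d`, `nucleus2d`, `bbox` and a
#'   `discard` reason (`NULL` if kept). Multiple components keep the largest
#'   (one cell per acquisition); the event is reported in `n_components`.
#' @export
detect_footprints <- function(stacks, nucleus_stack, min_area_um2 = 20,
                              rim = 12L) {
  pitch <- stacks[[1]]$pitch_xy
  projs <- lapply(stacks, max_projection)
  nproj <- max_projection(nucleus_stack)
  norm01 <- function(m) {
    m[is.na(m)] <- 0
    rng <- range(m); if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  overlay <- Reduce(`+`, lapply(projs, norm01)) + norm01(nproj)
  if (max(overlay) <= 0) return(list(discard = "no cell"))
  overlay <- overlay / max(overlay)
  sharp <- unsharp2d(overlay)
  sharp <- pmin(pmax(sharp, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(t(sharp)), range = c(0, 1))
  bw <- sharp > thr
  lab <- cpp_label3d(array(bw, c(dim(bw), 1)), c(dim(bw), 1L))[, , 1]
  if (max(lab) == 0) return(list(discard = "no cell"))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  cell2d <- lab == big
  if (sum(cell2d) * pitch^2 < min_area_um2) return(list(discard = "no cell"))
  nthr <- EBImage::otsu(EBImage::Image(t(norm01(nproj))), range = c(0, 1))
  nucleus2d <- norm01(nproj) > nthr & cell2d
  idx <- which(cell2d, arr.ind = TRUE)
  ny <- nrow(cell2d); nx <- ncol(cell2d)
  y0 <- max(1, min(idx[, 1]) - rim); y1 <- min(ny, max(idx[, 1]) + rim)
  x0 <- max(1, min(idx[, 2]) - rim); x1 <- min(nx, max(idx[, 2]) + rim)
  crop <- function(s) {
    s$values <- s$values[y0:y1, x0:x1, , drop = FALSE]
    s$valid <- s$valid[y0:y1, x0:x1, , drop = FALSE]
    s
  }
  list(
    stacks = lapply(stacks, crop),
    nucleus_stack = crop(nucleus_stack),
    cell2d = cell2d[y0:y1, x0:x1],
    nucleus2d = nucleus2d[y0:y1, x0:x1],
    bbox = c(y0, y1, x0, x1),
    n_components = max(lab),
    discard = NULL
  )
}

#' Estimate the cell base height from the filament channel
#'
#' The per-plane summary (median + 80th percentile) is collected along z; the
#' base height is the slice of maximum positive gradient of that profile.
#'
#' @param filament_stack a cropped [channel_stack()].
#' @return list with `z_b` (slice index), `z_peak` (slice of maximum of the
#'   profile) and `profile`; `z_b` is `NA` with a `discard` reason when the
#'   profile has no positive gradient.
#' @export
estimate_base_height <- function(filament_stack) {
  v <- stack_values(filament_stack)
  nz <- dim(v)[3]
  prof <- vapply(seq_len(nz), function(z) {
    p <- v[, , z]
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    median(p) + quantile(p, 0.80, names = FALSE)
  }, 0)
  grad <- diff(prof)
  if (all(is.na(grad)) || max(grad, na.rm = TRUE) <= 0)
    return(list(z_b = NA_integer_, z_peak = NA_integer_, profile = prof,
                discard = "no base-height gradient"))
  z_b <- which.max(grad) + 1L
  z_peak <- which.max(prof)
  list(z_b = z_b, z_peak = z_peak, profile = prof, discard = NULL)
}

#' Subtract constant corner background from a stack
#'
#' The background is the mean intensity of four fixed-size corner patches of
#' the cropped image that lie outside the detected cell; corners intersecting
#' the cell are skipped, and if all four intersect the stack is returned
#' unchanged with a warning. Negative values are clipped at zero.
#'
#' @param stack a cropped [channel_stack()].
#' @param cell2d the cell footprint mask of the crop.
#' @param patch corner patch edge length, px.
#' @return the background-corrected stack (attribute `background` records the
#'   subtracted offset).
#' @export
subtract_corner_background <- function(stack, cell2d, patch = 10L) {
  d <- dim(stack$values)
  ny <- d[1]; nx <- d[2]
  pys <- list(1:patch, (ny - patch + 1):ny)
  pxs <- list(1:patch, (nx - patch + 1):nx)
  vals <- c()
  for (py in pys) for (px in pxs) {
    if (any(cell2d[py, px])) next
    vals <- c(vals, as.numeric(stack$values[py, px, ]))
  }
  if (!length(vals)) {
    warning("all corner patches intersect the cell; background not subtracted")
    attr(stack, "background") <- 0
    return(stack)
  }
  b <- mean(vals, na.rm = TRUE)
  stack$values <- pmax(stack$values - b, 0)
  attr(stack, "background") <- b
  stack
}

circular_mean_180 <- function(theta_deg) {
  a <- theta_deg * pi / 90 # angle doubled, in radians
  0.5 * atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
}

warp_stack <- function(stack, theta, centre_yx, shift_yx, canvas) {
  d <- dim(stack$values)
  nz <- d[3]
  vals <- array(NA_real_, c(canvas[1], canvas[2], nz))
  pad <- array(NA_real_, c(canvas[1], canvas[2]))
  for (z in seq_len(nz)) {
    sl <- pad
    sl[seq_len(min(d[1], canvas[1])), seq_len(min(d[2], canvas[2]))] <-
      stack_values(stack)[seq_len(min(d[1], canvas[1])),
                          seq_len(min(d[2], canvas[2])), z]
    vals[, , z] <- cpp_warp2d(sl, theta, centre_yx[1], centre_yx[2],
                              shift_yx[1], shift_yx[2])
  }
  channel_stack(vals, pitch_xy = stack$pitch_xy, z_step = stack$z_step,
                channel = stack$channel)
}

warp_mask <- function(mask, theta, centre_yx, shift_yx, canvas) {
  pad <- matrix(0, canvas[1], canvas[2])
  pad[seq_len(min(nrow(mask), canvas[1])),
      seq_len(min(ncol(mask), canvas[2]))] <-
    mask[seq_len(min(nrow(mask), canvas[1])),
         seq_len(min(ncol(mask), canvas[2]))] * 1.0
  w <- cpp_warp2d(pad, theta, centre_yx[1], centre_yx[2],
                  shift_yx[1], shift_yx[2])
  !is.na(w) & w >= 0.5
}

flip180 <- function(arr) {
  if (length(dim(arr)) == 3) arr[rev(seq_len(dim(arr)[1])), rev(seq_len(dim(arr)[2])), , drop = FALSE]
  else arr[rev(seq_len(nrow(arr))), rev(seq_len(ncol(arr)))]
}

#' Quality-filter and align a batch of candidate cells
#'
#' Computes the batch orientation as the circular mean of the cells' long-axis
#' angles (mod 180 deg), discards cells violating the area window, the
#' principal-axis-ratio window, the orientation tolerance or the base-height /
#' peak-slice interval, rotates survivors to horizontal, centres them on a
#' common canvas and flips them so the nucleus centroid falls in the left
#' hemisphere. A batch with fewer than `min_batch` survivors is discarded
#' entirely.
#'
#' @param cells list of candidates: each a list from [detect_footprints()]
#'   augmented with `z_b`/`z_peak` from [estimate_base_height()] and an `id`.
#' @param area_target nominal pattern area, um^2 (the experimental constant is
#'   1257; synthetic batches pass the scaled value).
#' @param area_window keep cells with area in `area_window * area_target`.
#' @param ratio_window principal-axis short/long ratio window.
#' @param max_orientation_dev maximum deviation from the batch orientation, deg.
#' @param peak_interval allowed `z_peak - z_b` interval (slices).
#' @param min_batch minimum surviving cells per batch.
#' @param canvas c(ny, nx) of the aligned frame all cells are embedded in.
#' @return list with `records` (aligned cells) and `qc` (per-cell tibble with
#'   kept flag and discard reason).
#' @export
qc_and_align <- function(cells, area_target = 1257,
                         area_window = c(0.85, 1.10),
                         ratio_window = c(0.43, 0.55),
                         max_orientation_dev = 3,
                         peak_interval = c(2, 4),
                         min_batch = 10,
                         canvas = c(256L, 256L)) {
  pitch <- cells[[1]]$stacks[[1]]$pitch_xy
  mom <- lapply(cells, function(cl) mask_moments(cl$cell2d))
  qc <- tibble::tibble(
    id = vapply(cells, function(cl) cl$id, 0L),
    area_um2 = vapply(mom, function(m) m$area_px, 0) * pitch^2,
    axis_ratio = vapply(mom, function(m) m$axis_ratio, 0),
    orientation = vapply(mom, function(m) m$theta, 0),
    z_b = vapply(cells, function(cl) as.integer(cl$z_b %||% NA), 0L),
    z_peak = vapply(cells, function(cl) as.integer(cl$z_peak %||% NA), 0L)
  )
  batch_theta <- circular_mean_180(qc$orientation)
  reason <- rep(NA_character_, nrow(qc))
  dev <- (qc$orientation - batch_theta + 90) %% 180 - 90
  reason[is.na(qc$z_b)] <- "no base height"
  ok_peak <- !is.na(qc$z_b) &
    (qc$z_peak - qc$z_b) >= peak_interval[1] &
    (qc$z_peak - qc$z_b) <= peak_interval[2]
  reason[is.na(reason) & !ok_peak] <- "peak slice outside interval"
  ok_area <- qc$area_um2 >= area_window[1] * area_target &
    qc$area_um2 <= area_window[2] * area_target
  reason[is.na(reason) & !ok_area] <- "area"
  ok_ratio <- qc$axis_ratio >= ratio_window[1] & qc$axis_ratio <= ratio_window[2]
  reason[is.na(reason) & !ok_ratio] <- "axis ratio"
  reason[is.na(reason) & abs(dev) > max_orientation_dev] <- "orientation"
  keep <- is.na(reason)
  if (sum(keep) < min_batch) {
    reason[keep] <- "batch too small"
    keep[] <- FALSE
  }
  qc$kept <- keep
  qc$reason <- reason
  records <- list()
  ctr <- c((canvas[1] + 1) / 2, (canvas[2] + 1) / 2)
  for (i in which(keep)) {
    cl <- cells[[i]]
    m <- mom[[i]]
    shift <- c(ctr[1] - m$cy, ctr[2] - m$cx)
    theta <- -batch_theta
    stacks <- lapply(cl$stacks, warp_stack, theta = theta,
                     centre_yx = c(m$cy, m$cx), shift_yx = shift,
                     canvas = canvas)
    cell2d <- warp_mask(cl$cell2d, theta, c(m$cy, m$cx), shift, canvas)
    nucleus2d <- warp_mask(cl$nucleus2d, theta, c(m$cy, m$cx), shift, canvas)
    nm <- mask_moments(nucleus2d)
    flipped <- FALSE
    if (!is.null(nm) && nm$cx > ctr[2]) {
      stacks <- lapply(stacks, function(s) {
        s$values <- flip180(s$values); s$valid <- flip180(s$valid); s
      })
      cell2d <- flip180(cell2d); nucleus2d <- flip180(nucleus2d)
      flipped <- TRUE
    }
    records[[length(records) + 1]] <- list(
      id = cl$id, stacks = stacks, cell2d = cell2d, nucleus2d = nucleus2d,
      z_b = cl$z_b, orientation = batch_theta, flipped = flipped,
      area_um2 = qc$area_um2[i], axis_ratio = qc$axis_ratio[i]
    )
  }
  list(records = records, qc = qc, batch_orientation = batch_theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a channel of an aligned cell by its mean intensity
#'
#' The mean intensity is taken over representative voxels: inside the cell
#' footprint, outside the nucleus, at the second to fourth slice above the
#' cell base height. The channel is divided by this mean and voxels outside
#' the cell or inside the nucleus are masked for all downstream use.
#'
#' @param record an aligned cell from [qc_and_align()].
#' @param channel channel name in `record$stacks`.
#' @return list with the normalized [channel_stack()] and `I_mean`; `NULL`
#'   (discard) if the mean is non-positive.
#' @export
normalize_channel <- function(record, channel) {
  s <- record$stacks[[channel]]
  d <- dim(s$values)
  zset <- record$z_b + 2:4
  zset <- zset[zset >= 1 & zset <= d[3]]
  rep_mask <- record$cell2d & !record$nucleus2d
  v <- stack_values(s)
  vals <- c()
  for (z in zset) {
    sl <- v[, , z]
    vals <- c(vals, sl[rep_mask])
  }
  I_mean <- mean(vals, na.rm = TRUE)
  if (!is.finite(I_mean) || I_mean <= 0) return(NULL)
  s$values <- s$values / I_mean
  keep <- array(rep(rep_mask, d[3]), d)
  s <- mask_stack(s, keep)
  list(stack = s, I_mean = I_mean)
}
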