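# Distribution maps, radial and surface-relative profiles, negative control
# and voxel-wise cross-correlation.

#' Normalize a granule crop by the matching reference crop
#'
#' Point-wise ratio in units of relative intensity (1 = as expected in the
#' reference cell). A pixel is masked if it is masked in either input; valid
#' reference pixels equal to zero are masked with a warning.
#'
#' @param crop granule-centred image (matrix, `NA` = masked).
#' @param ref_crop matching reference crop.
#' @return relative-intensity matrix.
#' @export
normalize_granule_image <- function(crop, ref_crop) {
  stopifnot(identical(dim(crop), dim(ref_crop)))
  bad <- !is.na(ref_crop) & ref_crop == 0 & !is.na(crop)
  if (any(bad)) warning("reference crop contains zero-valued valid pixels; masked")
  out <- crop / ref_crop
  out[bad] <- NA_real_
  out
}

#' Bin granules by size and shape
#'
#' Round granules (principal-axis ratio at most `round_max`) are binned by
#' radius in steps of `step_px` pixels; the first bin starts at the 3-px
#' diffraction floor, so bin k covers `[3k, 3(k+1))` px and is labelled by its
#' central pixel `(3k + 1) px` (the first bin label is 0.26 um at 0.065 um/px).
#' Elongated granules are sub-binned by their axis ratio.
#'
#' @param granules granule tibble (columns `R_px`, `ellipticity`).
#' @param step_px radius bin width, px.
#' @param round_max maximum axis ratio of the round class.
#' @param e_step axis-ratio bin width for elongated granules.
#' @param pitch pixel pitch, um/px.
#' @return the tibble with `shape_class`, `radius_bin` (label, um) and
#'   `e_bin` columns.
#' @export
bin_granules <- function(granules, step_px = 3, round_max = 1.5, e_step = 0.5,
                         pitch = 0.065) {
  k <- floor(granules$R_px / step_px)
  granules$radius_bin <- (step_px * k + 1) * pitch
  granules$shape_class <- ifelse(granules$ellipticity <= round_max,
                                 "round", "elongated")
  granules$e_bin <- ifelse(
    granules$shape_class == "elongated",
    round_max + e_step * floor((granules$ellipticity - round_max) / e_step) +
      e_step / 2,
    NA_real_)
  granules
}

#' Average granule-centred images into a map
#'
#' Per-pixel mean over unmasked contributors, with contributor counts. In
#' `"averaged"` mode the inputs are plain intensity crops; in
#' `"distribution"` mode they are reference-normalized crops and the result
#' is a distribution map in relative-intensity units. With `rotate = TRUE`
#' each crop is first rotated so the granule's major principal axis is
#' vertical.
#'
#' @param crops list of matrices (one granule each).
#' @param orientations granule in-plane orientations (deg), used if `rotate`.
#' @param mode `"averaged"` or `"distribution"`.
#' @param rotate rotate crops to a common principal-axis frame first.
#' @return list of class `distribution_map`: `values`, `count`, `mode`, `n`.
#' @export
make_maps <- function(crops, orientations = NULL,
                      mode = c("distribution", "averaged"), rotate = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(crops) >= 1)
  d <- dim(crops[[1]])
  ctr <- (d + 1) / 2
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (i in seq_along(crops)) {
    m <- crops[[i]]
    if (rotate) {
      th <- 90 - orientations[i]
      m <- cpp_warp2d(m, th, ctr[1], ctr[2], 0, 0)
    }
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  vals <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(values = vals, count = cnt, mode = mode, n = length(crops)),
            class = "distribution_map")
}

# per-pixel radius map (px) about the crop centre
crop_radius_px <- function(d) {
  ctr <- (d + 1) / 2
  yy <- matrix(seq_len(d[1]) - ctr[1], d[1], d[2])
  xx <- matrix(rep(seq_len(d[2]) - ctr[2], each = d[1]), d[1], d[2])
  sqrt(yy^2 + xx^2)
}

#' Radial distribution function g(r) of a set of normalized crops
#'
#' Averages relative intensities over all contributing pixels of all crops at
#' distance r from the granule centre (1-px bins), rather than azimuthally
#' averaging the map, so varying per-pixel contributor counts are weighted
#' correctly. The standard error is SD/sqrt(n) per bin.
#'
#' @param crops list of reference-normalized crops.
#' @param pitch pixel pitch, um/px.
#' @param r_max_px largest radius bin, px.
#' @return tibble of class `radial_profile`: `r_um`, `g`, `se`, `n`.
#' @export
radial_profile <- function(crops, pitch = 0.065, r_max_px = 110) {
  d <- dim(crops[[1]])
  rmap <- round(crop_radius_px(d))
  keep <- rmap <= r_max_px
  bins <- 0:r_max_px
  sums <- sqs <- ns <- numeric(length(bins))
  for (m in crops) {
    ok <- keep & !is.na(m)
    if (!any(ok)) next
    b <- rmap[ok] + 1L
    v <- m[ok]
    sums <- sums + unname(tapply2(v, b, length(bins), sum))
    sqs <- sqs + unname(tapply2(v^2, b, length(bins), sum))
    ns <- ns + unname(tapply2(rep(1, length(v)), b, length(bins), sum))
  }
  g <- ifelse(ns > 0, sums / ns, NA_real_)
  varv <- ifelse(ns > 1, pmax(0, (sqs - ns * g^2) / (ns - 1)), NA_real_)
  out <- tibble::tibble(r_um = bins * pitch, g = g,
                        se = sqrt(varv / pmax(ns, 1)), n = as.integer(ns))
  class(out) <- c("radial_profile", class(out))
  out
}

# grouped sum over integer bins 1..nb
tapply2 <- function(v, b, nb, fun) {
  out <- numeric(nb)
  s <- rowsum(v, b)
  out[as.integer(rownames(s))] <- s
  out
}

#' Running peak summaries of g(r) across granule radius
#'
#' For each requested radius, pools crops of granules whose radius lies within
#' +/- `window_um`, computes g(r), and records the peak height `g_max` and
#' peak position `r_max`.
#'
#' @param granules granule tibble with a `rel_crop_tub` list-column.
#' @param radii_um radii at which to evaluate the running average.
#' @param window_um half-width of the running window, um.
#' @param pitch pixel pitch um/px.
#' @return tibble: `R_um`, `g_max`, `r_max_um`, `n_granules`.
#' @export
running_peak_summary <- function(granules, radii_um, window_um = 0.065,
                                 pitch = 0.065) {
  rows <- lapply(radii_um, function(R) {
    sel <- abs(granules$R_um - R) <= window_um
    if (!any(sel)) return(NULL)
    prof <- radial_profile(granules$rel_crop_tub[sel], pitch = pitch)
    i <- which.max(prof$g)
    tibble::tibble(R_um = R, g_max = prof$g[i], r_max_um = prof$r_um[i],
                   n_granules = sum(sel))
  })
  dplyr::bind_rows(rows)
}

#' Surface-relative distribution function g_s(d) of one granule
#'
#' The signed distance d of each pixel is the minimal Euclidean distance to
#' the detected granule outline (2D distance transform in the centroid
#' plane), negative inside the filled cross-section and zero on the outline.
#' g_s(d) is the mean relative intensity over pixels sharing a 1-px-wide
#' d-bin, with standard errors.
#'
#' @param granule one granule row (list-columns `cross_section`, `outline`,
#'   and the crop origin must be consistent with `crop`).
#' @param crop reference-normalized crop (any channel).
#' @param origin crop origin `c(y, x, z)`.
#' @param pitch pixel pitch, um/px.
#' @param d_max_px furthest distance bin, px.
#' @return tibble of class `surface_profile`: `d_um`, `g_s`, `se`, `n`.
#' @export
surface_profile <- function(granule, crop, origin, pitch = 0.065,
                            d_max_px = 30) {
  d <- dim(crop)
  ol <- granule$outline[[1]]
  cs <- granule$cross_section[[1]]
  oy <- ol[, 1] - origin["y"] + 1L; ox <- ol[, 2] - origin["x"] + 1L
  keep <- oy >= 1 & oy <= d[1] & ox >= 1 & ox <= d[2]
  if (!any(keep)) stop("granule outline outside crop")
  img <- matrix(1, d[1], d[2])
  img[cbind(oy[keep], ox[keep])] <- 0
  dist <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(img)))))
  inside <- matrix(FALSE, d[1], d[2])
  cy <- cs[, 1] - origin["y"] + 1L; cx <- cs[, 2] - origin["x"] + 1L
  okc <- cy >= 1 & cy <= d[1] & cx >= 1 & cx <= d[2]
  inside[cbind(cy[okc], cx[okc])] <- TRUE
  sgn <- ifelse(inside, -1, 1)
  sdist <- sgn * dist
  sdist[cbind(oy[keep], ox[keep])] <- 0
  b <- round(sdist)
  ok <- !is.na(crop) & abs(b) <= d_max_px
  db <- b[ok]; v <- crop[ok]
  agg <- tibble::tibble(d_px = db, v = v) |>
    dplyr::group_by(.data$d_px) |>
    dplyr::summarise(g_s = mean(.data$v), se = sd(.data$v) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$d_px)
  out <- tibble::tibble(d_um = agg$d_px * pitch, g_s = agg$g_s, se = agg$se,
                        n = agg$n)
  class(out) <- c("surface_profile", class(out))
  out
}

#' Computational negative control: sample crops from a different cell
#'
#' For each granule, both channels are extracted at the same aligned
#' coordinates from a uniformly chosen different cell, reference-normalized
#' and averaged into maps; structural correlations are destroyed while all
#' systematic intensity variation is retained.
#'
#' @param granules granule tibble (with `cell`, `y`, `x`, `z_plane`).
#' @param records aligned cells (with `$norm`).
#' @param refs named list of references per channel.
#' @param channels channels to process.
#' @param size crop size, px.
#' @return named list of `distribution_map`s.
#' @export
negative_control <- function(granules, records, refs,
                             channels = c("granule", "tubulin"), size = 221L) {
  if (length(records) < 2) stop("negative control needs at least two cells")
  n <- nrow(granules)
  crops <- lapply(channels, function(ch) vector("list", n))
  names(crops) <- channels
  for (i in seq_len(n)) {
    g <- granules[i, ]
    other <- sample(setdiff(seq_along(records), g$cell), 1)
    rec <- records[[other]]
    fake <- crop_granule_images(rec, g, size = size)
    for (ch in channels) {
      refc <- lookup_reference(refs[[ch]], rec, fake$origin, size = size)
      crops[[ch]][[i]] <- if (is.null(refc)) NULL
        else normalize_granule_image(fake[[ch]], refc)
    }
  }
  lapply(crops, function(cl) {
    cl <- cl[!vapply(cl, is.null, TRUE)]
    make_maps(cl, mode = "distribution")
  })
}

#' Voxel-wise cross-correlation between two normalized channels
#'
#' Pearson correlation over co-valid voxels per cell and pooled; cells with
#' fewer than `min_voxels` valid voxels are skipped.
#'
#' @param records aligned cells with `$norm`.
#' @param channels the two channel names.
#' @param min_voxels minimum co-valid voxels per cell.
#' @return tibble with one row per cell plus a pooled row (`cell = NA`).
#' @export
voxel_cross_correlation <- function(records, channels = c("granule", "tubulin"),
                                    min_voxels = 100) {
  rows <- list()
  all_a <- all_b <- list()
  for (i in seq_along(records)) {
    a <- stack_values(records[[i]]$norm[[channels[1]]])
    b <- stack_values(records[[i]]$norm[[channels[2]]])
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_voxels) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      cell = i, rho = cor(a[ok], b[ok]), n_voxels = sum(ok))
    all_a[[length(all_a) + 1]] <- a[ok]
    all_b[[length(all_b) + 1]] <- b[ok]
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out))
    out <- dplyr::bind_rows(out, tibble::tibble(
      cell = NA_integer_,
      rho = cor(unlist(all_a), unlist(all_b)),
      n_voxels = length(unlist(all_a))))
  out
}
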