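#' Channel stack: a 3D intensity grid with validity mask and voxel metadata
#'
#' The universal carrier between pipeline stages. Values are stored as a 3D
#' array indexed `[y, x, z]` (row, column, slice). Voxels flagged invalid are
#' excluded from every downstream mean, maximum, gradient and count; the
#' contract is enforced by [stack_values()], which is the only accessor the
#' pipeline uses.
#'
#' @param values numeric 3D array `[y, x, z]`.
#' @param valid logical array of the same dimension (default: all valid,
#'   with `NA` values marked invalid).
#' @param pitch_xy lateral pixel pitch in micrometres per pixel.
#' @param z_step axial slice spacing in micrometres.
#' @param channel channel label (e.g. `"granule"`, `"tubulin"`, `"nucleus"`).
#' @return A `channel_stack` object.
#' @export
channel_stack <- function(values, valid = NULL, pitch_xy = 0.065,
                          z_step = 0.200, channel = "unnamed") {
  stopifnot(length(dim(values)) == 3, pitch_xy > 0, z_step > 0)
  if (is.null(valid)) {
    valid <- !is.na(values)
  } else {
    stopifnot(identical(dim(valid), dim(values)))
    valid <- valid & !is.na(values)
  }
  structure(
    list(values = values, valid = valid, pitch_xy = pitch_xy,
         z_step = z_step, channel = channel),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<channel_stack '%s' %d x %d x %d, %.3f um/px, dz = %.3f um, %.1f%% valid>\n",
    x$channel, d[1], d[2], d[3], x$pitch_xy, x$z_step,
    100 * mean(x$valid)))
  invisible(x)
}

#' Masked values of a channel stack
#'
#' Returns the intensity array with invalid voxels set to `NA`. All pipeline
#' statistics are computed from this accessor, which is what guarantees the
#' masked-voxel contract.
#'
#' @param stack a [channel_stack()].
#' @return numeric 3D array with `NA` at invalid voxels.
#' @export
stack_values <- function(stack) {
  v <- stack$values
  v[!stack$valid] <- NA_real_
  v
}

#' Restrict the validity mask of a stack
#'
#' @param stack a [channel_stack()].
#' @param keep logical array; voxels where `keep` is `FALSE` become invalid.
#' @return the stack with an intersected mask.
#' @export
mask_stack <- function(stack, keep) {
  stopifnot(identical(dim(keep), dim(stack$values)))
  stack$valid <- stack$valid & keep
  stack
}

#' Write a multi-channel acquisition to disk
#'
#' Each channel is written as a multi-page 32-bit float TIFF
#' (`<prefix>_<channel>.tif`, one page per z-slice) together with a JSON
#' sidecar `<prefix>_meta.json` holding the pixel pitch, z-step and channel
#' labels. Invalid voxels are stored as `NaN`.
#'
#' @param stacks named list of [channel_stack()] objects sharing a shape.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the paths written.
#' @export
write_acquisition <- function(stacks, prefix) {
  stopifnot(length(stacks) >= 1)
  dims <- lapply(stacks, function(s) dim(s$values))
  if (length(unique(dims)) != 1) stop("channel stacks differ in shape")
  paths <- character(0)
  scales <- list()
  for (nm in names(stacks)) {
    s <- stacks[[nm]]
    v <- stack_values(s)
    # TIFF stores [0, 1]; carry the intensity scale in the sidecar and the
    # validity mask as a companion file
    vmax <- max(v, 0, na.rm = TRUE)
    if (vmax <= 0) vmax <- 1
    scales[[nm]] <- vmax
    pages <- lapply(seq_len(dim(v)[3]), function(z) {
      m <- v[, , z] / vmax
      m[is.na(m)] <- 0
      m
    })
    mpages <- lapply(seq_len(dim(v)[3]), function(z) (s$valid[, , z]) * 1.0)
    p <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 32L, reduce = FALSE)
    tiff::writeTIFF(mpages, paste0(prefix, "_", nm, "_mask.tif"),
                    bits.per.sample = 8L, reduce = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    pitch_xy = stacks[[1]]$pitch_xy,
    z_step = stacks[[1]]$z_step,
    channels = names(stacks),
    scales = scales
  )
  mp <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a multi-channel acquisition
#'
#' Reads the channel TIFFs and JSON sidecar written by [write_acquisition()].
#' `NaN` voxels become invalid. If the sidecar is missing, the default pixel
#' pitch (0.065 um) and z-step (0.200 um) are assumed with a warning.
#'
#' @param prefix path prefix used at write time.
#' @param channels channels to read; default: those listed in the sidecar.
#' @return named list of [channel_stack()] objects.
#' @export
read_acquisition <- function(prefix, channels = NULL) {
  mp <- paste0(prefix, "_meta.json")
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar at ", mp,
            "; assuming default pixel pitch 0.065 um and z-step 0.200 um")
    meta <- list(pitch_xy = 0.065, z_step = 0.200, channels = channels)
  }
  if (is.null(channels)) channels <- meta$channels
  if (is.null(channels)) stop("no channel list available")
  out <- list()
  shape <- NULL
  for (nm in channels) {
    p <- paste0(prefix, "_", nm, ".tif")
    if (!file.exists(p)) stop("missing channel file for '", nm, "': ", p)
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(shape)) shape <- dim(arr)
    if (!identical(shape, dim(arr)))
      stop("channel '", nm, "' shape mismatch with previous channels")
    vmax <- meta$scales[[nm]]
    if (!is.null(vmax)) arr <- arr * vmax
    mp <- paste0(prefix, "_", nm, "_mask.tif")
    valid <- NULL
    if (file.exists(mp)) {
      mpages <- tiff::readTIFF(mp, all = TRUE)
      if (!is.list(mpages)) mpages <- list(mpages)
      valid <- array(unlist(mpages), dim = shape) > 0.5
      arr[!valid] <- NA_real_
    }
    out[[nm]] <- channel_stack(arr, valid = valid, pitch_xy = meta$pitch_xy,
                               z_step = meta$z_step, channel = nm)
  }
  out
}

#' Write tabular pipeline results to CSV
#'
#' Thin wrapper ensuring a header-only file for empty tables and documented,
#' stable column order.
#'
#' @param records a data frame (granule table, profiles, partition results,
#'   fit summary, ...).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}
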