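#' Multi-channel 3D image stack
#'
#' Container for a confocal stack: a numeric array of non-negative
#' intensities with dimensions `height x width x planes x channels`, plus
#' channel names and an optional physical voxel size.  This is the raw
#' measured object of the imaging arm; all segmentation and measurement
#' operations consume it.
#'
#' @param voxels numeric array, `height x width x planes x channels`,
#'   finite and non-negative.
#' @param channel_names character vector, one name per channel
#'   (default `c("tumor", "neuronal")`).
#' @param voxel_size optional numeric length-3 vector (dy, dx, dz) in
#'   microns; metadata only, not used in any computation.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_names = c("tumor", "neuronal"),
                        voxel_size = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop_config("voxels must be a 4-d array (height x width x planes x channels)")
  d <- dim(voxels)
  if (d[3] < 1L) stop_config("stack must contain at least one plane")
  if (length(channel_names) != d[4])
    stop_config("channel_names length (%d) does not match channel dimension (%d)",
                length(channel_names), d[4])
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop_data("stack contains non-finite intensities")
  if (any(voxels < 0)) stop_data("stack contains negative intensities")
  structure(list(voxels = voxels,
                 channel_names = as.character(channel_names),
                 voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d pixels, %d planes, channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_planes <- function(stack) dim(stack$voxels)[3]

#' Resolve a channel name or index to an index
#' @noRd
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > dim(stack$voxels)[4])
      stop_config("channel index %d out of range", ch)
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch))
    stop_config("unknown channel '%s' (available: %s)", channel,
                paste(stack$channel_names, collapse = ", "))
  ch
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are plane-major with channels interleaved (page = (plane-1) *
#' n_channels + channel).  Intensities are stored as 32-bit float after
#' division by a scale factor (the stack maximum, recorded in the sidecar),
#' because baseline TIFF float samples are written in `[0, 1]`.  The sidecar
#' `<path>.json` records dimensions, channel layout, channel names and the
#' scale, so [read_stack_tiff()] restores the stack (to ~7 significant
#' digits).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (p in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      pages[[k]] <- stack$voxels[, , p, ch] / scale
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(height = d[1], width = d[2], n_planes = d[3],
               n_channels = d[4], channel_names = stack$channel_names,
               layout = "plane-major, channel-interleaved",
               intensity_scale = scale, voxel_size = stack$voxel_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop_data("stack file not found: %s", path)
  if (!file.exists(sidecar)) stop_data("sidecar metadata not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$height, meta$width, meta$n_planes, meta$n_channels)
  if (length(pages) != d[3] * d[4])
    stop_data("TIFF page count (%d) does not match sidecar (%d planes x %d channels)",
              length(pages), d[3], d[4])
  vox <- array(0, dim = d)
  k <- 1L
  for (p in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      vox[, , p, ch] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  vox[vox < 0] <- 0
  image_stack(vox, channel_names = meta$channel_names,
              voxel_size = meta$voxel_size)
}
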