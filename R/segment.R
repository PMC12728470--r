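## Otsu threshold of a numeric vector (EBImage histogram implementation).
## Returns NA for (near-)constant input.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) <= 0) return(NA_real_)
  img <- EBImage::Image(matrix((x - rng[1]) / diff(rng), nrow = 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

## Per-plane Otsu thresholds of a 3D array in one multi-frame EBImage call.
## Constant planes get NA.
otsu_threshold_planes <- function(a, levels = 256L) {
  rng <- range(a)
  np <- dim(a)[3]
  if (!all(is.finite(rng)) || diff(rng) <= 0) return(rep(NA_real_, np))
  img <- EBImage::Image((a - rng[1]) / diff(rng))
  th <- rng[1] + EBImage::otsu(img, range = c(0, 1), levels = levels) * diff(rng)
  ## flag constant planes (otsu output is meaningless there)
  mat <- matrix(a, ncol = np)
  cmin <- apply(mat, 2, min); cmax <- apply(mat, 2, max)
  th[cmax <= cmin] <- NA_real_
  th
}

## fill holes per plane (one EBImage call for the whole stack)
fill_holes_stack <- function(mask) {
  EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
}

## keep the largest connected component per plane (labels restart per frame)
largest_component_stack <- function(mask) {
  if (!any(mask)) return(mask)
  d <- dim(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  k <- max(lab) + 1L
  off <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2]) * k
  glab <- as.integer(lab) + off            # globally unique labels, 0 = bg per plane
  counts <- tabulate(glab[lab > 0], nbins = d[3] * k)
  keep <- logical(d[3] * k)
  for (p in seq_len(d[3])) {
    idx <- (p - 1L) * k + seq_len(k - 1L)  # labels 1..k-1 of plane p
    cc <- counts[idx]
    if (any(cc > 0)) keep[idx[which.max(cc)]] <- TRUE
  }
  out <- array(lab > 0 & keep[pmax(glab, 1L)], dim = d)
  out
}

#' Segment the organoid in a 3D stack
#'
#' Per-plane global thresholding (Otsu by default) of the channel sum,
#' followed by hole filling and retention of the largest connected component
#' in each plane.  Per-plane thresholds let the segmentation adapt to
#' depth-dependent intensity, but a plane's Otsu split is only trusted when
#' it is consistent with the whole-stack Otsu threshold
#' (`consistency_band`, default within 0.5x-2x of the global value):
#' planes whose histograms lack a clear background/tissue split — planes
#' with little tissue, or planes where a small very bright structure makes
#' Otsu separate bright-vs-rest instead of tissue-vs-background — inherit
#' the global threshold instead.  A single 3D global threshold
#' (`scope = "global"`) and a fixed numeric threshold are available as
#' alternatives.
#'
#' An all-zero (or constant) stack yields an empty mask with a warning, not
#' an error.
#'
#' @param stack an [image_stack()].
#' @param scope `"plane"` (default) or `"global"` Otsu scope.
#' @param consistency_band numeric length-2: multiples of the global Otsu
#'   threshold within which a per-plane threshold is accepted; outside the
#'   band (or for constant planes) the global threshold is used.
#' @param threshold optional fixed threshold overriding Otsu entirely.
#' @param fill_holes,largest_component per-plane post-processing toggles.
#' @return logical array (height x width x planes): the organoid mask, with
#'   attributes `thresholds` (per-plane) and `method`.
#' @export
segment_organoid <- function(stack, scope = c("plane", "global"),
                             consistency_band = c(0.5, 2), threshold = NULL,
                             fill_holes = TRUE, largest_component = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  scope <- match.arg(scope)
  d <- dim(stack$voxels)
  np <- d[3]
  ## sum across channels: the organoid is whatever carries any signal
  sumimg <- array(0, dim = d[1:3])
  for (ch in seq_len(d[4]))
    sumimg <- sumimg + array(stack$voxels[, , , ch], dim = d[1:3])

  if (diff(range(sumimg)) <= 0) {
    warning("constant stack: returning empty organoid mask")
    mask <- array(FALSE, dim = d[1:3])
    attr(mask, "thresholds") <- rep(NA_real_, np)
    attr(mask, "method") <- "constant"
    return(mask)
  }

  if (!is.null(threshold)) {
    thr <- rep(threshold, np)
    method <- "fixed"
  } else if (scope == "global") {
    thr <- rep(otsu_threshold(as.vector(sumimg)), np)
    method <- "otsu-global"
  } else {
    gthr <- otsu_threshold(as.vector(sumimg))
    thr <- otsu_threshold_planes(sumimg)
    bad <- is.na(thr) | thr < consistency_band[1] * gthr |
      thr > consistency_band[2] * gthr
    thr[bad] <- gthr
    method <- "otsu-plane-consistent"
  }

  mask <- sumimg > rep(thr, each = d[1] * d[2])
  dim(mask) <- d[1:3]
  if (any(mask)) {
    if (fill_holes) mask <- fill_holes_stack(mask)
    if (largest_component) mask <- largest_component_stack(mask)
  }
  attr(mask, "thresholds") <- thr
  attr(mask, "method") <- method
  mask
}

#' Segment tumor areas within the organoid
#'
#' Thresholds the tumor-marker channel restricted to organoid voxels (Otsu
#' by default, or a fixed threshold), intersects the result with the
#' organoid mask, and fills holes per plane.  All connected components are
#' kept (tumors form multiple foci).
#'
#' A weak-contrast guard rejects thresholds that merely split noise: the
#' threshold must exceed the median within-organoid tumor-channel intensity
#' by at least `min_contrast_sd` noise SDs, where the noise SD is estimated
#' from out-of-organoid voxels (97.5th percentile / 1.96, robust to the
#' zero-clipping of dark background).  Failing the guard yields an empty
#' tumor mask, the correct call when treatment has eliminated the tumor
#' signal.
#'
#' @param stack an [image_stack()].
#' @param organoid_mask logical array from [segment_organoid()].
#' @param channel tumor channel name or index (default `"tumor"`).
#' @param threshold optional fixed threshold (disables Otsu and the guard).
#' @param min_contrast_sd contrast guard in noise SD units (default 1.5).
#' @param fill_holes fill holes per plane (default `TRUE`).
#' @return logical array: tumor mask, a subset of `organoid_mask`, with
#'   attributes `threshold` and `method`.
#' @export
segment_tumor_areas <- function(stack, organoid_mask, channel = "tumor",
                                threshold = NULL, min_contrast_sd = 1.5,
                                fill_holes = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (!identical(dim(organoid_mask)[1:3], d[1:3]))
    stop_data("organoid mask shape does not match stack")
  ch <- channel_index(stack, channel)
  tum <- array(stack$voxels[, , , ch], dim = d[1:3])

  empty <- array(FALSE, dim = d[1:3])
  attr(empty, "threshold") <- NA_real_
  if (!any(organoid_mask)) {
    attr(empty, "method") <- "empty-organoid"
    return(empty)
  }

  inside <- tum[organoid_mask]
  if (is.null(threshold)) {
    thr <- otsu_threshold(inside)
    if (is.na(thr)) {
      attr(empty, "method") <- "constant"
      return(empty)
    }
    ## weak-contrast guard
    outside <- tum[!organoid_mask]
    noise_sd <- if (length(outside) > 10)
      as.numeric(quantile(outside, 0.975)) / 1.96 else 0
    if (thr - median(inside) < min_contrast_sd * noise_sd) {
      attr(empty, "method") <- "below-contrast-guard"
      return(empty)
    }
    method <- "otsu-within-organoid"
  } else {
    thr <- threshold
    method <- "fixed"
  }

  mask <- (tum > thr) & organoid_mask
  if (fill_holes && any(mask)) mask <- fill_holes_stack(mask) & organoid_mask
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

#' Run both segmentation stages on a stack
#'
#' @param stack an [image_stack()].
#' @param organoid_args,tumor_args argument lists for [segment_organoid()]
#'   and [segment_tumor_areas()].
#' @return list with `organoid_mask` and `tumor_mask` (tumor is always a
#'   subset of organoid).
#' @export
segment_stack <- function(stack, organoid_args = list(), tumor_args = list()) {
  org <- do.call(segment_organoid, c(list(stack), organoid_args))
  tum <- do.call(segment_tumor_areas, c(list(stack, org), tumor_args))
  list(organoid_mask = org, tumor_mask = tum)
}
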