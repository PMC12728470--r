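#' Summed brightness of a channel within a voxel mask
#'
#' Exact arithmetic sum of the channel's intensities over masked voxels,
#' reported per confocal plane and totalled over the stack.  This is the
#' organoid-level readout of the imaging arm: total fluorescence of a
#' compartment across all planes.
#'
#' @param stack an [image_stack()].
#' @param mask logical array matching the stack's spatial dimensions.
#' @param channel channel name or index.
#' @return list with `total` (numeric scalar) and `per_plane` (numeric
#'   vector, one entry per plane; sums to `total` exactly).
#' @export
sum_brightness <- function(stack, mask, channel) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (!identical(dim(mask), d[1:3]))
    stop_data("mask shape %s does not match stack planes %s",
              paste(dim(mask), collapse = "x"),
              paste(d[1:3], collapse = "x"))
  ch <- channel_index(stack, channel)
  vals <- array(stack$voxels[, , , ch], dim = d[1:3])
  vals[!mask] <- 0
  per_plane <- colSums(matrix(vals, ncol = d[3]))
  list(total = sum(per_plane), per_plane = as.numeric(per_plane))
}

#' Estimate per-channel constant background of a segmented stack
#'
#' Two estimators for the constant-background model:
#' * `"compartment"` (default): each marker channel's background is the
#'   median of its intensity over the organoid voxels belonging to the
#'   *other* compartment — tumor-channel background over organoid-minus-tumor
#'   voxels, neuronal-channel background over tumor voxels.  Because marker
#'   expression is compartment-specific (tumor marker absent from the TME,
#'   neuronal marker absent from tumor foci), those voxels carry only tissue
#'   autofluorescence plus noise.
#' * `"outside"`: median over out-of-organoid voxels per channel (a
#'   detector-offset estimate; near zero when the background is tissue
#'   autofluorescence confined to the organoid).
#'
#' When the tumor mask is empty the neuronal estimate falls back to the
#' outside median.
#'
#' @param stack an [image_stack()].
#' @param segmentation list with `organoid_mask` and `tumor_mask`.
#' @param method `"compartment"` or `"outside"`.
#' @param tumor_channel,neuronal_channel channel names or indices.
#' @return named numeric vector `c(tumor = ..., neuronal = ...)`.
#' @export
estimate_background <- function(stack, segmentation,
                                method = c("compartment", "outside"),
                                tumor_channel = "tumor",
                                neuronal_channel = "neuronal") {
  method <- match.arg(method)
  d <- dim(stack$voxels)
  org <- segmentation$organoid_mask
  tum <- segmentation$tumor_mask
  cht <- array(stack$voxels[, , , channel_index(stack, tumor_channel)],
               dim = d[1:3])
  chn <- array(stack$voxels[, , , channel_index(stack, neuronal_channel)],
               dim = d[1:3])
  med_or0 <- function(x) if (length(x)) median(x) else 0
  if (method == "outside") {
    b_t <- med_or0(cht[!org])
    b_n <- med_or0(chn[!org])
  } else {
    tme <- org & !tum
    b_t <- if (any(tme)) median(cht[tme]) else med_or0(cht[!org])
    b_n <- if (any(tum)) median(chn[tum]) else med_or0(chn[!org])
  }
  c(tumor = b_t, neuronal = b_n)
}

#' Measure an organoid: compartment sums and areas
#'
#' Computes the per-organoid readouts: summed tumor-channel brightness
#' within the tumor mask, summed neuronal-channel brightness over the whole
#' organoid (both totalled over all confocal planes, with per-plane
#' breakdowns), the tumor area (tumor voxel count) and the TME area
#' (organoid-minus-tumor voxel count).  With `background != "none"` a
#' constant per-channel background (see [estimate_background()]) times the
#' measured voxel count is subtracted from each sum; the subtraction is
#' applied per plane so additivity across planes is preserved exactly
#' (corrected sums may therefore be slightly negative under noise).
#'
#' @param stack an [image_stack()].
#' @param segmentation list with `organoid_mask` and `tumor_mask` (the tumor
#'   mask must be a subset of the organoid mask).
#' @param background `"none"` (default), `"compartment"` or `"outside"`.
#' @param tumor_channel,neuronal_channel channel names or indices.
#' @param saturation_level optional intensity at/above which a voxel is
#'   counted as saturated (QC metric only; saturated voxels stay in the
#'   sums).
#' @return object of class `organoid_measurement`: a list with `tumor_sum`,
#'   `neuronal_sum`, `tumor_area`, `tme_area`, `per_plane` (data.frame),
#'   `background` (estimates used), `n_saturated`, `background_method`.
#' @export
measure_organoid <- function(stack, segmentation,
                             background = c("none", "compartment", "outside"),
                             tumor_channel = "tumor",
                             neuronal_channel = "neuronal",
                             saturation_level = NULL) {
  background <- match.arg(background)
  d <- dim(stack$voxels)
  org <- segmentation$organoid_mask
  tum <- segmentation$tumor_mask
  if (!identical(dim(org), d[1:3]) || !identical(dim(tum), d[1:3]))
    stop_data("segmentation masks do not match stack shape")
  if (any(tum & !org))
    stop_data("tumor mask is not a subset of the organoid mask")

  ts <- sum_brightness(stack, tum, tumor_channel)
  ns <- sum_brightness(stack, org, neuronal_channel)
  tumor_area_pp <- colSums(matrix(tum, ncol = d[3]))
  org_area_pp <- colSums(matrix(org, ncol = d[3]))

  bg <- c(tumor = 0, neuronal = 0)
  if (background != "none") {
    bg <- estimate_background(stack, segmentation, method = background,
                              tumor_channel = tumor_channel,
                              neuronal_channel = neuronal_channel)
    ts$per_plane <- ts$per_plane - bg[["tumor"]] * tumor_area_pp
    ns$per_plane <- ns$per_plane - bg[["neuronal"]] * org_area_pp
    ts$total <- sum(ts$per_plane)
    ns$total <- sum(ns$per_plane)
  }

  n_sat <- 0L
  if (!is.null(saturation_level))
    n_sat <- sum(stack$voxels >= saturation_level)

  structure(list(
    tumor_sum = ts$total,
    neuronal_sum = ns$total,
    tumor_area = sum(tumor_area_pp),
    tme_area = sum(org_area_pp) - sum(tumor_area_pp),
    per_plane = data.frame(plane = seq_len(d[3]),
                           tumor_sum = ts$per_plane,
                           neuronal_sum = ns$per_plane,
                           tumor_area = as.integer(tumor_area_pp),
                           tme_area = as.integer(org_area_pp - tumor_area_pp)),
    background = bg,
    background_method = background,
    n_saturated = n_sat), class = "organoid_measurement")
}

#' @export
print.organoid_measurement <- function(x, ...) {
  cat(sprintf(paste0("<organoid_measurement> tumor_sum=%.4g neuronal_sum=%.4g ",
                     "tumor_area=%d tme_area=%d (background: %s)\n"),
              x$tumor_sum, x$neuronal_sum, x$tumor_area, x$tme_area,
              x$background_method))
  invisible(x)
}

#' Aggregate a measurement field over a group of organoids
#'
#' Sample mean, standard deviation (n-1 denominator) and standard error of
#' the mean.  For a single observation the SD is reported as 0 (documented
#' policy: a singleton group has no dispersion estimate, and 0 keeps
#' downstream error bars drawable), hence SEM 0.
#'
#' @param x numeric vector, or a list of `organoid_measurement` objects.
#' @param field measurement field name (required when `x` is a list), e.g.
#'   `"tumor_sum"`.
#' @return list with `n`, `mean`, `sd`, `sem`.
#' @export
aggregate_group <- function(x, field = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.numeric(x)) {
    if (is.null(field)) stop_config("field is required for measurement lists")
    x <- vapply(x, function(m) m[[field]], numeric(1))
  }
  x <- as.numeric(x)
  if (length(x) < 1L) stop_data("cannot aggregate an empty group")
  n <- length(x)
  s <- if (n > 1L) sd(x) else 0
  list(n = n, mean = mean(x), sd = s, sem = s / sqrt(n))
}
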