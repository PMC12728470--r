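#' Specification of a synthetic organoid image phantom
#'
#' Defines the geometry, intensities and treatment effect of a two-channel
#' organoid phantom.  The organoid is an ellipsoid (a circle per confocal
#' plane whose radius varies with plane depth; the z semi-axis spans the
#' stack), containing `n_tumor_foci` spherical tumor foci that lie entirely
#' inside the organoid and do not overlap each other.  The tumor channel
#' carries `tumor_intensity * (1 - tumor_kill)` inside the foci; the neuronal
#' channel carries `neuronal_intensity * (1 - neuronal_kill)` inside the
#' organoid outside the foci.  Both channels carry `background_intensity`
#' (organoid autofluorescence) everywhere inside the organoid, and zero
#' outside apart from noise.  Noise is additive Gaussian with SD `noise_sd`,
#' clipped at zero.
#'
#' `tumor_kill` and `neuronal_kill` are the simulated drug effect: the
#' fraction of tumor-compartment and neuronal-compartment signal removed by
#' treatment.  The defaults mirror the screening setup the pipeline is built
#' for: 29 confocal planes and four organoids per treatment group.
#'
#' @param n_planes number of confocal planes (default 29).
#' @param plane_shape integer (height, width) of each plane in pixels.
#' @param organoid_radius in-plane organoid radius, pixels.
#' @param n_tumor_foci number of spherical tumor foci.
#' @param focus_radius_range numeric length-2, min/max focus radius in
#'   pixels; the default is a fixed radius (degenerate range), which makes
#'   the tumor voxel count identical across phantoms and lets effect-recovery
#'   experiments isolate the measurement math.
#' @param tumor_fraction optional target fraction of organoid voxels that are
#'   tumor; when given, focus radii are rescaled once toward this target.
#' @param tumor_intensity,neuronal_intensity,background_intensity
#'   fluorescence levels, arbitrary units.
#' @param noise_sd additive Gaussian noise SD, same units.
#' @param tumor_kill,neuronal_kill fraction of tumor / neuronal signal
#'   removed by treatment, in `[0, 1]`.
#' @param seed integer; the generator is fully deterministic given the spec.
#' @param max_placement_tries bounded retries for focus placement before an
#'   explicit geometry error.
#' @return an object of class `phantom_spec` (a validated list).
#' @seealso [generate_organoid_stack()]
#' @export
phantom_spec <- function(n_planes = 29L,
                         plane_shape = c(64L, 64L),
                         organoid_radius = 24,
                         n_tumor_foci = 3L,
                         focus_radius_range = c(6, 6),
                         tumor_fraction = NULL,
                         tumor_intensity = 200,
                         neuronal_intensity = 150,
                         background_intensity = 20,
                         noise_sd = 10,
                         tumor_kill = 0,
                         neuronal_kill = 0,
                         seed = 1L,
                         max_placement_tries = 500L) {
  spec <- list(n_planes = as.integer(n_planes),
               plane_shape = as.integer(plane_shape),
               organoid_radius = organoid_radius,
               n_tumor_foci = as.integer(n_tumor_foci),
               focus_radius_range = as.numeric(focus_radius_range),
               tumor_fraction = tumor_fraction,
               tumor_intensity = tumor_intensity,
               neuronal_intensity = neuronal_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd,
               tumor_kill = tumor_kill,
               neuronal_kill = neuronal_kill,
               seed = as.integer(seed),
               max_placement_tries = as.integer(max_placement_tries))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_planes < 1L) stop_config("n_planes must be >= 1")
    if (length(plane_shape) != 2L || any(plane_shape < 4L))
      stop_config("plane_shape must be two integers >= 4")
    if (organoid_radius <= 0) stop_config("organoid_radius must be positive")
    if (n_tumor_foci < 0L) stop_config("n_tumor_foci must be >= 0")
    if (length(focus_radius_range) != 2L ||
        any(focus_radius_range <= 0) ||
        focus_radius_range[1] > focus_radius_range[2])
      stop_config("focus_radius_range must be an increasing positive pair")
    if (!is.null(tumor_fraction) &&
        (tumor_fraction <= 0 || tumor_fraction >= 1))
      stop_config("tumor_fraction must lie in (0, 1)")
    if (tumor_kill < 0 || tumor_kill > 1)
      stop_config("tumor_kill must lie in [0, 1]")
    if (neuronal_kill < 0 || neuronal_kill > 1)
      stop_config("neuronal_kill must lie in [0, 1]")
    if (any(c(tumor_intensity, neuronal_intensity,
              background_intensity, noise_sd) < 0))
      stop_config("intensities and noise_sd must be >= 0")
  })
  invisible(spec)
}

## voxel-center coordinate grids for a stack of the given shape
stack_grids <- function(h, w, np) {
  list(Y = array(rep(seq_len(h), times = w * np), dim = c(h, w, np)),
       X = array(rep(rep(seq_len(w), each = h), times = np), dim = c(h, w, np)),
       Z = array(rep(seq_len(np), each = h * w), dim = c(h, w, np)))
}

## place non-overlapping spherical foci entirely inside the organoid
## ellipsoid; when tumor_fraction is set, radii are rescaled toward the
## target before placement so containment is enforced on the final geometry
place_foci <- function(spec, cy, cx, cz, rz, n_organoid) {
  n <- spec$n_tumor_foci
  if (n == 0L) return(data.frame(y = numeric(0), x = numeric(0),
                                 z = numeric(0), r = numeric(0)))
  rxy <- spec$organoid_radius
  radii <- runif(n, spec$focus_radius_range[1], spec$focus_radius_range[2])
  if (!is.null(spec$tumor_fraction)) {
    target <- spec$tumor_fraction * n_organoid
    radii <- radii * (target / sum(4 / 3 * pi * radii^3))^(1 / 3)
  }
  foci <- data.frame(y = numeric(n), x = numeric(n), z = numeric(n), r = radii)
  ## sequential rejection sampling can wedge itself (early foci blocking the
  ## rest), so restart the whole configuration when a focus exhausts its
  ## per-focus try budget
  for (restart in seq_len(50L)) {
    i <- 1L
    tries <- 0L
    while (i <= n && tries <= spec$max_placement_tries) {
      tries <- tries + 1L
      fy <- round(runif(1, cy - rxy, cy + rxy))
      fx <- round(runif(1, cx - rxy, cx + rxy))
      fz <- round(runif(1, 1, spec$n_planes))
      r <- foci$r[i]
      ## conservative containment: scaled centre norm + worst-axis scaled radius
      sn <- sqrt(((fy - cy) / rxy)^2 + ((fx - cx) / rxy)^2 +
                 (if (rz > 0) ((fz - cz) / rz)^2 else 0))
      if (sn + r * max(1 / rxy, if (rz > 0) 1 / rz else 0) > 1) next
      if (i > 1L) {
        prev <- foci[seq_len(i - 1L), , drop = FALSE]
        d <- sqrt((prev$y - fy)^2 + (prev$x - fx)^2 + (prev$z - fz)^2)
        if (any(d < prev$r + r + 1)) next  # +1 voxel: strictly disjoint masks
      }
      foci[i, c("y", "x", "z")] <- c(fy, fx, fz)
      i <- i + 1L
      tries <- 0L
    }
    if (i > n) return(foci)
  }
  stop_data(paste0("could not place %d non-overlapping foci of radius ",
                   "%.1f-%.1f inside the organoid (%d tries per focus, ",
                   "50 restarts); geometry is infeasible"),
            n, spec$focus_radius_range[1], spec$focus_radius_range[2],
            spec$max_placement_tries)
}

#' Generate a synthetic two-channel organoid stack with voxel ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: organoid and tumor
#' masks, noiseless channel signals, and (if `noise_sd > 0`) additive
#' Gaussian noise clipped at zero.  The returned truth record holds the
#' masks, voxel counts and exact noiseless sums, so downstream segmentation
#' and measurement can be validated by parameter recovery.
#'
#' Deterministic: the same spec (including seed) yields a bit-identical
#' stack; specs that differ only in `tumor_kill`/`neuronal_kill` share the
#' same geometry and noise draws, so kill fractions scale signal without
#' moving the masks.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (organoid/tumor masks, voxel counts, noiseless signal and channel sums,
#'   focus table).
#' @export
generate_organoid_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec") || is.list(spec))
  validate_phantom_spec(spec)
  h <- spec$plane_shape[1]; w <- spec$plane_shape[2]; np <- spec$n_planes
  cy <- (h + 1) / 2; cx <- (w + 1) / 2; cz <- (np + 1) / 2
  rz <- if (np > 1L) (np - 1) / 2 else 0
  rxy <- spec$organoid_radius
  g <- stack_grids(h, w, np)
  zterm <- if (rz > 0) ((g$Z - cz) / rz)^2 else 0
  organoid <- (((g$Y - cy) / rxy)^2 + ((g$X - cx) / rxy)^2 + zterm) <= 1

  withr::with_seed(spec$seed, {
    foci <- place_foci(spec, cy, cx, cz, rz, sum(organoid))
    tumor <- array(FALSE, dim = c(h, w, np))
    for (i in seq_len(nrow(foci))) {
      d2 <- (g$Y - foci$y[i])^2 + (g$X - foci$x[i])^2 + (g$Z - foci$z[i])^2
      tumor <- tumor | (d2 <= foci$r[i]^2)
    }
    tumor <- tumor & organoid

    sig_t <- spec$tumor_intensity * (1 - spec$tumor_kill) * tumor
    sig_n <- spec$neuronal_intensity * (1 - spec$neuronal_kill) *
      (organoid & !tumor)
    bg <- spec$background_intensity * organoid
    ch_t <- sig_t + bg
    ch_n <- sig_n + bg
    if (spec$noise_sd > 0) {
      nv <- length(ch_t)
      ch_t <- pmax(ch_t + rnorm(nv, 0, spec$noise_sd), 0)
      ch_n <- pmax(ch_n + rnorm(nv, 0, spec$noise_sd), 0)
    }
  })

  n_org <- sum(organoid)
  n_tum <- sum(tumor)
  truth <- list(
    organoid_mask = organoid,
    tumor_mask = tumor,
    n_organoid_voxels = n_org,
    n_tumor_voxels = n_tum,
    ## noiseless compartment signal (background excluded)
    tumor_signal_sum = spec$tumor_intensity * (1 - spec$tumor_kill) * n_tum,
    neuronal_signal_sum = spec$neuronal_intensity *
      (1 - spec$neuronal_kill) * (n_org - n_tum),
    ## noiseless whole-stack channel totals (background included)
    tumor_channel_total = spec$tumor_intensity * (1 - spec$tumor_kill) *
      n_tum + spec$background_intensity * n_org,
    neuronal_channel_total = spec$neuronal_intensity *
      (1 - spec$neuronal_kill) * (n_org - n_tum) +
      spec$background_intensity * n_org,
    foci = foci,
    spec = spec)

  dimn <- c(h, w, np, 2L)
  vox <- array(c(ch_t, ch_n), dim = dimn)
  list(stack = image_stack(vox, channel_names = c("tumor", "neuronal")),
       truth = truth)
}
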