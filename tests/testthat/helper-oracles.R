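## Independent oracles and shared fixtures for the test suite.
## Oracles are deliberately naive (loops, enumeration) and never call the
## code paths they check.

## brute-force voxel-loop summed brightness
naive_sum_brightness <- function(voxels, mask, ch) {
  d <- dim(voxels)
  per_plane <- numeric(d[3])
  for (p in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        if (mask[i, j, p]) s <- s + voxels[i, j, p, ch]
      }
    }
    per_plane[p] <- s
  }
  list(total = sum(per_plane), per_plane = per_plane)
}

## exact two-sided Wilcoxon rank-sum p by full enumeration of rank
## assignments (no ties assumed)
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

## per-cell library-size + log1p normalization, naive loop
naive_normalize <- function(counts, sf = 1e4) {
  out <- matrix(0, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- log1p(counts[i, j] / tot * sf)
    }
  }
  out
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

## reduced phantom geometry for simulation-heavy checks (statistical
## properties of the downstream tests do not depend on stack size)
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(n_planes = 15L, plane_shape = c(32L, 32L),
               organoid_radius = 12, n_tumor_foci = 1L,
               focus_radius_range = c(4, 4), seed = seed, ...)
}

## reduced single-cell spec for simulation-heavy checks
small_cell_spec <- function(seed = 1L, ...) {
  synthetic_cell_spec(n_cells_per_condition = 150L,
                      n_signature_genes = 25L, n_cycle_genes = 30L,
                      n_background_genes = 500L,
                      library_size_mean = 3000, seed = seed, ...)
}

## generate-and-measure one phantom through the full quantification path
measure_phantom <- function(spec, background = "compartment") {
  g <- generate_organoid_stack(spec)
  seg <- segment_stack(g$stack)
  measure_organoid(g$stack, seg, background = background)
}
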