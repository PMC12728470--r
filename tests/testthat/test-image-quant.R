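test_that("sum_brightness is exact: uniform, empty-mask and oracle cases", {
  vox <- array(3, dim = c(5, 6, 4, 2))
  st <- image_stack(vox)
  mask <- array(FALSE, dim = c(5, 6, 4))
  mask[1:2, 1:3, c(1, 3)] <- TRUE           # 12 voxels
  sb <- sum_brightness(st, mask, "tumor")
  expect_equal(sb$total, 3 * 12)
  expect_equal(sum(sb$per_plane), sb$total)

  expect_equal(sum_brightness(st, array(FALSE, dim = c(5, 6, 4)), 2)$total, 0)
  expect_error(sum_brightness(st, mask, "gfp"), class = "tboscreen_config_error")
  expect_error(sum_brightness(st, array(FALSE, dim = c(5, 6, 5)), 1),
               class = "tboscreen_data_error")

  set.seed(1)
  for (i in 1:5) {
    d <- c(sample(3:8, 2), sample(2:5, 1), 2)
    vox <- array(runif(prod(d), 0, 1000), dim = d)
    mask <- array(runif(prod(d[1:3])) > 0.5, dim = d[1:3])
    st <- image_stack(vox)
    got <- sum_brightness(st, mask, 1)
    want <- naive_sum_brightness(vox, mask, 1)
    expect_equal(got$total, want$total, tolerance = 1e-12)
    expect_equal(got$per_plane, want$per_plane, tolerance = 1e-12)
  }
})

test_that("noiseless phantom segmentation recovers truth masks exactly", {
  g <- generate_organoid_stack(phantom_spec(noise_sd = 0))
  seg <- segment_stack(g$stack)
  expect_identical(unname(seg$organoid_mask > 0), unname(g$truth$organoid_mask))
  expect_identical(unname(seg$tumor_mask > 0), unname(g$truth$tumor_mask))
})

test_that("all-zero stacks give empty masks with a warning, not an error", {
  st <- image_stack(array(0, dim = c(8, 8, 3, 2)))
  expect_warning(m <- segment_organoid(st), "empty")
  expect_false(any(m))
  tm <- segment_tumor_areas(st, m)
  expect_false(any(tm))
})

test_that("complete tumor kill with zero background yields an empty tumor mask", {
  g <- generate_organoid_stack(phantom_spec(noise_sd = 0, tumor_kill = 1,
                                            background_intensity = 0))
  seg <- segment_stack(g$stack)
  expect_false(any(seg$tumor_mask))
})

test_that("tumor mask is always a subset of the organoid mask", {
  for (seed in 1:4) {
    g <- generate_organoid_stack(phantom_spec(seed = seed,
                                              tumor_kill = (seed - 1) / 4))
    seg <- segment_stack(g$stack)
    expect_false(any(seg$tumor_mask & !seg$organoid_mask))
  }
})

test_that("compartment background estimator recovers the autofluorescence level", {
  spec <- phantom_spec(seed = 2L)
  g <- generate_organoid_stack(spec)
  seg <- segment_stack(g$stack)
  bg <- estimate_background(g$stack, seg, method = "compartment")
  expect_lt(abs(bg[["tumor"]] - spec$background_intensity), 1.5)
  expect_lt(abs(bg[["neuronal"]] - spec$background_intensity), 1.5)
})

test_that("measure_organoid matches truth and is additive across planes", {
  g <- generate_organoid_stack(phantom_spec(noise_sd = 0))
  seg <- list(organoid_mask = g$truth$organoid_mask,
              tumor_mask = g$truth$tumor_mask)
  m <- measure_organoid(g$stack, seg)
  spec <- g$truth$spec
  expect_equal(m$tumor_sum, g$truth$tumor_signal_sum +
                 spec$background_intensity * g$truth$n_tumor_voxels)
  expect_equal(m$tumor_area, g$truth$n_tumor_voxels)
  expect_equal(m$tme_area, g$truth$n_organoid_voxels - g$truth$n_tumor_voxels)
  expect_equal(sum(m$per_plane$tumor_sum), m$tumor_sum)
  expect_equal(sum(m$per_plane$neuronal_sum), m$neuronal_sum)
  expect_equal(sum(m$per_plane$tumor_area), m$tumor_area)

  ## background-corrected measurement strips the autofluorescence exactly
  mc <- measure_organoid(g$stack, seg, background = "compartment")
  expect_equal(mc$tumor_sum, g$truth$tumor_signal_sum)

  ## complete neuronal kill, zero background: neuronal sum is 0
  g0 <- generate_organoid_stack(phantom_spec(noise_sd = 0, neuronal_kill = 1,
                                             background_intensity = 0))
  m0 <- measure_organoid(g0$stack, list(organoid_mask = g0$truth$organoid_mask,
                                        tumor_mask = g0$truth$tumor_mask))
  expect_equal(m0$neuronal_sum, 0)

  bad <- list(organoid_mask = g$truth$organoid_mask[, , 1:3],
              tumor_mask = g$truth$tumor_mask[, , 1:3])
  expect_error(measure_organoid(g$stack, bad), class = "tboscreen_data_error")
})

test_that("aggregate_group computes mean, SD (n-1) and SEM with the singleton policy", {
  a <- aggregate_group(c(2, 4, 6))
  expect_equal(a$mean, 4)
  expect_equal(a$sd, 2)
  expect_equal(a$sem, 2 / sqrt(3))
  s <- aggregate_group(5)
  expect_equal(s$sd, 0)
  expect_equal(s$sem, 0)
  expect_error(aggregate_group(numeric(0)), class = "tboscreen_data_error")
})

test_that("saturated voxels are counted but kept in the sums", {
  g <- generate_organoid_stack(phantom_spec(noise_sd = 0))
  seg <- list(organoid_mask = g$truth$organoid_mask,
              tumor_mask = g$truth$tumor_mask)
  m <- measure_organoid(g$stack, seg, saturation_level = 220)
  expect_equal(m$n_saturated, sum(g$stack$voxels >= 220))
  m2 <- measure_organoid(g$stack, seg)
  expect_equal(m$tumor_sum, m2$tumor_sum)
})

test_that("TIFF round trip preserves stack contents and metadata", {
  g <- generate_organoid_stack(small_phantom_spec(seed = 4L))
  path <- file.path(tempdir(), "stack_rt.tif")
  write_stack_tiff(g$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(back$channel_names, g$stack$channel_names)
  expect_equal(back$voxels, g$stack$voxels, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})
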