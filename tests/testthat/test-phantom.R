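test_that("noiseless phantom channel sums follow the closed form", {
  spec <- phantom_spec(noise_sd = 0, tumor_kill = 0, neuronal_kill = 0)
  g <- generate_organoid_stack(spec)
  tr <- g$truth
  expect_equal(sum(g$stack$voxels[, , , 1]),
               spec$tumor_intensity * tr$n_tumor_voxels +
                 spec$background_intensity * tr$n_organoid_voxels)
  expect_equal(sum(g$stack$voxels[, , , 2]),
               spec$neuronal_intensity *
                 (tr$n_organoid_voxels - tr$n_tumor_voxels) +
                 spec$background_intensity * tr$n_organoid_voxels)
  expect_equal(sum(g$stack$voxels[, , , 1]), tr$tumor_channel_total)

  ## complete tumor kill with zero background empties the tumor channel
  g1 <- generate_organoid_stack(phantom_spec(noise_sd = 0, tumor_kill = 1,
                                             background_intensity = 0))
  expect_equal(sum(g1$stack$voxels[, , , 1]), 0)
})

test_that("half tumor kill halves the noiseless signal; noisy sum stays within tolerance", {
  s0 <- phantom_spec(tumor_kill = 0, background_intensity = 0, noise_sd = 10,
                     seed = 1L)
  s5 <- phantom_spec(tumor_kill = 0.5, background_intensity = 0, noise_sd = 10,
                     seed = 1L)
  g0 <- generate_organoid_stack(s0)
  g5 <- generate_organoid_stack(s5)
  expect_equal(g5$truth$tumor_signal_sum, g0$truth$tumor_signal_sum / 2)
  ## measured (noisy) sum within the truth tumor mask: 4 sd(sum) band
  sb <- sum_brightness(g5$stack, g5$truth$tumor_mask, "tumor")
  tol <- 4 * 10 * sqrt(g5$truth$n_tumor_voxels)
  expect_lt(abs(sb$total - g5$truth$tumor_signal_sum), tol)
})

test_that("generation is deterministic and kill fractions act monotonically", {
  spec <- phantom_spec(seed = 7L)
  a <- generate_organoid_stack(spec)
  b <- generate_organoid_stack(spec)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$tumor_mask, b$truth$tumor_mask)

  kts <- c(0, 0.25, 0.5, 0.75, 1)
  sums <- vapply(kts, function(k) {
    generate_organoid_stack(phantom_spec(seed = 7L,
                                         tumor_kill = k))$truth$tumor_signal_sum
  }, numeric(1))
  expect_true(all(diff(sums) < 0))
  ## neuronal channel unaffected by tumor kill (identical geometry + noise)
  n0 <- generate_organoid_stack(phantom_spec(seed = 7L, tumor_kill = 0))
  n1 <- generate_organoid_stack(phantom_spec(seed = 7L, tumor_kill = 0.9))
  expect_identical(n0$stack$voxels[, , , 2], n1$stack$voxels[, , , 2])
})

test_that("foci lie inside the organoid, are disjoint, and infeasible geometry errors", {
  vt <- integer(5)
  for (seed in 1:5) {
    g <- generate_organoid_stack(phantom_spec(seed = seed))
    expect_false(any(g$truth$tumor_mask & !g$truth$organoid_mask))
    vt[seed] <- g$truth$n_tumor_voxels
  }
  ## fixed focus radius + integer centres + non-overlap: the tumor voxel
  ## count is a translation-invariant constant across phantoms
  expect_length(unique(vt), 1L)
  expect_error(
    generate_organoid_stack(phantom_spec(focus_radius_range = c(20, 20))),
    class = "tboscreen_data_error")
})

test_that("tumor_fraction target rescales foci toward the requested share", {
  g <- generate_organoid_stack(phantom_spec(tumor_fraction = 0.1, seed = 3L,
                                            focus_radius_range = c(4, 6)))
  frac <- g$truth$n_tumor_voxels / g$truth$n_organoid_voxels
  expect_lt(abs(frac - 0.1), 0.03)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(phantom_spec(tumor_kill = 1.2), class = "tboscreen_config_error")
  expect_error(phantom_spec(n_planes = 0), class = "tboscreen_config_error")
  expect_error(phantom_spec(noise_sd = -1), class = "tboscreen_config_error")
})

test_that("screen dataset generation counts wells and is reproducible", {
  truth <- screen_truth_table(drug = c("A", "B", "C"), tumor_kill = c(0.5, 0.2, 0),
                              n_per_group = 4L)
  spec <- small_phantom_spec(seed = 1L)
  ds <- generate_screen_dataset(truth, spec)
  expect_length(ds$stacks, 16L)        # 3 drugs x 4 + 4 DMSO
  expect_equal(nrow(ds$layout), 16L)
  expect_false(anyDuplicated(ds$layout$well_id) > 0)

  ds2 <- generate_screen_dataset(truth, spec)
  expect_identical(ds$stacks[["A_r01"]]$voxels, ds2$stacks[["A_r01"]]$voxels)

  dup <- rbind(truth, truth[1, ])
  expect_error(generate_screen_dataset(dup, spec),
               class = "tboscreen_data_error")
  expect_error(screen_truth_table(drug = "A", n_per_group = 0L),
               class = "tboscreen_data_error")
})
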