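## constructed curve in the long format build_curve() emits
make_curve <- function(doses, p_t, m_t, p_n, m_n) {
  rbind(
    data.frame(drug = "x", dose = 0, compartment = "tumor", n = 8,
               mean = 1, sem = 0, p = NA_real_),
    data.frame(drug = "x", dose = doses, compartment = "tumor", n = 8,
               mean = m_t, sem = 0, p = p_t),
    data.frame(drug = "x", dose = 0, compartment = "neuronal", n = 8,
               mean = 1, sem = 0, p = NA_real_),
    data.frame(drug = "x", dose = doses, compartment = "neuronal", n = 8,
               mean = m_n, sem = 0, p = p_n))
}

test_that("first_significant_dose finds the lowest significant reduction", {
  cur <- make_curve(1:5,
                    p_t = c(0.8, 0.6, 0.9, 0.01, 0.001),
                    m_t = c(1.01, 0.98, 0.99, 0.6, 0.4),
                    p_n = rep(0.5, 5), m_n = rep(1, 5))
  expect_equal(first_significant_dose(cur, "tumor"), 4)
  expect_true(is.na(first_significant_dose(cur, "neuronal")))
  ## degenerate alpha = 1: lowest dose with any reduction
  expect_equal(first_significant_dose(cur, "tumor", alpha = 1), 2)
  ## significance without reduction does not count
  cur2 <- make_curve(1:3, p_t = c(0.01, 0.5, 0.01), m_t = c(1.4, 1, 0.5),
                     p_n = rep(1, 3), m_n = rep(1, 3))
  expect_equal(first_significant_dose(cur2, "tumor"), 3)
})

test_that("therapeutic window follows tumor and neuronal onset doses", {
  ## tumor onset dose 2, neuronal onset dose 5 (of 6) -> [2, 4]
  cur <- make_curve(1:6,
                    p_t = c(0.7, 0.001, 0.001, 0.001, 0.001, 0.001),
                    m_t = c(1, 0.5, 0.4, 0.3, 0.2, 0.1),
                    p_n = c(0.9, 0.8, 0.7, 0.6, 0.01, 0.001),
                    m_n = c(1, 1, 1, 1, 0.6, 0.4))
  w <- therapeutic_window(cur)
  expect_true(w$exists)
  expect_equal(w$lower, 2)
  expect_equal(w$upper, 4)

  ## no tumor effect anywhere -> no window
  flat <- make_curve(1:6, p_t = rep(0.5, 6), m_t = rep(1, 6),
                     p_n = rep(0.5, 6), m_n = rep(1, 6))
  expect_false(therapeutic_window(flat)$exists)

  ## neuronal never significant, tumor from dose 1 -> [1, max]
  cur2 <- make_curve(1:6, p_t = rep(0.001, 6), m_t = seq(0.9, 0.4, by = -0.1),
                     p_n = rep(0.5, 6), m_n = rep(1, 6))
  w2 <- therapeutic_window(cur2)
  expect_equal(c(w2$lower, w2$upper), c(1, 6))

  ## neuronal toxic from the lowest dose -> window cannot exist
  cur3 <- make_curve(1:6, p_t = rep(0.001, 6), m_t = rep(0.5, 6),
                     p_n = rep(0.001, 6), m_n = rep(0.5, 6))
  expect_false(therapeutic_window(cur3)$exists)
})

test_that("stricter alpha never extends the window left or shrinks it from the right", {
  set.seed(1)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  for (i in 1:50) {
    cur <- make_curve(1:6,
                      p_t = runif(6), m_t = runif(6, 0.3, 1.2),
                      p_n = runif(6), m_n = runif(6, 0.3, 1.2))
    lowers <- uppers <- numeric(0)
    for (a in alphas) {
      w <- therapeutic_window(cur, alpha = a)
      ## NA lower = "beyond the top dose" (+Inf); NA upper = "below the
      ## bottom dose" (-Inf)
      lowers <- c(lowers, if (is.na(w$lower)) Inf else w$lower)
      uppers <- c(uppers, if (is.na(w$upper)) -Inf else w$upper)
    }
    expect_false(is.unsorted(lowers))
    expect_false(is.unsorted(uppers))
  }
})

test_that("build_curve on a null drug is flat at 1 with exact control column", {
  truth <- screen_truth_table(drug = rep("null", 3), tumor_kill = 0,
                              neuronal_kill = 0, dose = c(1, 2, 4),
                              n_per_group = 4L)
  meas <- simulate_screen_measurements(truth, small_phantom_spec(seed = 5L))
  cur <- build_curve(meas)
  expect_equal(cur$mean[cur$dose == 0], c(1, 1))
  expect_true(all(abs(cur$mean - 1) < 0.1))
})

test_that("build_curve recovers a Hill-shaped kill profile pointwise", {
  ## max_kill 0.8 keeps the top-dose tumor signal above the segmentation
  ## detection floor (~1.5 noise SDs over autofluorescence)
  doses <- c(0.5, 1, 2, 4, 8)
  kt <- hill_kill(doses, ec50 = 2, hill = 2, max_kill = 0.8)
  truth <- screen_truth_table(drug = rep("hilldrug", 5), tumor_kill = kt,
                              neuronal_kill = 0, dose = doses,
                              n_per_group = 8L)
  meas <- simulate_screen_measurements(truth, small_phantom_spec(seed = 6L))
  cur <- build_curve(meas)
  tum <- cur[cur$compartment == "tumor" & cur$dose > 0, ]
  expect_true(all(abs(tum$mean - (1 - kt)) <= 0.05))
  fit <- fit_hill(cur, "tumor")
  expect_lt(abs(log2(fit$ec50 / 2)), 1)  # EC50 within a factor of 2

  ## malformed input: fewer than 2 nonzero doses
  expect_error(build_curve(meas[meas$dose %in% c(0, 1), ]),
               class = "tboscreen_data_error")
})
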