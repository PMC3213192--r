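test_that("the cluster detector applies the count and mass thresholds literally", {
  # all molecules at one point, 21 on the membrane: polarized for any window
  for (w in c(0.15, 0.2, 0.25)) {
    dc <- detect_cluster(rep(0.4, 21), window_fraction = w)
    expect_true(dc$polarized)
    expect_equal(dc$in_window_fraction, 1)
  }
  # exactly 20 molecules: strictly "more than 20" fails
  dc20 <- detect_cluster(rep(0.4, 20))
  expect_false(dc20$polarized)
  # uniform molecules: in-window fraction is about the window width
  set.seed(11)
  pos <- stats::runif(1000)
  dcu <- detect_cluster(pos, window_fraction = 0.15)
  expect_false(dcu$polarized)
  expect_lt(dcu$in_window_fraction, 0.25)
  # empty membrane
  dce <- detect_cluster(numeric(0))
  expect_false(dce$polarized)
  expect_equal(dce$n_membrane, 0L)
})

test_that("the detector is rotation invariant up to scan discretization", {
  set.seed(22)
  pos <- (0.3 + 0.1 * stats::rnorm(200)) %% 1
  base <- detect_cluster(pos, window_fraction = 0.2)
  for (shift in c(0.123, 0.5, 0.9)) {
    shifted <- detect_cluster((pos + shift) %% 1, window_fraction = 0.2)
    expect_lt(abs(shifted$in_window_fraction - base$in_window_fraction),
              2 / 360 * 200 / 200 + 0.02)
  }
})

test_that("in-window mass is monotone in the window width", {
  set.seed(33)
  pos <- (0.6 + 0.07 * stats::rnorm(150)) %% 1
  fr <- vapply(c(0.1, 0.15, 0.2, 0.25, 0.4),
               function(w) detect_cluster(pos, w)$in_window_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("polarization frequency hits its trivial endpoints", {
  off <- make_fixture("off_state")
  expect_equal(polarization_frequency(off, burn_in = 0)$frequency, 0)
  pol <- make_fixture("polarized")
  i <- length(pol$t)
  expect_true(detect_cluster(pol$positions[[i]])$polarized)
  pf <- polarization_frequency(pol, burn_in = 0.5)
  expect_equal(pf$frequency, 1)
})

test_that("regimes are classified from simulated replicates", {
  set.seed(44)
  # below the critical number with tiny alpha: OFF
  m_off <- preset_model(300)
  runs_off <- simulate(m_off, nsim = 3, seed = 1, t_end = 10,
                       record_every = 0.25)
  expect_identical(classify_regime(m_off, runs_off)$label, "OFF")

  # consolidated single clans: POLARIZED (small fast system, no on-events)
  m_pol <- clan_model(N_T = 80, k_fb = 0.9, D_m = 0.1)
  runs_pol <- simulate(m_pol, nsim = 4, seed = 2, t_end = 16,
                       record_every = 0.25, membrane_fraction = 7 / 8,
                       n_clans = 10)
  expect_identical(classify_regime(m_pol, runs_pol,
                                   burn_in = 10)$label, "POLARIZED")

  # far above the locality bound: HOMOGENEOUS_ON
  m_hom <- polarity_model(N_T = 600, k_fb = 0.9, k_on = 0.05, D_m = 500)
  expect_false(regime_bounds(m_hom, K = 10)$locality_bound_ok)
  runs_hom <- simulate(m_hom, nsim = 3, seed = 3, t_end = 10,
                       record_every = 0.25, membrane_fraction = 0.9)
  expect_identical(classify_regime(m_hom, runs_hom)$label, "HOMOGENEOUS_ON")
})

test_that("phase scans separate off from on across the critical number and fail loudly on empty grids", {
  m <- preset_model(900)
  ps <- phase_scan(m, N_T_grid = c(300, 2700), size_grid = c(1, 2),
                   reps = 2, seed = 9, t_end = 8, record_every = 0.5)
  expect_equal(nrow(ps), 4)
  for (i in seq_len(nrow(ps))) {
    # R0 < 1 cells are OFF; R0 > 1 cells are occupied
    if (ps$N_T[i] / (900 * ps$size[i]) < 1) {
      expect_identical(ps$label[i], "OFF")
    } else {
      expect_false(ps$label[i] == "OFF")
    }
  }
  expect_error(phase_scan(m, N_T_grid = 300, size_grid = c(1, 2)))
  expect_error(phase_scan(m, N_T_grid = numeric(0), size_grid = c(1, 2)))
})

test_that("labels are density-governed: scaling N and V together preserves the on/off call", {
  m <- preset_model(900)
  ps <- phase_scan(m, N_T_grid = c(450, 1800), size_grid = c(1, 2),
                   reps = 2, seed = 10, t_end = 8, record_every = 0.5)
  off_small <- ps$label[ps$N_T == 450 & ps$size == 1]
  off_larger_cell <- ps$label[ps$N_T == 450 & ps$size == 2]
  on_small <- ps$label[ps$N_T == 1800 & ps$size == 1]
  expect_identical(off_small, "OFF")
  expect_identical(off_larger_cell, "OFF")
  expect_false(on_small == "OFF")
})
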