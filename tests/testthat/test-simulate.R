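test_that("initial states respect the membrane fraction and arc-based clan seeding", {
  m <- polarity_model(N_T = 1000)
  set.seed(1)
  st <- init_state(m, membrane_fraction = 0.1, n_clans = 25)
  expect_equal(length(st$positions), 100)
  expect_equal(st$N_c, 900L)
  # every molecule's label is the arc it sits in; labels partition the circle
  expect_equal(st$clan_ids, as.integer(floor(st$positions * 25)) + 1L)

  st0 <- init_state(m, membrane_fraction = 0)
  expect_equal(length(st0$positions), 0)
  expect_equal(st0$N_c, 1000L)
})

test_that("mass is conserved exactly at every recorded state", {
  m <- polarity_model(N_T = 300)
  tr <- simulate(m, seed = 3, t_end = 5, record_every = 0.05)
  expect_true(all(tr$N_c + tr$N_m == tr$N_T))
})

test_that("identical seeds give identical trajectories", {
  m <- polarity_model(N_T = 400)
  a <- simulate(m, seed = 99, t_end = 3, record_every = 0.1)
  b <- simulate(m, seed = 99, t_end = 3, record_every = 0.1)
  expect_identical(a$N_m, b$N_m)
  expect_identical(a$positions, b$positions)
  expect_identical(a$clan_ids, b$clan_ids)
  c2 <- simulate(m, seed = 100, t_end = 3, record_every = 0.1)
  expect_false(identical(a$N_m, c2$N_m))
})

test_that("a single membrane molecule recruits with the binomial probability", {
  # frozen dynamics except recruitment: membrane count after one step is
  # 1 + Bernoulli(k_fb*(V_fb/V)*N_c*dt)
  m <- polarity_model(N_T = 101, k_off = 0, k_on = 0, k_fb = 0.01, D_m = 0)
  dt <- 5e-3
  p <- 0.01 * 100 * dt
  set.seed(7)
  st0 <- init_state(m, membrane_fraction = 1 / 101, n_clans = 1)
  expect_equal(length(st0$positions), 1)
  reps <- 20000
  extra <- vapply(seq_len(reps), function(i) {
    length(step_state(st0, m, dt)$positions) - 1L
  }, integer(1))
  phat <- mean(extra)
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(phat - p), 3 * se + 1e-12)
  # the recruit appears at the recruiter's position with its clan id
  set.seed(8)
  repeat {
    st1 <- step_state(st0, m, dt)
    if (length(st1$positions) == 2) break
  }
  expect_equal(st1$positions[1], st1$positions[2])
  expect_equal(st1$clan_ids[1], st1$clan_ids[2])
})

test_that("without feedback the membrane fraction matches the two-state equilibrium", {
  # k_fb = 0: independent two-state molecules, P(membrane) = kon'/(kon'+koff)
  m <- polarity_model(N_T = 100, k_off = 9, k_on = 1, k_fb = 0, V_on = 1)
  tr <- simulate(m, seed = 12, t_end = 60, record_every = 0.05,
                 membrane_fraction = 0, record = "counts")
  keep <- tr$t >= 5
  frac <- mean(tr$N_m[keep]) / 100
  expect_lt(abs(frac - 0.1), 0.01)
})

test_that("an empty membrane with no spontaneous activation stays empty", {
  m <- polarity_model(N_T = 200, k_on = 0)
  tr <- simulate(m, seed = 5, t_end = 2, record_every = 0.1,
                 membrane_fraction = 0)
  expect_true(all(tr$N_m == 0))
})

test_that("too-large steps are rejected naming the violated bound", {
  m <- polarity_model(N_T = 2000)
  st <- init_state(m, 0.1, 10)
  expect_error(step_state(st, m, dt = 0.1), "dt too large")
})

test_that("halving dt leaves the time-averaged membrane fraction unchanged within noise", {
  m <- polarity_model(N_T = 80, k_fb = 0.9, k_on = 0.005)  # N_star = 10
  avg_frac <- function(dt, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate(m, seed = s, t_end = 12, record_every = 0.1, dt = dt,
                     membrane_fraction = 0.5, record = "counts")
      mean(tr$N_m[tr$t >= 2] / 80)
    }, numeric(1))
  }
  dt0 <- default_dt(m)
  a <- avg_frac(dt0, 1:24)
  b <- avg_frac(dt0 / 2, 101:124)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  # allow the O(dt) splitting bias at this step size on top of sampling noise
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 0.005 * mean(a))
})

test_that("perturbation events adjust the bookkeeping and reject impossible removals", {
  m <- polarity_model(N_T = 700)
  sch <- make_schedule(2, list(evt_add_cytosol(1, 600)), record_every = 0.1)
  tr <- simulate(m, seed = 21, schedule = sch, membrane_fraction = 0)
  expect_equal(tr$N_T[tr$t < 1][1], 700L)
  expect_equal(tr$N_T[length(tr$t)], 1300L)
  expect_true(all(tr$N_c + tr$N_m == tr$N_T))

  sch2 <- make_schedule(2, list(evt_remove_cytosol(1, 10000)),
                        record_every = 0.1)
  expect_error(simulate(m, seed = 21, schedule = sch2), "exceeds current N_c")

  # reseed moves the stated fraction into one membrane window
  sch3 <- make_schedule(1, list(evt_reseed(0.5, 0.5, 0.1)),
                        record_every = 0.05)
  m3 <- polarity_model(N_T = 400, k_off = 1e-6, k_on = 0, k_fb = 0, D_m = 0)
  tr3 <- simulate(m3, seed = 4, schedule = sch3, membrane_fraction = 0)
  i <- which(tr3$t > 0.5)[1]
  expect_equal(tr3$N_m[i], 200L)
  dc <- detect_cluster(tr3$positions[[i]], window_fraction = 0.15)
  expect_gte(dc$in_window_fraction, 0.99)
})

test_that("event times must be increasing and inside the run", {
  expect_error(make_schedule(10, list(evt_add_cytosol(5, 1),
                                      evt_add_cytosol(3, 1))))
  expect_error(make_schedule(10, list(evt_add_cytosol(11, 1))))
})

test_that("kymographs bin positions consistently with membrane counts", {
  tr <- make_fixture("two_clans", seed = 2)
  km <- kymograph(tr, n_bins = 24)
  expect_equal(unname(rowSums(km)), tr$N_m)

  # single frozen molecule: one constant nonzero column
  m <- polarity_model(N_T = 1, k_off = 0, k_on = 0, k_fb = 0, D_m = 0)
  tr1 <- simulate(m, seed = 6, t_end = 1, record_every = 0.1,
                  membrane_fraction = 1)
  km1 <- kymograph(tr1, n_bins = 10)
  expect_true(all(rowSums(km1) == 1))
  expect_equal(length(unique(apply(km1, 1, which.max))), 1L)

  # empty trajectory: all-zero matrix
  tr0 <- make_fixture("off_state")
  expect_true(all(kymograph(tr0, 12) == 0))
})

test_that("long-run count occupancy matches the stationary distribution", {
  # the spatial layer must not perturb count statistics
  m <- polarity_model(N_T = 100)
  dt <- default_dt(m)
  tr <- simulate(m, seed = 31, t_end = 2e5 * dt, record_every = dt,
                 record = "counts")
  occ <- tabulate(tr$N_c[-1] + 1L, nbins = 101) / (length(tr$N_c) - 1)
  pmf <- stationary_distribution(m)
  tv <- 0.5 * sum(abs(occ - pmf$p))
  expect_lt(tv, 0.05)
})
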