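test_that("clan extinction times are read off constructed trajectories", {
  traj <- structure(list(
    t = 0:6, N_m = c(10, 10, 9, 8, 8, 7, 7),
    n_clans = c(4L, 4L, 3L, 2L, 2L, 1L, 1L),
    positions = rep(list(rep(0.5, 3)), 7),
    clan_ids = rep(list(c(2L, 2L, 2L)), 7)
  ), class = "polarity_traj")
  cs <- clan_trajectory(traj)
  expect_equal(cs$K, 4L)
  expect_equal(cs$t_half_hat, 3)   # first crossing of ceiling(4/2) = 2
  expect_equal(cs$t_single_hat, 5)
  expect_equal(cs$winner_id, 2L)
  expect_equal(cs$winner_spread, 0)
})

test_that("a single founding clan persists until total extinction", {
  m <- clan_model(N_T = 30)
  tr <- simulate(m, seed = 44, t_end = 5, record_every = 0.1,
                 membrane_fraction = 2 / 3, n_clans = 1)
  alive <- tr$N_m > 0
  expect_true(all(tr$n_clans[alive] == 1))
})

test_that("without on-events the surviving-clan count never increases", {
  m <- clan_model()
  set.seed(55)
  for (r in 1:10) {
    tr <- simulate(m, t_end = 10, record_every = 0.05,
                   membrane_fraction = 5 / 6, n_clans = 50)
    expect_true(all(diff(tr$n_clans) <= 0))
  }
})

test_that("halving two clans is the same as reaching one", {
  m <- clan_model()
  expect_equal(clan_half_life(m, K = 2, N_m = 50),
               single_clan_time(m, K = 2, N_m = 50))
  # and the single-clan time dominates the half-life for K > 2
  for (K in c(4, 8, 32)) {
    expect_gte(single_clan_time(m, K, N_m = 48),
               clan_half_life(m, K, N_m = 48))
  }
})

test_that("analytic clan times track simulation medians across a parameter sweep", {
  run_medians <- function(m, K, mf, reps = 120, t_end = 25) {
    th <- ts <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- simulate(m, t_end = t_end, record_every = 0.05,
                     membrane_fraction = mf, n_clans = K, record = "counts")
      cs <- clan_trajectory(tr)
      th[r] <- ifelse(is.na(cs$t_half_hat), Inf, cs$t_half_hat)
      ts[r] <- ifelse(is.na(cs$t_single_hat), Inf, cs$t_single_hat)
    }
    c(half = stats::median(th), single = stats::median(ts))
  }
  set.seed(66)
  sweep <- list(list(m = clan_model(60, 0.9), K = 4, mf = 5 / 6),
                list(m = clan_model(60, 0.9), K = 10, mf = 5 / 6),
                list(m = clan_model(90, 0.3), K = 6, mf = 2 / 3))
  for (s in sweep) {
    N_m <- round(s$mf * s$m$N_T)
    med <- run_medians(s$m, s$K, s$mf)
    f_half <- clan_half_life(s$m, s$K, N_m)
    f_single <- single_clan_time(s$m, s$K, N_m)
    expect_lt(abs(f_half - med["half"]) / med["half"], 0.35)
    expect_lt(abs(log2(f_single / med["single"])), 1)  # within a factor of 2
  }
})

test_that("each exchangeable clan wins with equal probability", {
  m <- clan_model()
  set.seed(77)
  winners <- integer(0)
  for (r in 1:300) {
    tr <- simulate(m, t_end = 20, record_every = 0.1,
                   membrane_fraction = 5 / 6, n_clans = 5)
    cs <- clan_trajectory(tr)
    if (!is.na(cs$winner_id) && cs$winner_id <= 5) {
      winners <- c(winners, cs$winner_id)
    }
  }
  expect_gt(length(winners), 250)
  tab <- table(factor(winners, levels = 1:5))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("winner locality distinguishes frozen, slow, and fast diffusion", {
  # no diffusion: the surviving lineage collapses to its ancestral point
  st <- structure(list(positions = rep(0.31, 40), clan_ids = rep(3L, 40)),
                  class = "particle_state")
  m <- polarity_model(D_m = 0)
  wl <- winner_locality(st, m)
  expect_equal(wl$spread, 0)
  expect_true(wl$local)

  # uniform-like spread is flagged non-local
  set.seed(88)
  stu <- structure(list(positions = stats::runif(500),
                        clan_ids = rep(1L, 500)), class = "particle_state")
  wlu <- winner_locality(stu, polarity_model())
  expect_false(wlu$local)

  # more than one surviving clan is an error, not a guess
  st2 <- structure(list(positions = c(0.1, 0.9), clan_ids = c(1L, 2L)),
                   class = "particle_state")
  expect_error(winner_locality(st2, m), "exactly one clan")

  # slow Cdc42-scale diffusion, small system: spread far below the membrane size
  mc <- clan_model(N_T = 60)
  expect_true(regime_bounds(mc, K = 10)$locality_bound_ok)
  set.seed(89)
  spreads <- c()
  for (r in 1:20) {
    tr <- simulate(mc, t_end = 15, record_every = 0.25,
                   membrane_fraction = 5 / 6, n_clans = 10)
    i <- which(tr$n_clans == 1 & tr$N_m > 0)[1]
    if (is.na(i)) next
    stw <- structure(list(positions = tr$positions[[i]],
                          clan_ids = tr$clan_ids[[i]]),
                     class = "particle_state")
    spreads <- c(spreads, winner_locality(stw, mc)$spread)
  }
  expect_gt(length(spreads), 10)
  expect_lt(stats::median(spreads), 0.2)
})
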