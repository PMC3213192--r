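test_that("the rescaled rate vanishes at its fixed points and refills an empty cytosol", {
  d <- derive_constants(polarity_model(N_T = 500, k_on = 0))
  expect_equal(cytosol_rate(d$rho_T, d), 0)
  expect_equal(cytosol_rate(d$rho_star, d), 0)
  d2 <- derive_constants(polarity_model(N_T = 500))
  expect_gt(cytosol_rate(0, d2), 0)
})

test_that("without spontaneous activation the steady states are rho_T and rho_star", {
  # repressed branch: rho_T < rho_star
  d <- derive_constants(polarity_model(N_T = 450, k_on = 0))
  ss <- steady_states(d)
  expect_equal(ss$roots, c(450, 900))
  expect_equal(ss$stability, c("stable", "unstable"))
  expect_equal(ss$membrane_fraction, 0)
  expect_identical(ss$bifurcation_type, "transcritical")
  # permissive branch: rho_T > rho_star
  d2 <- derive_constants(polarity_model(N_T = 1800, k_on = 0))
  ss2 <- steady_states(d2)
  expect_equal(ss2$roots, c(900, 1800))
  expect_equal(ss2$membrane_fraction, 0.5)
  # at alpha = 0 the unstable root sits exactly at rho_T, still physical
  expect_true(ss2$physical[2])
})

test_that("with spontaneous activation the stable root matches a bisection oracle", {
  d <- derive_constants(polarity_model(N_T = 900))  # rho_T = rho_star
  d$alpha_on_off <- 1e-4
  ss <- steady_states(d)
  oracle <- stats::uniroot(function(x) cytosol_rate(x, d),
                           c(0, d$rho_T), tol = 1e-12)$root
  expect_lt(abs(ss$roots[1] - oracle), 1e-10 * d$rho_star)
  expect_lt(ss$roots[1], d$rho_star)
  expect_identical(ss$bifurcation_type, "imperfect_transcritical")
})

test_that("spontaneous activation leaves a unique stable physical root", {
  set.seed(404)
  for (i in 1:200) {
    m <- random_model()
    m$k_on <- stats::runif(1, 1e-6, 0.01)
    m$N_T <- m$N_T + 1L
    d <- derive_constants(m)
    ss <- steady_states(d)
    ok <- ss$physical & ss$stability == "stable"
    expect_equal(sum(ok), 1L)
    expect_false(ss$physical[2])
  }
})

test_that("the degenerate double root at the transcritical point is signalled", {
  d <- derive_constants(polarity_model(N_T = 900, k_on = 0))
  expect_warning(ss <- steady_states(d), "degenerate")
  expect_true(ss$degenerate)
})

test_that("density trajectories stay put at equilibrium and approach the stable root monotonically", {
  m <- polarity_model(N_T = 450, k_on = 0)
  d <- derive_constants(m)
  ss <- steady_states(d)
  tr <- integrate_density(m, ss$roots[1], t_end = 5)
  expect_true(all(abs(tr$rho_c - ss$roots[1]) < 1e-6))

  # rho_T < rho_star: monotone rise to rho_T
  tr2 <- integrate_density(m, 0.9 * d$rho_T, t_end = 5)
  expect_true(all(diff(tr2$rho_c) >= -1e-8))
  expect_lt(abs(tr2$rho_c[nrow(tr2)] - d$rho_T), 1e-5 * d$rho_T)

  # rho_T > rho_star from just above rho_star: monotone decay to rho_star
  m3 <- polarity_model(N_T = 1800, k_on = 0)
  d3 <- derive_constants(m3)
  tr3 <- integrate_density(m3, 1.05 * d3$rho_star, t_end = 5)
  expect_true(all(diff(tr3$rho_c) <= 1e-8))
  expect_lt(abs(tr3$rho_c[nrow(tr3)] - d3$rho_star), 1e-5 * d3$rho_star)
})

test_that("integration limit agrees with the analytic stable root across random draws", {
  set.seed(505)
  done <- 0
  while (done < 20) {
    m <- random_model()
    m$N_T <- m$N_T + 1L
    d <- derive_constants(m)
    # near the bifurcation point relaxation is critically slow; stay away
    if (abs(d$R0 - 1) < 0.25) next
    done <- done + 1
    ss <- steady_states(d)
    tr <- integrate_density(m, 0.5 * d$rho_T, t_end = 300 / m$k_off)
    expect_lt(abs(tr$rho_c[nrow(tr)] - ss$roots[1]),
              1e-5 * max(1, d$rho_star))
  }
})

test_that("bifurcation scans show the exchange of stability and membrane-fraction curve", {
  m0 <- polarity_model(N_T = 900, k_on = 0)
  grid <- seq(100, 1800, by = 100)
  bs <- bifurcation_scan(m0, grid)
  # transcritical: below rho_star the stable root is rho_T, above it is rho_star
  below <- bs$rho_T < 900
  expect_equal(bs$root_small[below], bs$rho_T[below])
  expect_equal(bs$root_small[!below], rep(900, sum(!below)))
  expect_true(all(bs$membrane_fraction[below] == 0))
  # closed form at rho_T = 2 rho_star
  expect_equal(bs$membrane_fraction[bs$rho_T == 1800], 0.5)

  # small alpha: smooth, strictly increasing, positive, pointwise near alpha=0
  m1 <- polarity_model(N_T = 900)
  d1 <- derive_constants(m1)
  m1_small <- m1; m1_small$k_on <- 9e-3 * m1$k_off  # alpha = 9e-3
  bs1 <- bifurcation_scan(m1_small, grid)
  expect_true(all(bs1$membrane_fraction > 0))
  expect_true(all(diff(bs1$membrane_fraction) > 0))
  m1_tiny <- m1; m1_tiny$k_on <- 9e-6 * m1$k_off
  bs2 <- bifurcation_scan(m1_tiny, grid)
  expect_true(all(abs(bs2$membrane_fraction - bs$membrane_fraction) <
                    abs(bs1$membrane_fraction - bs$membrane_fraction) + 1e-12))
})
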