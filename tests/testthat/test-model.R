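test_that("plasma concentration matches the bi-exponential closed form", {
  p <- gfap_params(); sc <- nominal_scenario()

  expect_identical(plasma_concentration(p, sc, 0), 0)
  expect_equal(plasma_concentration(p, injury_scenario(D0 = 0), c(0, 1, 10, 100)),
               rep(0, 4))
  # frozen from a direct high-precision evaluation of the closed form
  expect_equal(plasma_concentration(p, sc, 5), 20.0489627678, tolerance = 1e-9)

  # agrees with the independent literal formula on random valid inputs
  set.seed(42)
  for (i in 1:25) {
    ka <- runif(1, 0.002, 1); ke <- runif(1, 0.001, ka * 0.99)
    D0 <- runif(1, 1e4, 1e6); Vd <- runif(1, 3000, 7000); t <- runif(1, 0, 300)
    expect_equal(
      plasma_concentration(kinetic_params(ka, ke), injury_scenario(D0, Vd), t),
      oracle_cp(ka, ke, 0.8, D0, Vd, t), tolerance = 1e-12)
  }
})

test_that("concentration input validation rejects bad domains", {
  p <- gfap_params(); sc <- nominal_scenario()
  expect_error(plasma_concentration(p, sc, -1), ">= 0")
  expect_error(kinetic_params(-0.1, 0.02), "ka")
  expect_error(kinetic_params(0.1, 0), "ke")
  expect_error(kinetic_params(0.1, 0.02, F = 1.4), "F")
  expect_error(injury_scenario(D0 = -5), "D0")
  expect_error(injury_scenario(Vd = 0), "Vd")
})

test_that("the ka = ke singularity is handled continuously", {
  ke <- 0.05; sc <- nominal_scenario(); t <- c(1, 10, 20, 100)
  at_limit <- plasma_concentration(kinetic_params(ke, ke), sc, t)
  near <- plasma_concentration(kinetic_params(ke * (1 + 1e-8), ke), sc, t)
  expect_equal(near, at_limit, tolerance = 1e-6)
  # analytic limit formula: F*D0*ka*t*exp(-ka*t)/Vd
  expect_equal(at_limit, 0.8 * 4e5 * ke * t * exp(-ke * t) / 5000,
               tolerance = 1e-12)
})

test_that("compartment amounts satisfy the mass balance", {
  p <- gfap_params(); sc <- nominal_scenario()

  st0 <- amounts_at(p, sc, 0)
  expect_equal(st0$D_br, sc$D0)
  expect_equal(st0$D_bl, 0)

  # both compartments empty after ~20 elimination half-lives
  late <- amounts_at(p, sc, 20 * 0.693 / p$ke)
  expect_lt(late$D_br / sc$D0, 1e-6)
  expect_lt(late$D_bl / sc$D0, 1e-3)

  # central difference of D_bl reproduces inflow - outflow at t = 5
  h <- 1e-4
  dDbl <- (amounts_at(p, sc, 5 + h)$D_bl - amounts_at(p, sc, 5 - h)$D_bl) / (2 * h)
  st <- amounts_at(p, sc, 5)
  expect_equal(dDbl, p$F * p$ka * st$D_br - p$ke * st$D_bl, tolerance = 1e-6)
})

test_that("half-life and elimination rate interconvert with 0.693", {
  expect_equal(ke_from_half_life(1.5), 0.462)
  expect_equal(ke_from_half_life(36), 0.01925)
  expect_equal(half_life_from_ke(0.462), 1.5)
  expect_equal(half_life_from_ke(0.693), 1.0)
  # exact ln 2 variant available
  expect_equal(ke_from_half_life(2, const = log(2)), log(2) / 2)

  set.seed(7)
  x <- runif(20, 0.1, 800)
  expect_equal(ke_from_half_life(2 * x), ke_from_half_life(x) / 2)
  expect_equal(half_life_from_ke(ke_from_half_life(x)), x)

  expect_error(ke_from_half_life(0), "positive")
  expect_error(half_life_from_ke(-1), "positive")
})

test_that("time of peak matches the closed form and the grid argmax", {
  expect_equal(time_of_peak(kinetic_params(0.009, 0.0014))$Tmax, 244.8358,
               tolerance = 1e-6)
  expect_equal(time_of_peak(gfap_params())$Tmax, 23.4254, tolerance = 1e-6)
  # removable limit at ka = ke
  expect_equal(time_of_peak(kinetic_params(0.1, 0.1))$Tmax, 10)

  # closed form sits at the grid argmax
  p <- gfap_params(); sc <- nominal_scenario()
  grid <- seq(0, 200, by = 0.01)
  argmax <- grid[which.max(plasma_concentration(p, sc, grid))]
  expect_equal(time_of_peak(p)$Tmax, argmax, tolerance = 0.02)

  pk <- time_of_peak(p, sc)
  expect_equal(pk$Cmax, plasma_concentration(p, sc, pk$Tmax))
  expect_equal(pk$t_half, 0.693 / p$ke)
})

test_that("ka recovered from Tmax agrees with a bisection oracle", {
  expect_equal(ka_from_tmax(240, 0.0014), oracle_ka_bisect(240, 0.0014),
               tolerance = 1e-9)
  expect_equal(round(ka_from_tmax(240, 0.0014), 3), 0.009)

  # peak time of the returned ka reproduces the requested Tmax
  set.seed(3)
  for (i in 1:20) {
    ke <- runif(1, 0.001, 0.5); tmax <- runif(1, 0.3, 0.9) / ke
    ka <- ka_from_tmax(tmax, ke)
    expect_gt(ka, ke)
    expect_equal(time_of_peak(kinetic_params(ka, ke))$Tmax, tmax,
                 tolerance = 1e-9)
  }

  # round trip through the forward map
  ka0 <- 0.08; ke0 <- 0.0193
  expect_equal(ka_from_tmax(time_of_peak(kinetic_params(ka0, ke0))$Tmax, ke0),
               ka0, tolerance = 1e-9)
})

test_that("flip-flop branch selection works and degenerates at Tmax*ke = 1", {
  # the two branches give mirrored rate pairs with the same Tmax
  fast <- ka_from_tmax(24, 0.0193, branch = "absorption-faster")
  slow <- ka_from_tmax(24, 0.08, branch = "absorption-slower")
  # symmetry: Tmax(ka, ke) = Tmax(ke, ka); solving for the slower rate given
  # the faster one recovers the partner root
  expect_equal(time_of_peak(kinetic_params(0.08, slow))$Tmax, 24,
               tolerance = 1e-8)
  expect_lt(slow, 0.08)
  expect_gt(fast, 0.0193)

  deg <- ka_from_tmax(10, 0.1)
  expect_equal(as.numeric(deg), 0.1)
  expect_true(attr(deg, "degenerate"))

  # a peak later than 1/ke cannot come from faster absorption
  expect_error(ka_from_tmax(2000, 0.0014, branch = "absorption-faster"), "branch")
})

test_that("curves over a grid are consistent, linear in D0, with the right AUC", {
  p <- gfap_params(); sc <- nominal_scenario()

  empty <- curve_over_grid(p, sc, numeric(0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("time_hr", "level_pg_ml"))

  expect_error(curve_over_grid(p, sc, c(3, 2, 5)), "increasing")

  grid <- seq(0, 2000, by = 0.1)
  cur <- curve_over_grid(p, sc, grid)
  auc <- sum(diff(grid) * (head(cur$level_pg_ml, -1) + tail(cur$level_pg_ml, -1)) / 2)
  expect_equal(auc, 0.8 * 4e5 / (0.0193 * 5000), tolerance = 1e-3)

  doubled <- curve_over_grid(p, injury_scenario(D0 = 8e5), grid[1:100])
  expect_equal(doubled$level_pg_ml, 2 * cur$level_pg_ml[1:100])
})

test_that("the curve rises to the peak and falls after it", {
  set.seed(11)
  for (i in 1:10) {
    ka <- runif(1, 0.01, 1); ke <- runif(1, 0.001, ka * 0.95)
    p <- kinetic_params(ka, ke)
    tmax <- time_of_peak(p)$Tmax
    up <- plasma_concentration(p, nominal_scenario(),
                               seq(tmax / 100, tmax, length.out = 50))
    down <- plasma_concentration(p, nominal_scenario(),
                                 seq(tmax, 10 * tmax, length.out = 50))
    expect_true(all(diff(up) > 0))
    expect_true(all(diff(down) < 0))
  }
})
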