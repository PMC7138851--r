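test_that("dalziel_rate matches direct evaluation of the rate law", {
  # HsGrx5-loop-like reciprocal coefficients: 2e3 and 5e3 1/(M s)
  p <- ping_pong_params(phi0 = 1, phi1 = 1 / 2000, phi2 = 1 / 5000)
  v <- dalziel_rate(p, enzyme0 = 1e-6, gssr = 1e-4, gsh = 1e-3)
  expect_equal(v, 1e-6 / (1 + 1 / (2000 * 1e-4) + 1 / (5000 * 1e-3)))

  # saturation limit: v/e0 -> 1/phi0 as both substrates -> infinity
  expect_equal(dalziel_rate(p, 1, 1e6, 1e6), 1 / p$phi0, tolerance = 1e-5)
  # no enzyme, no rate
  expect_identical(dalziel_rate(p, 0, 1e-4, 1e-3), 0)
  # domain errors on non-positive substrate
  expect_error(dalziel_rate(p, 1e-6, 0, 1e-3), "gssr")
  expect_error(dalziel_rate(p, 1e-6, 1e-4, -1), "gsh")
})

test_that("dalziel_rate is monotone in substrates and enzyme", {
  p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1 / 1e5)
  s <- seq(1e-6, 1e-3, length.out = 25)
  expect_true(all(diff(dalziel_rate(p, 1e-8, s, 1e-3)) > 0))
  expect_true(all(diff(dalziel_rate(p, 1e-8, 1e-4, s)) > 0))
  e <- seq(0, 1e-7, length.out = 10)
  expect_true(all(diff(dalziel_rate(p, e, 1e-4, 1e-3)) > 0))
})

test_that("phi_from_microscopic has the stated limiting forms", {
  # no unproductive dissociation: 1/phi1 equals the association rate
  k <- microscopic_rates(k1 = 1e5, k_minus1 = 0, k2 = 100,
                         k4 = 2e4, k_minus4 = 5, k5 = 50)
  p <- phi_from_microscopic(k)
  expect_equal(1 / p$phi1, 1e5)
  # equal chemical steps: phi0 = 2/k2
  k2 <- microscopic_rates(k1 = 1e5, k_minus1 = 10, k2 = 100,
                          k4 = 2e4, k_minus4 = 5, k5 = 100)
  expect_equal(phi_from_microscopic(k2)$phi0, 2 / 100)
  expect_error(microscopic_rates(k1 = -1, k_minus1 = 0, k2 = 1,
                                 k4 = 1, k_minus4 = 0, k5 = 1))
})

test_that("Dalziel mapping agrees with the mass-action steady-state oracle", {
  set.seed(42)
  rel_err <- replicate(100, {
    k <- random_rates()
    gssr <- 10^runif(1, -5, -3)
    gsh <- 10^runif(1, -4, -2)
    v_closed <- dalziel_rate(phi_from_microscopic(k), 1e-6, gssr, gsh)
    v_ode <- steady_state_rate_ode(k, 1e-6, gssr, gsh)
    abs(v_closed - v_ode) / v_ode
  })
  expect_true(all(rel_err < 1e-6))
})

test_that("half-reaction rate constants are bounded by the association steps", {
  set.seed(7)
  for (i in 1:50) {
    k <- random_rates()
    p <- phi_from_microscopic(k)
    expect_lte(1 / p$phi1, k$k1 * (1 + 1e-12))
    expect_lte(1 / p$phi2, k$k4 * (1 + 1e-12))
  }
})

test_that("simulated progress curves behave like the photometric assay", {
  p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1 / 1e5)
  cond <- assay_conditions(enzyme0 = 10e-9, gssr0 = 1e-4, gsh0 = 1e-3)
  curve <- simulate_assay(p, cond, t_end = 330, dt = 1)

  # flat 30 s baseline, then monotone non-increasing A340
  base <- curve$a340[curve$time < cond$baseline_s]
  expect_true(all(abs(base - base[1]) < 1e-12))
  post <- curve$a340[curve$time >= cond$baseline_s]
  expect_true(all(diff(post) <= 1e-12))

  # initial slope matches the rate law within 1 %
  v0_pred <- dalziel_rate(p, cond$enzyme0, cond$gssr0, cond$gsh0)
  sel <- curve$time >= 30 & curve$time <= 40
  slope <- coef(lm(a340 ~ time, curve[sel, ]))[[2]]
  expect_equal(-slope / 6220, v0_pred, tolerance = 0.01)

  # stoichiometric bound on the total absorbance drop
  expect_lte(curve$a340[1] - min(curve$a340), 6220 * 1 * 1e-4 + 1e-9)

  # glutathione moieties conserved: gsh + gssr + 2 gssg constant
  moieties <- curve$gsh + curve$gssr + 2 * curve$gssg
  expect_equal(max(abs(moieties - moieties[1])), 0, tolerance = 1e-9)

  # no enzyme -> flat curve
  cond0 <- assay_conditions(enzyme0 = 0, gssr0 = 1e-4, gsh0 = 1e-3)
  flat <- simulate_assay(p, cond0, t_end = 120)
  expect_equal(diff(range(flat$a340)), 0, tolerance = 1e-12)
})

test_that("finite-GR mode also conserves glutathione moieties", {
  p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1 / 1e5)
  cond <- assay_conditions(enzyme0 = 10e-9, gssr0 = 1e-4, gsh0 = 5e-4)
  curve <- simulate_assay(p, cond, t_end = 200, gr_mode = "finite")
  moieties <- curve$gsh + curve$gssr + 2 * curve$gssg
  expect_equal(max(abs(moieties - moieties[1])) / moieties[1], 0,
               tolerance = 1e-6)
})

test_that("initial_rate extracts v0 from slope and round trips", {
  # perfectly linear synthetic curve of slope -0.01 AU/s
  cond <- assay_conditions(enzyme0 = 1e-8, gssr0 = 1e-4, gsh0 = 1e-3)
  tt <- seq(0, 120, by = 1)
  lin <- structure(
    data.frame(time = tt, a340 = 0.622 - 0.01 * pmax(tt - 30, 0)),
    class = c("progress_curve", "data.frame"), meta = cond)
  expect_equal(initial_rate(lin, window = 60), 0.01 / 6220)

  # flat curve -> 0
  flat <- structure(data.frame(time = tt, a340 = rep(0.6, length(tt))),
                    class = c("progress_curve", "data.frame"), meta = cond)
  expect_equal(initial_rate(flat), 0)

  # window must hold >= 3 samples
  expect_error(initial_rate(lin, window = 1), "3 samples")

  # round trip through the simulator within 1 %
  p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1 / 1e5)
  curve <- simulate_assay(p, cond, t_end = 90, dt = 0.5)
  v0 <- dalziel_rate(p, cond$enzyme0, cond$gssr0, cond$gsh0)
  expect_equal(initial_rate(curve, window = 10), v0, tolerance = 0.01)
})
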