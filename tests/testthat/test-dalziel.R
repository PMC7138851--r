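test_that("blank correction subtracts matched reference rates", {
  raw <- rate_grid(gssr = c(1e-4, 1e-4), gsh = c(1e-3, 5e-4),
                   enzyme0 = 1e-8, rate = c(1e-7, 1e-7))
  zero <- rate_grid(gssr = c(1e-4, 1e-4), gsh = c(1e-3, 5e-4),
                    enzyme0 = 0, rate = c(0, 0))
  expect_equal(blank_correct(raw, zero)$rate, raw$rate)

  same <- blank_correct(raw, raw)
  expect_true(all(same$rate == 0))

  ref <- rate_grid(gssr = c(1e-4, 1e-4), gsh = c(1e-3, 5e-4),
                   enzyme0 = 0, rate = c(2e-8, 2e-8))
  corr <- blank_correct(rate_grid(gssr = c(1e-4, 1e-4),
                                  gsh = c(1e-3, 5e-4), enzyme0 = 1e-8,
                                  rate = c(1e-7, 1e-7)), ref)
  expect_equal(corr$rate, c(8e-8, 8e-8))

  bad <- rate_grid(gssr = c(2e-4, 2e-4), gsh = c(1e-3, 5e-4),
                   enzyme0 = 0, rate = c(0, 0))
  expect_error(blank_correct(raw, bad), "matching conditions")
})

test_that("apparent MM fits recover generator parameters", {
  s <- c(25, 50, 100, 200, 400, 800) * 1e-6
  grid <- rate_grid(gssr = rep(1e-4, 6), gsh = s, enzyme0 = 1e-8,
                    rate = mm_rates(s, kcat = 10, km = 200e-6))
  fit <- fit_apparent_mm(grid, fixed = "gssr")
  expect_equal(fit$kcat_app, 10, tolerance = 1e-3)
  expect_equal(fit$km_app, 200e-6, tolerance = 1e-3)
  expect_false(fit$degenerate)
})

test_that("ridge-line data flag unidentifiable km but fix the efficiency", {
  s <- c(1, 2, 4, 8, 16) * 1e-6  # km >> s: v ~ (kcat/km) * s
  kcat <- 10; km <- 0.05
  grid <- rate_grid(gssr = rep(1e-4, 5), gsh = s, enzyme0 = 1e-8,
                    rate = mm_rates(s, kcat, km))
  fit <- fit_apparent_mm(grid, fixed = "gssr")
  expect_true(fit$degenerate)
  expect_equal(fit$kcat_app / fit$km_app, kcat / km, tolerance = 0.01)
})

test_that("constant rates give a degenerate flag", {
  s <- c(25, 50, 100, 200) * 1e-6
  grid <- rate_grid(gssr = rep(1e-4, 4), gsh = s, enzyme0 = 1e-8,
                    rate = rep(5e-8, 4))
  fit <- fit_apparent_mm(grid, fixed = "gssr")
  expect_true(fit$degenerate)
})

test_that("all three linearisations agree with the generator on noiseless data", {
  s <- c(25, 50, 100, 200, 400, 800) * 1e-6
  kcat <- 10; km <- 200e-6; e0 <- 1e-8
  v <- mm_rates(s, kcat, km, e0)
  for (m in c("lineweaver_burk", "eadie_hofstee", "hanes")) {
    lin <- linearize(s, v, enzyme0 = e0, method = m)
    expect_equal(lin$kcat_app, kcat, tolerance = 1e-6, label = m)
    expect_equal(lin$km_app, km, tolerance = 1e-6, label = m)
  }
  # Hanes slope is 1/Vmax
  expect_equal(linearize(s, v, method = "hanes")$slope, 1 / (e0 * kcat),
               tolerance = 1e-6)
  # km = 0: v = Vmax exactly, Lineweaver-Burk line is horizontal
  lb <- linearize(s, rep(e0 * kcat, length(s)), method = "lineweaver_burk")
  expect_equal(lb$slope, 0, tolerance = 1e-12)
})

test_that("Dalziel fit recovers the generating coefficients exactly", {
  set <- load_variant("HsGrx5_loop")
  fit <- fit_dalziel(generate_rate_grid(set))
  expect_equal(fit$reciprocal$phi1_inv, 2000, tolerance = 1e-3)
  expect_equal(fit$reciprocal$phi2_inv, 5000, tolerance = 1e-3)
  # reported reciprocals are element-wise reciprocals of the fitted Phi
  expect_equal(fit$reciprocal$phi1_inv, 1 / fit$params$phi1)
  expect_equal(fit$reciprocal$kcat_true, 1 / fit$params$phi0)
})

test_that("one-stage and two-stage Dalziel routes coincide on noiseless data", {
  fit <- fit_dalziel(generate_rate_grid(load_variant("WT")))
  expect_equal(fit$two_stage$phi0, fit$params$phi0, tolerance = 1e-8)
  expect_equal(fit$two_stage$phi1, fit$params$phi1, tolerance = 1e-8)
  expect_equal(fit$two_stage$phi2, fit$params$phi2, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected", {
  g <- rate_grid(gssr = rep(1e-4, 4), gsh = c(1, 2, 4, 8) * 1e-4,
                 enzyme0 = 1e-8, rate = rep(1e-8, 4))
  expect_error(fit_dalziel(g), "rank-deficient")
})

test_that("ping-pong closed-form consistency links the MM and Dalziel layers", {
  p <- load_variant("WT")$kinetic
  gssr_levels <- c(25, 50, 100, 150) * 1e-6
  s <- seq(50e-6, 1.5e-3, length.out = 8)
  for (cg in gssr_levels) {
    v <- dalziel_rate(p, 1e-8, cg, s)
    grid <- rate_grid(gssr = rep(cg, 8), gsh = s, enzyme0 = 1e-8, rate = v)
    fit <- fit_apparent_mm(grid, fixed = "gssr")
    # kcat_app at fixed [GSSR] is 1/(phi0 + phi1/[GSSR])
    expect_equal(fit$kcat_app, 1 / (p$phi0 + p$phi1 / cg), tolerance = 1e-4)
    # catalytic efficiency for GSH is the reciprocal Dalziel coefficient,
    # independent of the fixed co-substrate level (parallel-line signature)
    expect_equal(fit$kcat_app / fit$km_app, 1 / p$phi2, tolerance = 1e-4)
  }
})

test_that("parallel Lineweaver-Burk lines signal the ping-pong mechanism", {
  p <- load_variant("WT")$kinetic
  s <- seq(50e-6, 1.5e-3, length.out = 8)
  slopes <- vapply(c(25, 150) * 1e-6, function(cg) {
    v <- dalziel_rate(p, 1e-8, cg, s) / 1e-8
    linearize(s, v, method = "lineweaver_burk")$slope
  }, numeric(1))
  expect_equal(slopes[1], slopes[2], tolerance = 1e-9)
})

test_that("Dalziel recovery under 2 % multiplicative noise is accurate", {
  set <- load_variant("WT")
  true_r <- reciprocal_coefficients(set$kinetic)
  rel_err <- vapply(1:200, function(i) {
    g <- generate_rate_grid(set, noise_model("multiplicative_gaussian",
                                             sd = 0.02, seed = i))
    fit <- fit_dalziel(g)
    max(abs(fit$reciprocal$phi1_inv / true_r$phi1_inv - 1),
        abs(fit$reciprocal$phi2_inv / true_r$phi2_inv - 1))
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})

test_that("variant comparison reports the expected ratios", {
  wt <- fit_dalziel(generate_rate_grid(load_variant("WT")))
  expect_equal(compare_variants(wt, wt)$ratio, rep(1, 3), tolerance = 1e-9)

  mut <- fit_dalziel(generate_rate_grid(load_variant("E147K")))
  cmp <- compare_variants(wt, mut)
  expect_equal(cmp$ratio[cmp$quantity == "phi2_inv"], 2.5, tolerance = 1e-6)

  r153a <- fit_dalziel(generate_rate_grid(load_variant("R153A")))
  cmp2 <- compare_variants(wt, r153a)
  expect_equal(cmp2$percent_reduction[cmp2$quantity == "phi1_inv"], 60,
               tolerance = 1e-6)

  # ratio(a,b) * ratio(b,a) = 1
  ab <- compare_variants(wt, mut)$ratio
  ba <- compare_variants(mut, wt)$ratio
  expect_equal(ab * ba, rep(1, 3), tolerance = 1e-9)

  # mismatched substrate labels are rejected
  heds <- fit_dalziel(rate_grid(gssr = rep(c(1e-4, 2e-4), each = 4),
                                gsh = rep(c(1, 2, 4, 8) * 1e-4, 2),
                                enzyme0 = 1e-8,
                                rate = dalziel_rate(load_variant("WT")$kinetic,
                                                    1e-8,
                                                    rep(c(1e-4, 2e-4), each = 4),
                                                    rep(c(1, 2, 4, 8) * 1e-4, 2)),
                                substrate_label = "HEDS"))
  expect_error(compare_variants(wt, heds), "substrate labels")
})

test_that("GSH-independent rates yield a vanishing phi2 reported as bound", {
  # generator with phi2 -> 0: rates do not depend on GSH
  p <- ping_pong_params(phi0 = 0.02, phi1 = 1 / 2e5, phi2 = 1e-12)
  d <- expand.grid(gssr = c(25, 50, 100, 150) * 1e-6,
                   gsh = seq(50e-6, 1.5e-3, length.out = 8))
  g <- rate_grid(gssr = d$gssr, gsh = d$gsh, enzyme0 = 1e-8,
                 rate = dalziel_rate(p, 1e-8, d$gssr, d$gsh))
  fit <- fit_dalziel(g)
  expect_lt(fit$params$phi2, 1e-8)
})
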