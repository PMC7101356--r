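test_that("hill_predict has the fixed-asymptote logistic form", {
  expect_equal(hill_predict(-6, -6, 1), 50)        # midpoint
  expect_equal(hill_predict(-30, -6, 1), 0, tolerance = 1e-12)
  expect_equal(hill_predict(30, -6, 1), 100, tolerance = 1e-12)
  expect_equal(hill_predict(-5, -6, 1), 100 / (1 + 10^-1)) # 90.909...
  # strictly increasing in log concentration
  x <- seq(-9, -3, 0.1)
  expect_true(all(diff(hill_predict(x, -6, 0.7)) > 0))
})

test_that("noiseless Hill data are recovered essentially exactly", {
  for (pars in list(c(-6, 1), c(-7.3, 0.6), c(-5.1, 1.8))) {
    pts <- make_hill_points(pars[1], pars[2])
    f <- fit_hill(pts, apc_config())
    expect_equal(f$fit_status, "ok")
    expect_equal(f$log10_ic50, pars[1], tolerance = 1e-6)
    expect_equal(f$hill_slope, pars[2], tolerance = 1e-6)
    expect_lt(f$rss, 1e-10)
  }
})

test_that("fitted slope and IC50 respect the stated constraints", {
  set.seed(11)
  for (i in 1:20) {
    pts <- make_hill_points(runif(1, -8, -5), runif(1, 0.3, 1.9),
                            noise_sd = 8)
    f <- fit_hill(pts, apc_config())
    if (f$fit_status != "ok") next
    expect_gt(f$hill_slope, 0)
    expect_lt(f$hill_slope, 2)
    expect_gte(f$log10_ic50, log10(min(pts$concentration)) - 2)
    expect_lte(f$log10_ic50, log10(max(pts$concentration)) + 2)
  }
})

test_that("the no-fit rule censors flat or small responses", {
  # small effect size: max mean inhibition 15%
  small <- make_hill_points(-6, 1, max_block = 15)
  expect_equal(fit_hill(small, apc_config())$fit_status, "no_fit")
  # boundary: exactly 20% maximal effect is still censored (<= rule)
  edge <- make_hill_points(-20, 1)  # plateau ~ 100 at all concs
  edge$pct_inhibition <- c(20, 18, 19, 20, 17, 18, 20)
  expect_equal(fit_hill(edge, apc_config())$fit_status, "no_fit")
  # concentration-inversely-related response is censored too
  dec <- make_hill_points(-6, 1)
  dec$pct_inhibition <- rev(dec$pct_inhibition)
  expect_equal(fit_hill(dec, apc_config())$fit_status, "no_fit")
  # above threshold with real concentration dependence fits
  ok <- make_hill_points(-6, 1, max_block = 60)
  expect_equal(fit_hill(ok, apc_config())$fit_status, "ok")
})

test_that("fewer than four usable concentrations is insufficient data", {
  pts <- make_hill_points(-6, 1, concs = 10^c(-7, -6.5, -6))
  expect_equal(fit_hill(pts, apc_config())$fit_status,
               "insufficient_data")
  # a 4-conc series whose lowest point lacks wells degrades to the same
  pts4 <- make_hill_points(-6, 1, concs = 10^c(-7, -6.5, -6, -5.5))
  pts4$n_wells[1] <- 2L
  pts4$insufficient[1] <- TRUE
  expect_equal(fit_hill(pts4, apc_config())$fit_status,
               "insufficient_data")
})

test_that("fit is invariant to row order of the concentration series", {
  set.seed(3)
  pts <- make_hill_points(-6.4, 1.2, noise_sd = 5)
  f1 <- fit_hill(pts, apc_config())
  f2 <- fit_hill(pts[sample(nrow(pts)), ], apc_config())
  expect_equal(f1, f2)
})

test_that("noisy fits agree with a dense grid-search oracle", {
  set.seed(21)
  for (i in 1:3) {
    true_l <- runif(1, -7, -6)
    pts <- make_hill_points(true_l, 1, noise_sd = 5)
    f <- fit_hill(pts, apc_config())
    expect_equal(f$fit_status, "ok")
    g <- grid_search_hill(pts$concentration, pts$pct_inhibition,
                          lgrid = seq(true_l - 1, true_l + 1, 0.005),
                          hgrid = seq(0.25, 1.95, 0.005))
    expect_equal(f$log10_ic50, g$log10_ic50, tolerance = 0.005)
    expect_equal(f$hill_slope, g$hill_slope, tolerance = 0.005)
    expect_lte(f$rss, g$rss + 1e-8)
  }
})

test_that("single-concentration inversion is the exact inverse of the curve", {
  expect_equal(invert_single_concentration(5e-8, 50), 5e-8)
  # composition identity over a parameter sweep
  set.seed(9)
  for (i in 1:25) {
    ic50 <- 10^runif(1, -9, -5)
    h <- runif(1, 0.3, 1.9)
    conc <- 10^runif(1, -9, -5)
    inh <- hill_predict(log10(conc), log10(ic50), h)
    expect_equal(invert_single_concentration(conc, inh, h), ic50,
                 tolerance = 1e-9)
  }
  expect_error(invert_single_concentration(1e-7, 0), "between 0 and 100")
  expect_error(invert_single_concentration(1e-7, 100), "between 0 and 100")
})

test_that("historical single-concentration block brackets known IC50 ranges", {
  # terfenadine: 60 nM at mean -/+ 2 SD of 81.7 +/- 7.0 % block
  expect_equal(signif(invert_single_concentration(60, 81.7 - 2 * 7.0), 2),
               29)
  expect_equal(signif(invert_single_concentration(60, 81.7 + 2 * 7.0), 1),
               3)
  # cisapride: 90 nM at 83.4 - 2 x 7.7 % block
  expect_equal(signif(invert_single_concentration(90, 83.4 - 2 * 7.7), 2),
               42)
})
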