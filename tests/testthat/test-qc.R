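test_that("QC criteria fail individually and thresholds are inclusive", {
  cfg <- apc_config()
  # Rm just below threshold, everything else fine
  r <- passes_qc(make_well(rm = 199), cfg)
  expect_false(r$passed)
  expect_equal(r$reasons, "low_Rm")
  # boundaries are inclusive: Rm = 200 with leak exactly 25% of peak
  b <- passes_qc(make_well(pre = 0.8, post = 0.5, endblk = 0.2, rm = 200),
                 cfg)
  expect_equal(abs(b$endblocker_current), 0.25 * abs(b$pre_drug_current))
  expect_true(b$passed)
  expect_equal(b$reasons, "")
  # baseline exactly at the 0.2 nA threshold also passes
  b2 <- passes_qc(make_well(pre = 0.2, post = 0.1, endblk = 0, rm = 300),
                  cfg)
  expect_true(b2$passed)
  # interior point
  g <- passes_qc(make_well(pre = 1, post = 0.5, endblk = 0.05, rm = 500),
                 cfg)
  expect_true(g$passed)
  # zero pre-drug current fails as low baseline
  z <- passes_qc(make_well(pre = 0, post = 0, endblk = 0), cfg)
  expect_false(z$passed)
  expect_true(z$low_baseline)
})

test_that("tightening any QC threshold can only shrink the passing set", {
  set.seed(42)
  wells <- dplyr::bind_rows(lapply(1:60, function(i) {
    make_well(pre = runif(1, 0.1, 2), post = runif(1, 0, 1.5),
              endblk = runif(1, 0, 0.5), rm = runif(1, 100, 900),
              well = sprintf("w%03d", i))
  }))
  base <- passes_qc(wells, apc_config())$passed
  tighter <- list(
    apc_config(min_rm_mohm = 400),
    apc_config(max_leak_fraction = 0.1),
    apc_config(min_baseline_na = 0.5)
  )
  for (cfg in tighter) {
    expect_true(all(passes_qc(wells, cfg)$passed <= base))
  }
})

test_that("percent inhibition matches the leak-subtracted formula", {
  expect_equal(percent_inhibition(1.0, 0.4, 0.2), 75)
  expect_equal(percent_inhibition(0.8, 0.8, 0.3), 0)   # no block
  expect_equal(percent_inhibition(0.8, 0.2, 0.2), 100) # full block
  # invariant to common rescaling of all three currents
  expect_equal(percent_inhibition(2.2, 1.3, 0.4),
               percent_inhibition(7 * 2.2, 7 * 1.3, 7 * 0.4))
  expect_error(percent_inhibition(0.2, 0.1, 0.2), "undefined")
})

test_that("aggregation reproduces per-well means and flags small groups", {
  # three wells engineered to give inhibitions 70, 75, 80
  wells <- dplyr::bind_rows(
    make_well(pre = 1.1, post = 0.1 + 0.30, well = "w1"),
    make_well(pre = 1.1, post = 0.1 + 0.25, well = "w2"),
    make_well(pre = 1.1, post = 0.1 + 0.20, well = "w3")
  )
  pt <- aggregate_inhibition(wells, apc_config())
  expect_equal(nrow(pt), 1)
  expect_equal(pt$pct_inhibition, 75)
  expect_equal(pt$sd, 5)
  expect_equal(pt$n_wells, 3L)
  expect_false(pt$insufficient)
  # brute-force mean equality
  expect_equal(pt$pct_inhibition,
               mean(percent_inhibition(wells$pre_drug_current,
                                       wells$steady_state_current,
                                       wells$endblocker_current)))
  # two wells only -> insufficient; identical wells -> sd 0
  two <- aggregate_inhibition(wells[1:2, ], apc_config())
  expect_true(two$insufficient)
  same <- aggregate_inhibition(wells[c(1, 1, 1), ] |>
                                 dplyr::mutate(well_id = c("a", "b", "c")),
                               apc_config())
  expect_equal(same$sd, 0)
})

test_that("vehicle correction is a plain, non-idempotent shift", {
  pts <- tibble::tibble(pct_inhibition = c(10, 20))
  expect_equal(vehicle_correction(pts, 0), pts)
  expect_equal(vehicle_correction(pts, 5)$pct_inhibition, c(5, 15))
  twice <- vehicle_correction(vehicle_correction(pts, 5), 5)
  expect_equal(twice$pct_inhibition, pts$pct_inhibition - 10)
})
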