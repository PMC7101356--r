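test_that("IC50 summaries use interpolated percentiles and fold spans", {
  recs <- make_records(c(-8, -7.5, -7, -6.5, -6), "p1")
  s <- summarize_ic50(recs, apc_config())
  expect_equal(s$p25, -7.5)
  expect_equal(s$p75, -6.5)
  expect_equal(s$median, -7)
  expect_equal(s$span_log, 1)
  expect_equal(s$fold_range, 10)
  # identical records collapse to zero span / fold 1
  same <- summarize_ic50(make_records(rep(-7, 4), "p1"), apc_config())
  expect_equal(same$span_log, 0)
  expect_equal(same$fold_range, 1)
  # a 0.22 log-unit interquartile span is a 1.7-fold range
  q <- summarize_ic50(make_records(c(-6.11, -6.11, -5.89, -5.89),
                                   "p1"), apc_config())
  expect_equal(round(q$span_log, 2), 0.22)
  expect_equal(round(q$fold_range, 1), 1.7)
})

test_that("summaries exclude censored records and omit empty groups", {
  recs <- dplyr::bind_rows(
    make_records(c(-7, -7.4), "p1"),
    make_records(NA_real_, "p2", site_id = "s08", fit_status = "no_fit"),
    make_records(NA_real_, "p2", drug_id = "dB", site_id = "s09",
                 fit_status = "no_fit")
  )
  recs$hill_slope[recs$fit_status != "ok"] <- NA_real_
  s <- summarize_ic50(recs, apc_config())
  expect_equal(nrow(s), 1)  # drug dB has no ok record -> omitted
  expect_equal(s$n, 2L)
  expect_equal(s$n_censored, 1L)
  expect_equal(s$min, -7.4)
})

test_that("variance components match the hand-computed unbalanced oracle", {
  recs <- make_records(c(-7.0, -7.2, -6.5, -6.7, -6.0, -6.2),
                       rep(c("pA", "pB", "pC"), each = 2))
  vc <- variance_components(recs, apc_config())
  expect_true(vc$feasible)
  expect_equal(vc$sigma2_within, 0.02)
  expect_equal(vc$sigma2_between, 0.24)
  expect_equal(vc$pct_between, 100 * 0.24 / 0.26)
  expect_equal(vc$pct_between + vc$pct_within, 100)
})

test_that("balanced designs agree exactly with the aov decomposition", {
  set.seed(14)
  x <- rnorm(12, -6.5, 0.4)
  g <- rep(c("p1", "p2", "p3"), each = 4)
  vc <- variance_components(make_records(x, g), apc_config())
  fit <- stats::aov(x ~ factor(g))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_equal(vc$sigma2_within, ms[2])
  expect_equal(vc$sigma2_between, max(0, (ms[1] - ms[2]) / 4))
})

test_that("pure platform separation gives 100% between-platform variance", {
  recs <- make_records(c(-7, -7, -6, -6, -5, -5),
                       rep(c("pA", "pB", "pC"), each = 2))
  vc <- variance_components(recs, apc_config())
  expect_equal(vc$sigma2_within, 0)
  expect_equal(vc$pct_between, 100)
})

test_that("under the null the truncated between-share stays small", {
  set.seed(99)
  est <- replicate(300, {
    recs <- make_records(rnorm(12, -6, 0.3), rep(paste0("p", 1:4), 3))
    variance_components(recs, apc_config())$pct_between
  })
  # truncation at zero leaves a positive but modest mean share
  expect_lt(mean(est), 25)
})

test_that("scarce designs are reported infeasible without components", {
  # only two platforms have replicates (need three)
  recs <- make_records(c(-7, -7.1, -6.5, -6.6, -6.2),
                       c("pA", "pA", "pB", "pB", "pC"))
  vc <- variance_components(recs, apc_config())
  expect_false(vc$feasible)
  expect_true(is.na(vc$sigma2_between))
})

test_that("repeatability coefficient follows 1.96 * sqrt(2) * sigma", {
  expect_equal(repeatability_coefficient(0)$rc_fold, 1)
  rc <- repeatability_coefficient(0.2)
  expect_equal(rc$rc_log, 1.96 * sqrt(2) * 0.2)
  expect_equal(round(rc$rc_log, 4), 0.5544)
  expect_equal(round(rc$rc_fold, 3), 3.584)
  # algebraic inverse: the sigma that yields a 3.7-fold coefficient
  sig <- log10(3.7) / (1.96 * sqrt(2))
  expect_equal(repeatability_coefficient(sig)$rc_fold, 3.7)
  expect_error(repeatability_coefficient(-0.1), "non-negative")
})

test_that("per-platform repeatability pools drug-centred replicates", {
  # platform pA: two drugs with within-platform SD ~ d/sqrt(2)
  recs <- dplyr::bind_rows(
    make_records(c(-7.0, -7.2), "pA", drug_id = "dA"),
    make_records(c(-6.0, -6.4), "pA", drug_id = "dB",
                 site_id = c("s03", "s04")),
    make_records(-5.0, "pA", drug_id = "dC", site_id = "s05") # unreplicated
  )
  rp <- repeatability(recs, apc_config())
  expect_equal(rp$n_drugs, 2L)
  expect_equal(rp$df, 2L)
  # pooled SS = 0.02 + 0.08 over 2 df
  expect_equal(rp$sigma_resid, sqrt(0.05))
  expect_equal(rp$rc_fold, 10^(1.96 * sqrt(2) * sqrt(0.05)))
})

test_that("fold summaries are invariant to a global potency shift", {
  set.seed(8)
  x <- rnorm(10, -6, 0.5)
  g <- rep(c("pA", "pB"), 5)
  s1 <- summarize_ic50(make_records(x, g), apc_config())
  s2 <- summarize_ic50(make_records(x + 2, g), apc_config())
  expect_equal(s1$fold_range, s2$fold_range)
  r1 <- repeatability(make_records(x, g), apc_config())
  r2 <- repeatability(make_records(x + 2, g), apc_config())
  expect_equal(r1$rc_fold, r2$rc_fold)
})

test_that("NOEL summaries average per-drug lowest-concentration block", {
  pts <- tibble::tibble(
    site_id = "s01", platform_id = "p1", current_type = "hERG",
    drug_id = rep(c("dA", "dB", "dC"), each = 2),
    concentration = rep(c(1e-8, 1e-7), 3),
    pct_inhibition = c(5, 50, 10, 60, 15, 70),
    n_wells = 3L, sd = 1, insufficient = FALSE
  )
  ns <- noel_loel_summary(pts, apc_config())
  expect_equal(ns$mean_pct, 10)  # mean of 5, 10, 15 at lowest concs
  expect_equal(ns$sd_pct, 5)
  expect_equal(ns$n_drugs, 3L)
  # adding a constant shifts the mean, not the SD
  shifted <- dplyr::mutate(pts, pct_inhibition = pct_inhibition + 7)
  ns2 <- noel_loel_summary(shifted, apc_config())
  expect_equal(ns2$mean_pct, 17)
  expect_equal(ns2$sd_pct, 5)
})
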