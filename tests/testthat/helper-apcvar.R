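# Shared fixtures and independent oracles, built in code at test time.

# Exact concentration-response points generated from the Hill model.
make_hill_points <- function(log10_ic50 = -6, hill = 1,
                             concs = 10^seq(-8, -5, 0.5),
                             max_block = 100, noise_sd = 0, n_wells = 3L) {
  y <- max_block * hill_predict(log10(concs), log10_ic50, hill) / 100
  if (noise_sd > 0) y <- y + rnorm(length(concs), 0, noise_sd)
  tibble::tibble(concentration = concs, pct_inhibition = y,
                 n_wells = n_wells, insufficient = n_wells < 3L)
}

# Brute-force grid-search oracle for the constrained Hill fit,
# independent of the package optimizer: dense evaluation of the RSS
# over (log10_ic50, hill_slope).
grid_search_hill <- function(concs, y, lgrid, hgrid) {
  logc <- log10(concs)
  best <- c(NA, NA, Inf)
  for (h in hgrid) {
    pred <- outer(lgrid, logc, function(l, x) 100 / (1 + 10^((l - x) * h)))
    rss <- rowSums((matrix(y, nrow = length(lgrid), ncol = length(y),
                           byrow = TRUE) - pred)^2)
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(lgrid[i], h, rss[i])
  }
  list(log10_ic50 = best[1], hill_slope = best[2], rss = best[3])
}

# One synthetic well record with controllable QC-relevant fields.
make_well <- function(pre = 1.1, post = 0.6, endblk = 0.1, rm = 500,
                      site = "s01", platform = "p1", drug = "dA",
                      current = "hERG", conc = 1e-6, well = "w001") {
  tibble::tibble(
    site_id = site, platform_id = platform, current_type = current,
    drug_id = drug, plate_id = "plateA", well_id = well,
    concentration = conc, pre_drug_current = pre,
    steady_state_current = post, endblocker_current = endblk,
    membrane_resistance = rm, temperature_class = "room"
  )
}

# IC50 record table builder for the statistics modules.
make_records <- function(log10_ic50, platform_id,
                         drug_id = "dA", current_type = "hERG",
                         site_id = sprintf("s%02d", seq_along(log10_ic50)),
                         fit_status = "ok") {
  tibble::tibble(
    site_id = site_id, platform_id = platform_id, drug_id = drug_id,
    current_type = current_type, replicate_index = 0L,
    log10_ic50 = log10_ic50, hill_slope = 1,
    fit_status = fit_status
  )
}
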