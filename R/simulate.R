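# Deterministic 31-bit sub-seed from string components, so each
# (site, drug, current) group owns an independent reproducible RNG
# stream and adding a site never perturbs another site's draws.
hash_seed <- function(...) {
  s <- paste(c(...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Default ground-truth potency table for the synthetic study
#'
#' Plausible true potencies for the 12-drug panel against the four
#' cardiac currents, chosen to sit inside each drug's tested
#' concentration range. All 12 drugs block hERG; six block peak Nav1.5,
#' four block Cav1.2 and four block late Nav1.5 — the remaining
#' combinations are non-blockers (`max_block_pct = 10`), which the
#' fitting stage must censor via the no-fit rule.
#'
#' @return Tibble per drug x current: `true_log10_ic50` (log10 molar),
#'   `true_hill`, `max_block_pct`.
#' @export
apc_truth <- function() {
  drugs <- apc_drugs()$drug_id
  ic50_uM <- list(
    hERG = c(bep = 0.1, cpz = 1, cis = 0.02, dil = 30, dof = 0.03,
             mex = 50, ond = 1, qui = 0.9, ran = 30, sot = 150,
             ter = 0.06, ver = 0.25),
    peak_Nav1.5 = c(bep = 0.2, cpz = 2, dil = 50, mex = 40, qui = 5,
                    ran = 40),
    late_Nav1.5 = c(bep = 0.1, mex = 10, qui = 3, ran = 10),
    Cav1.2 = c(bep = 0.15, cpz = 1.5, dil = 20, ver = 0.3)
  )
  hill <- c(qui = 1.2, mex = 0.9)
  mid_conc <- vapply(apc_drugs()$concentrations,
                     function(cc) exp(mean(log(range(cc)))), numeric(1))
  names(mid_conc) <- drugs
  rows <- list()
  for (ct in apc_currents()) {
    blockers <- ic50_uM[[ct]]
    for (d in drugs) {
      blocks <- d %in% names(blockers)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        drug_id = d, current_type = ct,
        true_log10_ic50 = if (blocks) log10(blockers[[d]] * 1e-6)
                          else log10(mid_conc[[d]]),
        true_hill = if (ct == "hERG" && d %in% names(hill)) hill[[d]] else 1,
        max_block_pct = if (blocks) 100 else 10
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Parameters for the synthetic multi-site study generator
#'
#' Defines the hierarchical generating model behind [generate_study()]:
#' each site's effective log10 IC50 for a drug is the true value plus a
#' platform effect `b_p ~ N(0, sigma_between^2)` plus a
#' site-within-platform effect `e_s ~ N(0, sigma_within^2)`; each well's
#' percent inhibition is `max_block_pct * hill / 100` plus Gaussian well
#' noise. The defaults emulate the study conditions: half-log
#' concentration series (the panel's nominal series, or four half-log
#' steps centred on the true IC50 with `conc_design = "centered"`),
#' at least three analysable wells per concentration, and a fraction of
#' wells corrupted to violate exactly one QC criterion.
#'
#' @param drugs Drug panel (see [apc_drugs()]); its concentration series
#'   is used under the `"nominal"` design.
#' @param sites Site roster; `NULL` builds a generic roster of
#'   `n_platforms x sites_per_platform` sites all measuring `currents`.
#' @param currents Currents to simulate (subset of [apc_currents()]).
#' @param n_platforms,sites_per_platform Shape of the generic roster when
#'   `sites` is `NULL`.
#' @param truth Ground-truth table (see [apc_truth()]).
#' @param sigma_between Between-platform SD of log10 IC50 (log10 units).
#' @param sigma_within Site-within-platform SD (log10 units).
#' @param well_noise_sd Well-level inhibition noise SD (%).
#' @param wells_per_conc Wells recorded per concentration.
#' @param qc_fail_rate Fraction of wells corrupted to fail QC, in \[0, 1).
#' @param conc_design `"nominal"` (panel series) or `"centered"` (four
#'   half-log steps centred on each drug's true IC50).
#' @param baseline_na Leak-subtracted pre-drug current amplitude (nA).
#' @param endblocker_na Residual (leak) current after the end-blocker (nA).
#' @param rm_median_mohm,rm_sdlog Lognormal membrane-resistance model;
#'   draws are floored at 125% of the QC threshold so that only
#'   deliberately corrupted wells fail.
#' @param qc Thresholds used when corrupting wells (an [apc_config()]).
#' @param seed Integer master seed.
#' @return An object of class `apc_sim_params`.
#' @export
synthetic_params <- function(drugs = apc_drugs(),
                             sites = NULL,
                             currents = "hERG",
                             n_platforms = 4,
                             sites_per_platform = 4,
                             truth = apc_truth(),
                             sigma_between = 0.3,
                             sigma_within = 0.15,
                             well_noise_sd = 5,
                             wells_per_conc = 5,
                             qc_fail_rate = 0.1,
                             conc_design = c("nominal", "centered"),
                             baseline_na = 1,
                             endblocker_na = 0.1,
                             rm_median_mohm = 500,
                             rm_sdlog = 0.3,
                             qc = apc_config(),
                             seed = 1L) {
  conc_design <- match.arg(conc_design)
  if (is.null(sites)) {
    plats <- sprintf("p%d", seq_len(n_platforms))
    sites <- tibble::tibble(
      site_id = sprintf("s%02d", seq_len(n_platforms * sites_per_platform)),
      platform_id = rep(plats, each = sites_per_platform),
      temperature_class = "room",
      currents = rep(list(currents), n_platforms * sites_per_platform)
    )
  }
  stopifnot(
    all(currents %in% apc_currents()),
    sigma_between >= 0, sigma_within >= 0, well_noise_sd >= 0,
    wells_per_conc >= 1, qc_fail_rate >= 0, qc_fail_rate < 1,
    baseline_na > 0, endblocker_na >= 0
  )
  structure(
    list(
      drugs = drugs, sites = sites, currents = currents, truth = truth,
      sigma_between = sigma_between, sigma_within = sigma_within,
      well_noise_sd = well_noise_sd, wells_per_conc = wells_per_conc,
      qc_fail_rate = qc_fail_rate, conc_design = conc_design,
      baseline_na = baseline_na, endblocker_na = endblocker_na,
      rm_median_mohm = rm_median_mohm, rm_sdlog = rm_sdlog,
      qc = qc, seed = as.integer(seed)
    ),
    class = "apc_sim_params"
  )
}

#' Preset emulating the full multi-site study design
#'
#' Twelve drugs, the 17-site / 5-platform roster with its per-current
#' participation (16 sites hERG, 15 peak Nav1.5, 8 Cav1.2, 4 late
#' Nav1.5), nominal half-log concentration series, five wells per
#' concentration and a 10% QC corruption rate.
#'
#' @param seed Integer master seed.
#' @param ... Overrides passed to [synthetic_params()].
#' @return An `apc_sim_params` object.
#' @export
study_preset <- function(seed = 1L, ...) {
  synthetic_params(sites = apc_sites(), currents = apc_currents(),
                   conc_design = "nominal", seed = seed, ...)
}

#' Minimal single-current preset
#'
#' Twelve drugs against hERG only, on a compact generic roster (default
#' two platforms of three sites), with concentrations centred on each
#' drug's true IC50; intended for fast end-to-end checks.
#'
#' @param seed Integer master seed.
#' @param n_platforms,sites_per_platform Roster shape.
#' @param ... Overrides passed to [synthetic_params()].
#' @return An `apc_sim_params` object.
#' @export
minimal_preset <- function(seed = 1L, n_platforms = 2,
                           sites_per_platform = 3, ...) {
  synthetic_params(currents = "hERG", n_platforms = n_platforms,
                   sites_per_platform = sites_per_platform,
                   conc_design = "centered", seed = seed, ...)
}

# Concentration series for one drug under the chosen design.
sim_concs <- function(params, drug_id, true_log10_ic50) {
  if (params$conc_design == "nominal") {
    params$drugs$concentrations[[match(drug_id, params$drugs$drug_id)]]
  } else {
    10^(true_log10_ic50 + c(-0.75, -0.25, 0.25, 0.75))
  }
}

# Corrupt selected wells so each violates exactly one QC criterion while
# the current triple stays internally consistent with the well's
# inhibition. mode: 1 low_Rm, 2 high_leak (leak = 50% of peak),
# 3 low_baseline (baseline halved below threshold, leak kept <= 25%).
corrupt_wells <- function(g, inh, corrupt, mode, qc) {
  m <- ifelse(corrupt, mode, 0L)
  b0 <- g$pre_drug_current - g$endblocker_current
  g$membrane_resistance[m == 1] <- qc$min_rm_mohm * 0.5
  i2 <- m == 2
  g$endblocker_current[i2] <- b0[i2]
  g$pre_drug_current[i2] <- 2 * b0[i2]
  g$steady_state_current[i2] <- b0[i2] + b0[i2] * (1 - inh[i2] / 100)
  i3 <- m == 3
  b3 <- qc$min_baseline_na * 0.5
  g$endblocker_current[i3] <- b3 / 4
  g$pre_drug_current[i3] <- b3 / 4 + b3
  g$steady_state_current[i3] <- b3 / 4 + b3 * (1 - inh[i3] / 100)
  g
}

#' Generate a synthetic multi-site APC study
#'
#' Draws the hierarchical model of [synthetic_params()]: platform effects
#' shared by all sites on a platform (per drug x current), independent
#' site effects, well-level inhibition noise, and converts every well's
#' inhibition back into a consistent (pre-drug, steady-state,
#' end-blocker) current triple with a lognormal membrane resistance.
#' A `qc_fail_rate` fraction of wells is corrupted to violate exactly
#' one QC criterion (low Rm, high leak, or low baseline). Fully
#' reproducible from the master seed; random streams are split per
#' platform and per site x drug x current.
#'
#' @param params An [synthetic_params()] object.
#' @param wells If `FALSE`, skip well synthesis and return only the
#'   site-level ground truth (identical to the truth produced with
#'   `wells = TRUE` under the same seed); useful for Monte Carlo studies
#'   of the site-level statistics.
#' @return A list of class `apc_sim_study`:
#' \describe{
#'   \item{wells}{well-level records in the [read_wells()] schema.}
#'   \item{truth_sites}{per site x drug x current: the true, platform,
#'     site and effective log10 IC50 plus `true_hill`, `max_block_pct`.}
#'   \item{truth_wells}{per well: the generator's noisy percent
#'     inhibition and the QC corruption flag/mode.}
#'   \item{params}{the generating parameters.}
#' }
#' @export
generate_study <- function(params = synthetic_params(), wells = TRUE) {
  stopifnot(inherits(params, "apc_sim_params"))
  wells_acc <- list()
  tw_acc <- list()
  ts_acc <- list()
  for (ct in params$currents) {
    does_ct <- vapply(params$sites$currents, function(x) ct %in% x,
                      logical(1))
    sites <- params$sites[does_ct, , drop = FALSE]
    if (nrow(sites) == 0) next
    for (d in params$drugs$drug_id) {
      tr <- params$truth[params$truth$drug_id == d &
                           params$truth$current_type == ct, , drop = FALSE]
      if (nrow(tr) == 0) next
      concs <- sim_concs(params, d, tr$true_log10_ic50)
      # one platform-effect draw per platform, shared across its sites
      b_p <- vapply(unique(sites$platform_id), function(p) {
        set.seed(hash_seed("platform", params$seed, ct, d, p))
        stats::rnorm(1, 0, params$sigma_between)
      }, numeric(1))
      e_vec <- vapply(sites$site_id, function(s) {
        set.seed(hash_seed("site", params$seed, ct, d, s))
        stats::rnorm(1, 0, params$sigma_within)
      }, numeric(1))
      eff_vec <- tr$true_log10_ic50 + unname(b_p[sites$platform_id]) +
        unname(e_vec)
      ts_acc[[length(ts_acc) + 1L]] <- tibble::tibble(
        site_id = sites$site_id, platform_id = sites$platform_id,
        current_type = ct, drug_id = d,
        true_log10_ic50 = tr$true_log10_ic50,
        platform_effect = unname(b_p[sites$platform_id]),
        site_effect = unname(e_vec),
        effective_log10_ic50 = eff_vec,
        true_hill = tr$true_hill, max_block_pct = tr$max_block_pct
      )
      if (!wells) next
      for (i in seq_len(nrow(sites))) {
        s <- sites$site_id[i]
        p <- sites$platform_id[i]
        eff <- eff_vec[i]
        # re-enter this site's stream after its site-effect draw
        set.seed(hash_seed("site", params$seed, ct, d, s))
        invisible(stats::rnorm(1))
        nw <- length(concs) * params$wells_per_conc
        conc_vec <- rep(concs, each = params$wells_per_conc)
        inh <- tr$max_block_pct *
          hill_predict(log10(conc_vec), eff, tr$true_hill) / 100 +
          stats::rnorm(nw, 0, params$well_noise_sd)
        rm_ <- pmax(params$rm_median_mohm *
                      exp(stats::rnorm(nw, 0, params$rm_sdlog)),
                    1.25 * params$qc$min_rm_mohm)
        corrupt <- stats::runif(nw) < params$qc_fail_rate
        mode <- sample.int(3L, nw, replace = TRUE)
        g <- tibble::tibble(
          site_id = s, platform_id = p, current_type = ct, drug_id = d,
          plate_id = paste(s, d, ct, sep = "-"),
          well_id = sprintf("w%03d", seq_len(nw)),
          concentration = conc_vec,
          pre_drug_current = params$endblocker_na + params$baseline_na,
          steady_state_current = params$endblocker_na +
            params$baseline_na * (1 - inh / 100),
          endblocker_current = params$endblocker_na,
          membrane_resistance = rm_,
          temperature_class = sites$temperature_class[i]
        )
        g <- corrupt_wells(g, inh, corrupt, mode, params$qc)
        tw_acc[[length(tw_acc) + 1L]] <- tibble::tibble(
          site_id = s, platform_id = p, current_type = ct, drug_id = d,
          well_id = g$well_id, concentration = conc_vec,
          pct_inhibition = inh, qc_corrupted = corrupt,
          corrupt_mode = ifelse(corrupt,
                                c("low_Rm", "high_leak",
                                  "low_baseline")[mode], NA_character_)
        )
        wells_acc[[length(wells_acc) + 1L]] <- g
      }
    }
  }
  structure(
    list(
      wells = dplyr::bind_rows(wells_acc),
      truth_sites = dplyr::bind_rows(ts_acc),
      truth_wells = dplyr::bind_rows(tw_acc),
      params = params
    ),
    class = "apc_sim_study"
  )
}

#' Generate wells for a deliberately non-blocking drug
#'
#' Overrides one drug's maximal block to sit below the no-fit threshold
#' (default 10%) and simulates only that drug, so every downstream fit
#' must return `fit_status = "no_fit"`.
#'
#' @param params An [synthetic_params()] object.
#' @param drug_id Drug to simulate.
#' @param max_block_pct Maximal block (%), at or below the no-fit
#'   threshold.
#' @return An `apc_sim_study` list, as [generate_study()].
#' @export
generate_nonblocker <- function(params = synthetic_params(), drug_id,
                                max_block_pct = 10) {
  stopifnot(drug_id %in% params$drugs$drug_id)
  params$drugs <- params$drugs[params$drugs$drug_id == drug_id, ,
                               drop = FALSE]
  sel <- params$truth$drug_id == drug_id
  params$truth <- params$truth[sel, , drop = FALSE]
  params$truth$max_block_pct <- max_block_pct
  generate_study(params)
}

#' @export
print.apc_sim_study <- function(x, ...) {
  cat("<apc_sim_study>\n")
  cat("  wells:", nrow(x$wells), " site-drug-current groups:",
      nrow(x$truth_sites), "\n")
  cat("  currents:", paste(unique(x$wells$current_type), collapse = ", "),
      "\n")
  invisible(x)
}
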