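#' Default drug panel
#'
#' The 12-drug CiPA panel used throughout: compound name, torsadogenic risk
#' category, and the four nominal test concentrations (half-log spaced,
#' stored internally in molar). Concentrations were chosen so that the
#' lowest elicits little or no block and the highest approaches full block
#' of the most sensitive current.
#'
#' @return A tibble with columns `drug_id`, `name`, `risk_category`
#'   (`"high"`, `"intermediate"` or `"low"`) and `concentrations`
#'   (list-column of ascending molar concentrations).
#' @export
apc_drugs <- function() {
  uM <- function(...) c(...) * 1e-6
  tibble::tibble(
    drug_id = c("bep", "cpz", "cis", "dil", "dof", "mex",
                "ond", "qui", "ran", "sot", "ter", "ver"),
    name = c("bepridil", "chlorpromazine", "cisapride", "diltiazem",
             "dofetilide", "mexiletine", "ondansetron", "quinidine",
             "ranolazine", "sotalol", "terfenadine", "verapamil"),
    risk_category = c("high", "intermediate", "intermediate", "low",
                      "high", "low", "intermediate", "high",
                      "low", "high", "intermediate", "low"),
    concentrations = list(
      uM(0.01, 0.03, 0.1, 0.3),    # bepridil
      uM(0.1, 0.3, 1, 3),          # chlorpromazine
      uM(0.001, 0.01, 0.1, 0.3),   # cisapride
      uM(3, 10, 30, 100),          # diltiazem
      uM(0.001, 0.003, 0.01, 0.1), # dofetilide
      uM(1, 10, 30, 100),          # mexiletine
      uM(0.3, 1, 3, 10),           # ondansetron
      uM(0.1, 0.3, 1, 10),         # quinidine
      uM(3, 10, 30, 100),          # ranolazine
      uM(10, 30, 100, 300),        # sotalol
      uM(0.01, 0.03, 0.1, 0.3),    # terfenadine
      uM(0.03, 0.1, 0.3, 1)        # verapamil
    )
  )
}

#' Default site and platform roster
#'
#' The 17-site, 5-platform roster of the multi-site study design: each site
#' runs exactly one APC platform, records at room or near-physiologic
#' temperature, and contributes a subset of the four cardiac currents.
#' Platform dataset counts are p1: 6, p2: 4, p3: 4, p4: 2, p5: 1; per
#' current, 16 sites contribute hERG, 15 peak Nav1.5, 8 Cav1.2 and
#' 4 late Nav1.5.
#'
#' @return A tibble with columns `site_id`, `platform_id`,
#'   `temperature_class` (`"room"` or `"physiologic"`) and `currents`
#'   (list-column of current types measured at that site).
#' @export
apc_sites <- function() {
  h <- "hERG"; pn <- "peak_Nav1.5"; ln <- "late_Nav1.5"; cv <- "Cav1.2"
  tibble::tibble(
    site_id = c("s01", "s02", "s03", "s04", "s05", "s06", "s07", "s10",
                "s11", "s12", "s13", "s14", "s15", "s16", "s17", "s18", "s19"),
    platform_id = c("p1", "p2", "p2", "p3", "p4", "p4", "p5", "p3",
                    "p1", "p2", "p2", "p1", "p1", "p3", "p1", "p1", "p3"),
    temperature_class = c("room", "room", "room", "room", "room", "room",
                          "room", "room", "physiologic", "room",
                          "physiologic", "room", "room", "room", "room",
                          "physiologic", "room"),
    currents = list(
      c(h, pn, cv),     # s01
      c(h, pn, cv),     # s02
      h,                # s03
      c(h, pn, cv),     # s04
      c(h, pn, ln, cv), # s05
      h,                # s06
      c(h, pn, ln),     # s07
      c(h, pn),         # s10
      c(h, pn, cv),     # s11
      c(h, pn),         # s12
      c(h, pn, ln),     # s13
      c(h, pn, ln, cv), # s14
      c(h, pn),         # s15
      c(h, pn, cv),     # s16
      pn,               # s17
      c(h, pn, cv),     # s18
      c(h, pn)          # s19
    )
  )
}

#' Valid current types
#' @return Character vector of the four cardiac current labels.
#' @export
apc_currents <- function() c("hERG", "peak_Nav1.5", "late_Nav1.5", "Cav1.2")

#' Study configuration
#'
#' Bundles the drug panel, site roster, well-level QC thresholds and the
#' analysis settings used by every downstream stage. The defaults are the
#' study's fixed values: membrane resistance >= 200 MOhm, leak current
#' <= 25% of peak, baseline current >= 0.2 nA, a minimum of four
#' concentrations with three wells each, a no-fit rule at <= 20% maximal
#' effect, limits of agreement at mean difference +/- 2 SD with the
#' (-0.48, 0.48) log10 (3-fold) acceptance bound, and variance components
#' requiring at least three platforms with replicate measurements.
#'
#' @param drugs Drug panel tibble, see [apc_drugs()].
#' @param sites Site roster tibble, see [apc_sites()].
#' @param min_rm_mohm Minimum membrane resistance (MOhm), inclusive.
#' @param max_leak_fraction Maximum |end-blocker| / |pre-drug| current
#'   ratio, inclusive.
#' @param min_baseline_na Minimum leak-subtracted pre-drug current
#'   amplitude (nA), inclusive.
#' @param min_wells Minimum wells per concentration for a usable point.
#' @param min_concs Minimum usable concentrations for curve fitting.
#' @param nofit_max_effect_pct No-fit rule: maximal mean inhibition (%)
#'   at or below which no curve is fitted.
#' @param loa_multiplier SD multiplier for the limits of agreement.
#' @param loa_log_bound Acceptance bound for the limits of agreement on
#'   the log10 scale (0.48 corresponds to 3-fold).
#' @param min_platforms_with_replicates Platforms with >= 2 measurements
#'   required for a feasible variance-component estimate.
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `apc_config` (a named list).
#' @export
apc_config <- function(drugs = apc_drugs(),
                       sites = apc_sites(),
                       min_rm_mohm = 200,
                       max_leak_fraction = 0.25,
                       min_baseline_na = 0.2,
                       min_wells = 3,
                       min_concs = 4,
                       nofit_max_effect_pct = 20,
                       loa_multiplier = 2,
                       loa_log_bound = 0.48,
                       min_platforms_with_replicates = 3,
                       seed = 1L) {
  stopifnot(
    is.data.frame(drugs), all(c("drug_id", "concentrations") %in% names(drugs)),
    is.data.frame(sites), all(c("site_id", "platform_id") %in% names(sites)),
    min_rm_mohm > 0, max_leak_fraction > 0, min_baseline_na > 0,
    min_wells >= 1, min_concs >= 2,
    nofit_max_effect_pct > 0, loa_multiplier > 0, loa_log_bound > 0,
    min_platforms_with_replicates >= 2
  )
  if (anyDuplicated(drugs$drug_id)) stop("duplicated drug_id in drug panel")
  if (anyDuplicated(sites$site_id)) stop("duplicated site_id in site roster")
  for (i in seq_len(nrow(drugs))) {
    cc <- drugs$concentrations[[i]]
    if (length(cc) < 2 || any(cc <= 0) || any(diff(cc) <= 0)) {
      stop("concentrations for drug '", drugs$drug_id[i],
           "' must be positive and strictly increasing")
    }
  }
  structure(
    list(
      drugs = drugs, sites = sites,
      min_rm_mohm = min_rm_mohm,
      max_leak_fraction = max_leak_fraction,
      min_baseline_na = min_baseline_na,
      min_wells = min_wells, min_concs = min_concs,
      nofit_max_effect_pct = nofit_max_effect_pct,
      loa_multiplier = loa_multiplier,
      loa_log_bound = loa_log_bound,
      min_platforms_with_replicates = min_platforms_with_replicates,
      seed = as.integer(seed)
    ),
    class = "apc_config"
  )
}

#' @export
print.apc_config <- function(x, ...) {
  cat("<apc_config>\n")
  cat("  drugs:", nrow(x$drugs), " sites:", nrow(x$sites),
      " platforms:", length(unique(x$sites$platform_id)), "\n")
  cat("  QC: Rm >=", x$min_rm_mohm, "MOhm; leak <=",
      x$max_leak_fraction * 100, "%; baseline >=", x$min_baseline_na, "nA\n")
  cat("  fit: >=", x$min_concs, "concs x >=", x$min_wells,
      "wells; no-fit <=", x$nofit_max_effect_pct, "%\n")
  cat("  LoA: mean +/-", x$loa_multiplier, "SD, bound +/-",
      x$loa_log_bound, "log10\n")
  invisible(x)
}

#' Convert a log10 difference to a fold change
#'
#' Differences of log10 IC50 values correspond to ratios on the molar
#' scale; this maps a span or limit in log10 units to its fold equivalent
#' (e.g. 0.48 log10 units is 3.0-fold).
#'
#' @param log10_units Numeric vector of log10 differences.
#' @return `10^log10_units`.
#' @export
fold_change <- function(log10_units) 10^log10_units

# Look up the platform for each site id under a config.
site_platform <- function(config, site_id) {
  idx <- match(site_id, config$sites$site_id)
  config$sites$platform_id[idx]
}
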