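#' Well-level quality control
#'
#' Applies the three whole-cell validity criteria to each well:
#' membrane resistance at least `min_rm_mohm`, leak current (estimated by
#' the residual current after the saturating end-blocker) no more than
#' `max_leak_fraction` of the pre-drug peak, and a leak-subtracted
#' pre-drug baseline of at least `min_baseline_na`. All thresholds are
#' inclusive. A zero pre-drug current fails with reason `low_baseline`.
#'
#' @param wells Tibble of well records (see [read_wells()] for the schema;
#'   molar / nA / MOhm units).
#' @param config An [apc_config()].
#' @return The input keyed columns plus logical `low_rm`, `high_leak`,
#'   `low_baseline`, `passed`, and a `reasons` string (comma-separated,
#'   empty when passed).
#' @export
passes_qc <- function(wells, config = apc_config()) {
  stopifnot(is.data.frame(wells))
  rm_ok <- wells$membrane_resistance >= config$min_rm_mohm
  leak_ok <- abs(wells$endblocker_current) <=
    config$max_leak_fraction * abs(wells$pre_drug_current)
  baseline <- abs(wells$pre_drug_current - wells$endblocker_current)
  base_ok <- baseline >= config$min_baseline_na & wells$pre_drug_current != 0
  res <- dplyr::mutate(
    wells,
    low_rm = !rm_ok,
    high_leak = !leak_ok,
    low_baseline = !base_ok,
    passed = rm_ok & leak_ok & base_ok
  )
  res$reasons <- apply(
    cbind(
      ifelse(res$low_rm, "low_Rm", NA),
      ifelse(res$high_leak, "high_leak", NA),
      ifelse(res$low_baseline, "low_baseline", NA)
    ),
    1L,
    function(r) paste(r[!is.na(r)], collapse = ",")
  )
  res
}

#' Leak-corrected percent inhibition
#'
#' Current inhibition as a percentage of the pre-drug control after
#' subtracting the end-blocker (leak) current from both the pre-drug and
#' the steady-state drug current:
#' `100 * (1 - (post - endblocker) / (pre - endblocker))`.
#' Values are deliberately not clipped to \[0, 100\]; noisy wells may
#' return slightly negative or above-100 values and these propagate to
#' the concentration-response fit unchanged.
#'
#' @param pre_drug Pre-drug current (nA).
#' @param post_drug Steady-state current in drug (nA).
#' @param endblocker Residual current after the saturating end-blocker (nA).
#' @return Percent inhibition (vectorised).
#' @export
percent_inhibition <- function(pre_drug, post_drug, endblocker = 0) {
  denom <- pre_drug - endblocker
  if (any(denom == 0)) {
    stop("pre-drug current equals end-blocker current: inhibition undefined")
  }
  100 * (1 - (post_drug - endblocker) / denom)
}

#' Aggregate per-well inhibition into concentration-response points
#'
#' Computes the leak-corrected percent inhibition for every well, then the
#' mean, SD and well count per site x drug x current x concentration
#' group. Groups with fewer than `min_wells` wells are flagged
#' `insufficient` (the study design required at least three wells per
#' concentration); they are retained but excluded from curve fitting.
#'
#' @param wells Tibble of well records, normally pre-filtered with
#'   [passes_qc()].
#' @param config An [apc_config()].
#' @return A tibble with one row per group: keys, `concentration` (molar),
#'   `pct_inhibition` (mean, %), `sd` (% , `NA` when n = 1), `n_wells`,
#'   `insufficient`.
#' @export
aggregate_inhibition <- function(wells, config = apc_config()) {
  stopifnot(is.data.frame(wells))
  if (nrow(wells) == 0) {
    return(tibble::tibble(
      site_id = character(), platform_id = character(),
      drug_id = character(), current_type = character(),
      concentration = numeric(), pct_inhibition = numeric(),
      sd = numeric(), n_wells = integer(), insufficient = logical()
    ))
  }
  wells |>
    dplyr::mutate(.inh = percent_inhibition(
      .data$pre_drug_current, .data$steady_state_current,
      .data$endblocker_current
    )) |>
    dplyr::summarise(
      pct_inhibition = mean(.data$.inh),
      sd = if (dplyr::n() >= 2) stats::sd(.data$.inh) else NA_real_,
      n_wells = dplyr::n(),
      .by = c("site_id", "platform_id", "drug_id", "current_type",
              "concentration")
    ) |>
    dplyr::mutate(insufficient = .data$n_wells < config$min_wells) |>
    dplyr::arrange(.data$site_id, .data$drug_id, .data$current_type,
                   .data$concentration)
}

#' Vehicle correction of inhibition points
#'
#' Subtracts the mean vehicle-period response from every inhibition value,
#' removing addition artefacts measured before drug exposure. Off by
#' default in the pipeline; note the operation is a plain shift and is
#' therefore not idempotent — applying it twice subtracts twice.
#'
#' @param points Tibble with a `pct_inhibition` column
#'   (see [aggregate_inhibition()]).
#' @param vehicle_mean Mean vehicle response (%), finite scalar.
#' @return `points` with `pct_inhibition` shifted by `-vehicle_mean`.
#' @export
vehicle_correction <- function(points, vehicle_mean) {
  stopifnot(is.numeric(vehicle_mean), length(vehicle_mean) == 1,
            is.finite(vehicle_mean))
  dplyr::mutate(points, pct_inhibition = .data$pct_inhibition - vehicle_mean)
}
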