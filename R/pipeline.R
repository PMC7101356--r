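#' Run the full variability analysis on well-level recordings
#'
#' Orchestrates the standard analysis: well-level QC ([passes_qc()]),
#' leak-corrected percent inhibition aggregated per concentration
#' ([aggregate_inhibition()]), constrained Hill fitting per site x drug
#' x current ([fit_hill_all()]), then the study-level statistics —
#' log-scale IC50 spread summaries, between/within-platform variance
#' components, per-platform repeatability coefficients, site-level
#' inhibition at the lowest tested concentrations, platform mean tables
#' and the pairwise Bland-Altman agreement matrix. All downstream tables
#' use only records with `fit_status == "ok"`. The pipeline is
#' deterministic given its inputs and invariant to input row order.
#'
#' @param wells Tibble of well records (see [read_wells()] /
#'   [generate_study()]).
#' @param config An [apc_config()].
#' @return A list of class `apc_study`: `qc`, `points`, `records`,
#'   `summaries`, `variance`, `repeatability`, `noel`, `platform_means`,
#'   `agreement`, `config`. If no well survives QC, a warning is issued
#'   and the tables are empty.
#' @export
run_pipeline <- function(wells, config = apc_config()) {
  stopifnot(is.data.frame(wells), nrow(wells) > 0)
  wells <- dplyr::arrange(
    wells, .data$current_type, .data$drug_id, .data$site_id,
    .data$concentration, .data$well_id
  )
  qc <- passes_qc(wells, config)
  passing <- qc[qc$passed, , drop = FALSE]
  if (nrow(passing) == 0) {
    warning("no wells survived QC; returning empty study tables")
  }
  points <- aggregate_inhibition(passing, config)
  records <- fit_hill_all(points, config)
  structure(
    list(
      qc = qc[, c("site_id", "platform_id", "current_type", "drug_id",
                  "plate_id", "well_id", "passed", "low_rm", "high_leak",
                  "low_baseline", "reasons")],
      points = points,
      records = records,
      summaries = summarize_ic50(records, config),
      variance = variance_components(records, config),
      repeatability = repeatability(records, config),
      noel = noel_loel_summary(points, config),
      platform_means = platform_mean_table(records),
      agreement = agreement_matrix(records, config),
      config = config
    ),
    class = "apc_study"
  )
}

#' @export
print.apc_study <- function(x, ...) {
  cat("<apc_study>\n")
  cat("  wells:", nrow(x$qc), " (", sum(x$qc$passed), "passed QC )\n")
  n_ok <- sum(x$records$fit_status == "ok")
  cat("  fits:", nrow(x$records), " (", n_ok, "ok,",
      sum(x$records$fit_status == "no_fit"), "no_fit,",
      sum(x$records$fit_status == "insufficient_data"),
      "insufficient )\n")
  cat("  drug x current summaries:", nrow(x$summaries),
      " agreement pairs:", nrow(x$agreement), "\n")
  invisible(x)
}

#' Write all study tables as CSV files
#'
#' Emits the tidy result tables of [run_pipeline()] into a directory:
#' `qc_report.csv`, `inhibition_points.csv`, `ic50_long.csv`,
#' `summaries.csv`, `variance_components.csv`, `repeatability.csv`,
#' `noel_summary.csv`, `platform_means.csv`, `agreement.csv`.
#'
#' @param study An `apc_study` (see [run_pipeline()]).
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "apc_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$qc, file.path(dir, "qc_report.csv"))
  readr::write_csv(study$points, file.path(dir, "inhibition_points.csv"))
  write_ic50_table(study$records, file.path(dir, "ic50_long.csv"))
  readr::write_csv(study$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(study$variance,
                   file.path(dir, "variance_components.csv"))
  readr::write_csv(study$repeatability, file.path(dir, "repeatability.csv"))
  readr::write_csv(study$noel, file.path(dir, "noel_summary.csv"))
  readr::write_csv(study$platform_means,
                   file.path(dir, "platform_means.csv"))
  readr::write_csv(study$agreement, file.path(dir, "agreement.csv"))
  invisible(dir)
}
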