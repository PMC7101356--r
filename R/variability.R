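#' Log-scale IC50 spread summaries
#'
#' Per drug x current box-plot style summary of the fitted log10 IC50
#' values across sites: median, 25/75 percentiles (linear interpolation
#' between order statistics), min/max, the interquartile span in log10
#' units and its fold equivalent `10^(p75 - p25)`. Only records with
#' `fit_status == "ok"` contribute; censored (no-fit / insufficient)
#' records are counted separately. Groups with no usable record are
#' omitted rather than returned as NA rows.
#'
#' @param records Long IC50 table (see [fit_hill_all()] or
#'   [read_ic50_table()]).
#' @param config An [apc_config()].
#' @return Tibble with one row per drug x current: `n`, `n_censored`,
#'   `median`, `p25`, `p75`, `min`, `max` (log10 molar), `span_log`,
#'   `fold_range`.
#' @export
summarize_ic50 <- function(records, config = apc_config()) {
  stopifnot(is.data.frame(records))
  cens <- records |>
    dplyr::summarise(
      n_censored = sum(.data$fit_status != "ok"),
      .by = c("drug_id", "current_type")
    )
  ok <- records[records$fit_status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) {
    return(tibble::tibble(
      drug_id = character(), current_type = character(), n = integer(),
      n_censored = integer(), median = numeric(), p25 = numeric(),
      p75 = numeric(), min = numeric(), max = numeric(),
      span_log = numeric(), fold_range = numeric()
    ))
  }
  ok |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$log10_ic50),
      p25 = unname(stats::quantile(.data$log10_ic50, 0.25, type = 7)),
      p75 = unname(stats::quantile(.data$log10_ic50, 0.75, type = 7)),
      min = min(.data$log10_ic50),
      max = max(.data$log10_ic50),
      .by = c("drug_id", "current_type")
    ) |>
    dplyr::mutate(
      span_log = .data$p75 - .data$p25,
      fold_range = fold_change(.data$span_log)
    ) |>
    dplyr::left_join(cens, by = c("drug_id", "current_type")) |>
    dplyr::mutate(n_censored = dplyr::coalesce(.data$n_censored, 0L)) |>
    dplyr::relocate("n_censored", .after = "n") |>
    dplyr::arrange(.data$current_type, .data$drug_id)
}

# One-way random-effects method-of-moments decomposition for a single
# drug x current. x: log10 IC50 values; g: platform labels.
vc_moments <- function(x, g, min_platforms_with_replicates = 3) {
  g <- as.character(g)
  ni <- tapply(x, g, length)
  k <- length(ni)
  N <- length(x)
  feasible <- sum(ni >= 2) >= min_platforms_with_replicates && N > k && k >= 2
  out <- list(
    k_platforms = k, n_total = N, feasible = feasible,
    sigma2_between = NA_real_, sigma2_within = NA_real_,
    pct_between = NA_real_, pct_within = NA_real_, truncated = NA
  )
  if (!feasible) return(out)
  mi <- tapply(x, g, mean)
  grand <- mean(x)
  ssw <- sum((x - mi[g])^2)
  msw <- ssw / (N - k)
  msb <- sum(ni * (mi - grand)^2) / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b_raw <- (msb - msw) / n0
  out$sigma2_within <- msw
  out$sigma2_between <- max(0, s2b_raw)
  out$truncated <- s2b_raw < 0
  tot <- out$sigma2_between + out$sigma2_within
  if (tot > 0) {
    out$pct_between <- 100 * out$sigma2_between / tot
    out$pct_within <- 100 * out$sigma2_within / tot
  } else {
    out$pct_between <- 0
    out$pct_within <- 100
  }
  out
}

#' Between- vs within-platform variance components
#'
#' One-way random-effects analysis of variance on the log10 IC50 values,
#' conducted separately for each drug x current with platform as the
#' grouping factor. The residual mean square estimates the
#' within-platform variance; the between-platform component is the
#' method-of-moments estimate `max(0, (MS_between - MS_within) / n0)`
#' with the unbalanced-design coefficient
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`. Negative raw estimates are
#' truncated to zero and flagged. A group is feasible only when at least
#' `min_platforms_with_replicates` platforms contribute two or more
#' measurements.
#'
#' @param records Long IC50 table; only `fit_status == "ok"` rows are used.
#' @param config An [apc_config()].
#' @return Tibble per drug x current: `k_platforms`, `n_total`,
#'   `feasible`, `sigma2_between`, `sigma2_within` (log10^2 units),
#'   `pct_between`, `pct_within`, `truncated`.
#' @export
variance_components <- function(records, config = apc_config()) {
  stopifnot(is.data.frame(records))
  ok <- records[records$fit_status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) {
    return(tibble::tibble(
      drug_id = character(), current_type = character(),
      k_platforms = integer(), n_total = integer(), feasible = logical(),
      sigma2_between = numeric(), sigma2_within = numeric(),
      pct_between = numeric(), pct_within = numeric(), truncated = logical()
    ))
  }
  ok |>
    tidyr::nest(.by = c("drug_id", "current_type")) |>
    dplyr::mutate(vc = purrr::map(.data$data, function(d) {
      tibble::as_tibble(vc_moments(
        d$log10_ic50, d$platform_id,
        config$min_platforms_with_replicates
      ))
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("vc") |>
    dplyr::arrange(.data$current_type, .data$drug_id)
}

#' Repeatability coefficient from a residual SD
#'
#' The repeatability coefficient is `1.96 * sqrt(2)` times the residual
#' (within-platform) standard deviation on the log10 scale: the typical
#' (95% coverage) absolute difference between two measurements made on
#' the same platform. `rc_fold = 10^rc_log` expresses it as a fold
#' difference on the concentration scale; 1 means perfect repeatability.
#'
#' @param sigma_resid Residual SD in log10 units, >= 0.
#' @return Tibble with `sigma_resid`, `rc_log`, `rc_fold` (vectorised).
#' @export
repeatability_coefficient <- function(sigma_resid) {
  if (any(sigma_resid < 0)) stop("sigma_resid must be non-negative")
  rc_log <- 1.96 * sqrt(2) * sigma_resid
  tibble::tibble(sigma_resid = sigma_resid, rc_log = rc_log,
                 rc_fold = fold_change(rc_log))
}

#' Per-platform repeatability coefficients
#'
#' Pools, within each platform x current, the drug-mean-centred log10
#' IC50 values across all drugs with at least two measurements on that
#' platform; the pooled SD (`sqrt(sum SS_d / sum df_d)`) is the
#' platform's residual SD, converted to a repeatability coefficient via
#' [repeatability_coefficient()]. Platforms with no replicated drug are
#' omitted.
#'
#' @param records Long IC50 table; only `fit_status == "ok"` rows are used.
#' @param config An [apc_config()].
#' @return Tibble per platform x current: `n_drugs` (drugs contributing
#'   replicates), `df` (pooled degrees of freedom), `sigma_resid`,
#'   `rc_log`, `rc_fold`.
#' @export
repeatability <- function(records, config = apc_config()) {
  stopifnot(is.data.frame(records))
  ok <- records[records$fit_status == "ok", , drop = FALSE]
  empty <- tibble::tibble(
    platform_id = character(), current_type = character(),
    n_drugs = integer(), df = integer(), sigma_resid = numeric(),
    rc_log = numeric(), rc_fold = numeric()
  )
  if (nrow(ok) == 0) return(empty)
  pooled <- ok |>
    dplyr::summarise(
      n = dplyr::n(),
      ss = sum((.data$log10_ic50 - mean(.data$log10_ic50))^2),
      .by = c("platform_id", "current_type", "drug_id")
    ) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::summarise(
      n_drugs = dplyr::n(),
      df = sum(.data$n - 1L),
      sigma_resid = sqrt(sum(.data$ss) / sum(.data$n - 1L)),
      .by = c("platform_id", "current_type")
    )
  if (nrow(pooled) == 0) return(empty)
  dplyr::bind_cols(
    pooled[c("platform_id", "current_type", "n_drugs", "df")],
    repeatability_coefficient(pooled$sigma_resid)
  ) |>
    dplyr::arrange(.data$current_type, .data$platform_id)
}

#' Site-level inhibition at the lowest tested concentration
#'
#' The lowest test concentration of every drug is chosen to sit at or
#' below the no/lowest-observed-effect level, so inhibition there should
#' cluster near zero; systematic departures reveal site-level bias or
#' noise. For each site (and current), the per-drug mean inhibition at
#' that drug's lowest tested concentration is averaged across drugs.
#'
#' @param points Inhibition points (see [aggregate_inhibition()]).
#' @param config An [apc_config()].
#' @return Tibble per site x current: `mean_pct`, `sd_pct` (SD across
#'   drugs, `NA` with a single drug), `n_drugs`.
#' @export
noel_loel_summary <- function(points, config = apc_config()) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0) {
    return(tibble::tibble(
      site_id = character(), platform_id = character(),
      current_type = character(), mean_pct = numeric(),
      sd_pct = numeric(), n_drugs = integer()
    ))
  }
  points |>
    dplyr::filter(
      .data$concentration == min(.data$concentration),
      .by = c("drug_id", "current_type")
    ) |>
    dplyr::summarise(
      pct = mean(.data$pct_inhibition),
      .by = c("site_id", "platform_id", "current_type", "drug_id")
    ) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct),
      sd_pct = if (dplyr::n() >= 2) stats::sd(.data$pct) else NA_real_,
      n_drugs = dplyr::n(),
      .by = c("site_id", "platform_id", "current_type")
    ) |>
    dplyr::arrange(.data$current_type, .data$site_id)
}
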