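#' Hill (four-parameter logistic) prediction with fixed asymptotes
#'
#' Predicted percent inhibition under the sigmoidal concentration-response
#' model with the bottom fixed at 0%, the top at 100%:
#' `100 / (1 + 10^((log10_ic50 - log_conc) * hill_slope))`.
#' The curve is strictly increasing in `log_conc`, equals 50% at the IC50
#' and approaches 0 / 100% at the asymptotes.
#'
#' @param log_conc log10 molar concentration (vectorised).
#' @param log10_ic50 log10 molar IC50.
#' @param hill_slope Hill slope, > 0.
#' @return Percent inhibition in (0, 100).
#' @export
hill_predict <- function(log_conc, log10_ic50, hill_slope = 1) {
  stopifnot(all(hill_slope > 0))
  100 / (1 + 10^((log10_ic50 - log_conc) * hill_slope))
}

# Bounds used for the constrained fit: IC50 within two decades of the
# tested range; Hill slope strictly inside (0, 2).
hill_bounds <- function(log_conc) {
  list(
    lower = c(min(log_conc) - 2, 1e-3),
    upper = c(max(log_conc) + 2, 2 - 1e-6)
  )
}

# Bounded least-squares on per-concentration means with multi-start:
# log10 IC50 started at the min, mid and max of the tested log range,
# Hill slope started at 1. Best RSS wins; near-ties go to the slope
# closest to 1.
hill_ls_fit <- function(log_conc, y) {
  b <- hill_bounds(log_conc)
  starts <- c(min(log_conc), mean(range(log_conc)), max(log_conc))
  resid_fun <- function(par) y - hill_predict(log_conc, par[1], par[2])
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(s, 1),
      lower = b$lower, upper = b$upper,
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 500
      )
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cand <- list(par = fit$par, rss = sum(fit$fvec^2))
    if (is.null(best) ||
        cand$rss < best$rss * (1 - 1e-9) ||
        (abs(cand$rss - best$rss) <= 1e-9 * max(best$rss, 1e-300) &&
         abs(cand$par[2] - 1) < abs(best$par[2] - 1))) {
      best <- cand
    }
  }
  best
}

hill_fit_row <- function(log10_ic50 = NA_real_, hill_slope = NA_real_,
                         rss = NA_real_, fit_status, n_conc = NA_integer_) {
  tibble::tibble(
    log10_ic50 = log10_ic50, hill_slope = hill_slope,
    top = 100, bottom = 0, rss = rss,
    fit_status = fit_status, n_conc = as.integer(n_conc)
  )
}

#' Fit a constrained Hill curve to one concentration-response
#'
#' Unweighted least squares of [hill_predict()] against per-concentration
#' mean inhibition, with Top fixed at 100%, Bottom at 0%, the Hill slope
#' constrained to (0, 2) and log10 IC50 to within two decades of the
#' tested concentration range.
#'
#' No curve is fitted when the response shows no usable
#' concentration-dependent block: if the maximum mean inhibition is at or
#' below `nofit_max_effect_pct` (default 20%), or the Spearman rank
#' correlation between concentration and mean inhibition is zero or
#' negative, the result carries `fit_status = "no_fit"` and no parameters.
#' Fewer than `min_concs` usable concentrations (each needing
#' `min_wells` wells) gives `fit_status = "insufficient_data"`.
#'
#' @param points Tibble for a single site x drug x current with columns
#'   `concentration` (molar) and `pct_inhibition` (per-concentration mean,
#'   %); optional `n_wells` and `insufficient` columns gate usability.
#' @param config An [apc_config()].
#' @return One-row tibble: `log10_ic50`, `hill_slope`, `top`, `bottom`,
#'   `rss`, `fit_status` (`"ok"`, `"no_fit"` or `"insufficient_data"`),
#'   `n_conc`.
#' @export
fit_hill <- function(points, config = apc_config()) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "pct_inhibition") %in% names(points)))
  usable <- points
  if ("insufficient" %in% names(usable)) {
    usable <- usable[!usable$insufficient, , drop = FALSE]
  } else if ("n_wells" %in% names(usable)) {
    usable <- usable[usable$n_wells >= config$min_wells, , drop = FALSE]
  }
  usable <- usable[is.finite(usable$concentration) &
                     usable$concentration > 0 &
                     is.finite(usable$pct_inhibition), , drop = FALSE]
  usable <- usable[order(usable$concentration), , drop = FALSE]
  if (length(unique(usable$concentration)) < config$min_concs) {
    return(hill_fit_row(fit_status = "insufficient_data",
                        n_conc = length(unique(usable$concentration))))
  }
  y <- usable$pct_inhibition
  logc <- log10(usable$concentration)
  rho <- suppressWarnings(stats::cor(logc, y, method = "spearman"))
  if (max(y) <= config$nofit_max_effect_pct || is.na(rho) || rho <= 0) {
    return(hill_fit_row(fit_status = "no_fit", n_conc = length(y)))
  }
  best <- hill_ls_fit(logc, y)
  if (is.null(best)) {
    return(hill_fit_row(fit_status = "no_fit", n_conc = length(y)))
  }
  hill_fit_row(log10_ic50 = best$par[1], hill_slope = best$par[2],
               rss = best$rss, fit_status = "ok", n_conc = length(y))
}

#' Fit Hill curves for every site x drug x current group
#'
#' Maps [fit_hill()] over the grouped concentration-response points and
#' returns a long IC50 table (one row per group) suitable for the
#' variability and agreement analyses.
#'
#' @param points Output of [aggregate_inhibition()].
#' @param config An [apc_config()].
#' @return Tibble with columns `site_id`, `platform_id`, `drug_id`,
#'   `current_type`, `replicate_index`, `log10_ic50`, `hill_slope`,
#'   `rss`, `fit_status`, `n_conc`.
#' @export
fit_hill_all <- function(points, config = apc_config()) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0) {
    return(tibble::tibble(
      site_id = character(), platform_id = character(),
      drug_id = character(), current_type = character(),
      replicate_index = integer(), log10_ic50 = numeric(),
      hill_slope = numeric(), rss = numeric(),
      fit_status = character(), n_conc = integer()
    ))
  }
  points |>
    dplyr::arrange(.data$site_id, .data$drug_id, .data$current_type,
                   .data$concentration) |>
    tidyr::nest(.by = c("site_id", "platform_id", "drug_id",
                        "current_type")) |>
    dplyr::mutate(fit = purrr::map(.data$data, fit_hill, config = config)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("fit") |>
    dplyr::mutate(replicate_index = 0L,
                  .after = "current_type") |>
    dplyr::select(-"top", -"bottom") |>
    dplyr::arrange(.data$current_type, .data$drug_id, .data$site_id)
}

#' Back-calculate an IC50 from a single-concentration block measurement
#'
#' Exact algebraic inverse of [hill_predict()] with Top = 100 and
#' Bottom = 0: given the percent inhibition observed at one test
#' concentration, `IC50 = conc * ((100 - inhibition) / inhibition)^(1 /
#' hill_slope)`. Used to bracket the IC50 implied by historical
#' single-concentration screening data (e.g. mean block +/- 2 SD).
#'
#' @param conc Test concentration (any unit; the result is in the same
#'   unit).
#' @param inhibition Observed percent inhibition, strictly between 0
#'   and 100.
#' @param hill_slope Assumed Hill slope (default 1).
#' @return Implied IC50 in the unit of `conc` (vectorised).
#' @export
invert_single_concentration <- function(conc, inhibition, hill_slope = 1) {
  stopifnot(all(conc > 0), all(hill_slope > 0))
  if (any(inhibition <= 0 | inhibition >= 100)) {
    stop("inhibition must be strictly between 0 and 100 percent")
  }
  conc * ((100 - inhibition) / inhibition)^(1 / hill_slope)
}
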