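#' Platform-level mean log10 IC50 table
#'
#' Averages the fitted log10 IC50 values across sites and replicates
#' within each platform x drug x current, producing the paired values the
#' Bland-Altman comparison operates on. Only `fit_status == "ok"`
#' records contribute.
#'
#' @param records Long IC50 table.
#' @return Tibble per platform x drug x current: `mean_log10_ic50`, `n`.
#' @export
platform_mean_table <- function(records) {
  stopifnot(is.data.frame(records))
  ok <- records[records$fit_status == "ok", , drop = FALSE]
  ok |>
    dplyr::summarise(
      mean_log10_ic50 = mean(.data$log10_ic50),
      n = dplyr::n(),
      .by = c("platform_id", "drug_id", "current_type")
    ) |>
    dplyr::arrange(.data$current_type, .data$drug_id, .data$platform_id)
}

#' Bland-Altman agreement between two platforms
#'
#' Given the drug-matched platform mean log10 IC50 values `log_a` and
#' `log_b`, computes the per-drug differences `a - b`, their mean and
#' sample SD, and the limits of agreement
#' `mean_diff -/+ loa_multiplier * sd_diff` (multiplier 2 by default,
#' giving approximately 95% coverage). On the concentration scale,
#' `mean_ratio = 10^mean_diff` is the average fold bias of platform A
#' relative to B and `loa_fold_low` / `loa_fold_high` bracket the typical
#' fold difference. The pair passes the high-throughput screening
#' acceptance criterion when both limits lie within
#' `(-loa_log_bound, +loa_log_bound)` — with the default 0.48 bound,
#' 3-fold on the raw scale. Pearson correlation of the paired log values
#' is reported alongside.
#'
#' With fewer than two shared drugs the SD, limits and pass flag are
#' returned as `NA`.
#'
#' @param log_a,log_b Paired log10 molar IC50 vectors (same drugs, same
#'   order).
#' @param config An [apc_config()] supplying `loa_multiplier` and
#'   `loa_log_bound`.
#' @return One-row tibble: `n_drugs`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high` (log10 units), `mean_ratio`, `loa_fold_low`,
#'   `loa_fold_high`, `pass_criterion`, `pearson_r`.
#' @export
bland_altman <- function(log_a, log_b, config = apc_config()) {
  stopifnot(length(log_a) == length(log_b))
  d <- log_a - log_b
  n <- length(d)
  if (n < 2) {
    return(tibble::tibble(
      n_drugs = n, mean_diff = if (n == 1) d else NA_real_,
      sd_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
      mean_ratio = if (n == 1) fold_change(d) else NA_real_,
      loa_fold_low = NA_real_, loa_fold_high = NA_real_,
      pass_criterion = NA, pearson_r = NA_real_
    ))
  }
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - config$loa_multiplier * s
  hi <- m + config$loa_multiplier * s
  r <- if (stats::sd(log_a) > 0 && stats::sd(log_b) > 0) {
    stats::cor(log_a, log_b)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_drugs = n, mean_diff = m, sd_diff = s,
    loa_low = lo, loa_high = hi,
    mean_ratio = fold_change(m),
    loa_fold_low = fold_change(lo), loa_fold_high = fold_change(hi),
    pass_criterion = lo >= -config$loa_log_bound &
      hi <= config$loa_log_bound,
    pearson_r = r
  )
}

#' Pairwise platform agreement matrix
#'
#' Runs [bland_altman()] for every ordered pair of platforms within each
#' current, pairing drugs on their platform-level mean log10 IC50 (sites
#' averaged first). Pairs sharing fewer than two drugs are reported with
#' `n_drugs` and `NA` statistics, mirroring a full comparison matrix.
#'
#' @param records Long IC50 table.
#' @param config An [apc_config()].
#' @return Tibble with one row per current x ordered platform pair:
#'   `platform_a`, `platform_b` plus the [bland_altman()] columns.
#' @export
agreement_matrix <- function(records, config = apc_config()) {
  pm <- platform_mean_table(records)
  empty <- tibble::tibble(
    current_type = character(), platform_a = character(),
    platform_b = character(), n_drugs = integer(), mean_diff = numeric(),
    sd_diff = numeric(), loa_low = numeric(), loa_high = numeric(),
    mean_ratio = numeric(), loa_fold_low = numeric(),
    loa_fold_high = numeric(), pass_criterion = logical(),
    pearson_r = numeric()
  )
  if (nrow(pm) == 0) return(empty)
  out <- list()
  for (ct in sort(unique(pm$current_type))) {
    sub <- pm[pm$current_type == ct, , drop = FALSE]
    plats <- sort(unique(sub$platform_id))
    if (length(plats) < 2) next
    for (pa in plats) for (pb in plats) {
      if (pa == pb) next
      wide <- merge(
        sub[sub$platform_id == pa, c("drug_id", "mean_log10_ic50")],
        sub[sub$platform_id == pb, c("drug_id", "mean_log10_ic50")],
        by = "drug_id", suffixes = c("_a", "_b")
      )
      ba <- bland_altman(wide$mean_log10_ic50_a, wide$mean_log10_ic50_b,
                         config)
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(current_type = ct, platform_a = pa, platform_b = pb),
        ba
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$current_type, .data$platform_a, .data$platform_b)
}
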