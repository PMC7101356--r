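#' Plot the spread of log10 IC50 values per drug
#'
#' Box-and-whisker summary (median, 25/75 percentiles, min/max) of the
#' fitted log10 IC50 values per drug for one current, with individual
#' site values overlaid and coloured by platform.
#'
#' @param records Long IC50 table.
#' @param current_type Current to plot.
#' @return A ggplot object.
#' @export
plot_ic50_spread <- function(records, current_type = "hERG") {
  ok <- records[records$fit_status == "ok" &
                  records$current_type == current_type, , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$drug_id,
                                   y = .data$log10_ic50)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = Inf) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$platform_id),
                         width = 0.15, height = 0) +
    ggplot2::labs(x = NULL, y = "log10 IC50 (molar)",
                  colour = "platform",
                  title = paste0(current_type,
                                 " IC50 spread across sites")) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for one platform pair
#'
#' Per-drug difference of platform mean log10 IC50 (A - B) against the
#' pair mean, with the mean-difference line and the limits of agreement.
#'
#' @param records Long IC50 table.
#' @param platform_a,platform_b Platforms to compare.
#' @param current_type Current to plot.
#' @param config An [apc_config()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(records, platform_a, platform_b,
                              current_type = "hERG",
                              config = apc_config()) {
  pm <- platform_mean_table(records)
  pm <- pm[pm$current_type == current_type, , drop = FALSE]
  wide <- merge(
    pm[pm$platform_id == platform_a, c("drug_id", "mean_log10_ic50")],
    pm[pm$platform_id == platform_b, c("drug_id", "mean_log10_ic50")],
    by = "drug_id", suffixes = c("_a", "_b")
  )
  ba <- bland_altman(wide$mean_log10_ic50_a, wide$mean_log10_ic50_b,
                     config)
  df <- tibble::tibble(
    drug_id = wide$drug_id,
    avg = (wide$mean_log10_ic50_a + wide$mean_log10_ic50_b) / 2,
    diff = wide$mean_log10_ic50_a - wide$mean_log10_ic50_b
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "blue", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "pair mean log10 IC50 (molar)",
      y = paste0("difference ", platform_a, " - ", platform_b),
      title = paste0(current_type, ": ", platform_a, " vs ", platform_b)
    ) +
    ggplot2::theme_minimal()
}
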