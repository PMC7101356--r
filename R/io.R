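# Long-format CSV interchange. One canonical unit set internally:
# molar for concentrations, nA for currents, MOhm for resistance;
# on disk, concentrations travel in the uM column `conc_uM`.

wells_csv_cols <- c("site_id", "platform_id", "current_type", "drug_id",
                    "plate_id", "well_id", "conc_uM", "pre_drug_nA",
                    "steady_state_nA", "endblocker_nA", "rm_mohm",
                    "temperature_class")
wells_num_cols <- c("conc_uM", "pre_drug_nA", "steady_state_nA",
                    "endblocker_nA", "rm_mohm")

ic50_csv_cols <- c("site_id", "platform_id", "drug_id", "current_type",
                   "replicate_index", "log10_ic50_molar", "hill_slope",
                   "fit_status")

#' Read a long-format well-recording CSV
#'
#' Reads one row per well with the schema `site_id, platform_id,
#' current_type, drug_id, plate_id, well_id, conc_uM, pre_drug_nA,
#' steady_state_nA, endblocker_nA, rm_mohm, temperature_class`,
#' converting concentrations from the micromolar column convention to
#' internal molar (`x 1e-6`). A missing required column is a schema
#' error; rows with non-numeric or invalid values (negative
#' concentration, non-positive membrane resistance, non-finite currents)
#' are dropped with a line-numbered diagnostic rather than aborting the
#' read.
#'
#' @param path CSV file path.
#' @param config An [apc_config()] (reserved for schema options).
#' @return Tibble of well records (internal units) with attribute
#'   `"problems"`: a tibble of `line` (file line number, header = 1) and
#'   `message` for every rejected row. A warning summarises rejections.
#' @export
read_wells <- function(path, config = apc_config()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(wells_csv_cols, names(raw))
  if (length(missing) > 0) {
    stop("wells file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num <- lapply(raw[wells_num_cols],
                function(x) suppressWarnings(as.numeric(x)))
  bad_num <- Reduce(`|`, lapply(num, function(x) !is.finite(x)))
  bad_rng <- !bad_num & (num$conc_uM < 0 | num$rm_mohm <= 0)
  bad <- bad_num | bad_rng
  problems <- tibble::tibble(
    line = which(bad) + 1L,   # +1 for the header line
    message = ifelse(bad_num[bad],
                     "non-numeric or missing numeric value",
                     "out-of-range value (conc < 0 or rm <= 0)")
  )
  out <- tibble::tibble(
    site_id = raw$site_id, platform_id = raw$platform_id,
    current_type = raw$current_type, drug_id = raw$drug_id,
    plate_id = raw$plate_id, well_id = raw$well_id,
    concentration = num$conc_uM * 1e-6,
    pre_drug_current = num$pre_drug_nA,
    steady_state_current = num$steady_state_nA,
    endblocker_current = num$endblocker_nA,
    membrane_resistance = num$rm_mohm,
    temperature_class = raw$temperature_class
  )[!bad, , drop = FALSE]
  if (nrow(problems) > 0) {
    warning(nrow(problems), " row(s) rejected while reading '", path,
            "' (see attr(., 'problems')); first at line ",
            problems$line[1])
  }
  attr(out, "problems") <- problems
  out
}

#' Write well records to the interchange CSV
#'
#' Inverse of [read_wells()]: internal molar concentrations are rendered
#' in the micromolar column `conc_uM`.
#'
#' @param wells Tibble of well records (internal units).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  out <- tibble::tibble(
    site_id = wells$site_id, platform_id = wells$platform_id,
    current_type = wells$current_type, drug_id = wells$drug_id,
    plate_id = wells$plate_id, well_id = wells$well_id,
    conc_uM = wells$concentration * 1e6,
    pre_drug_nA = wells$pre_drug_current,
    steady_state_nA = wells$steady_state_current,
    endblocker_nA = wells$endblocker_current,
    rm_mohm = wells$membrane_resistance,
    temperature_class = wells$temperature_class
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a long-format per-site IC50 table
#'
#' Schema: `site_id, platform_id, drug_id, current_type,
#' replicate_index, log10_ic50_molar, hill_slope, fit_status`.
#' Enforces the record invariants: `log10_ic50` must be present exactly
#' when `fit_status == "ok"`, and present Hill slopes must lie in
#' (0, 2). Violating rows are dropped with line-numbered diagnostics.
#'
#' @param path CSV file path.
#' @return Tibble with columns `site_id`, `platform_id`, `drug_id`,
#'   `current_type`, `replicate_index`, `log10_ic50`, `hill_slope`,
#'   `fit_status`, plus a `"problems"` attribute as in [read_wells()].
#' @export
read_ic50_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(ic50_csv_cols, names(raw))
  if (length(missing) > 0) {
    stop("IC50 file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  lg <- suppressWarnings(as.numeric(raw$log10_ic50_molar))
  hs <- suppressWarnings(as.numeric(raw$hill_slope))
  ri <- suppressWarnings(as.integer(raw$replicate_index))
  st <- raw$fit_status
  bad_status <- !st %in% c("ok", "no_fit", "insufficient_data")
  bad_ok <- st == "ok" & (!is.finite(lg) | !is.finite(hs) |
                            hs <= 0 | hs >= 2)
  bad_cens <- st != "ok" & !bad_status & is.finite(lg)
  bad_ri <- is.na(ri)
  bad <- bad_status | bad_ok | bad_cens | bad_ri
  msg <- dplyr::case_when(
    bad_status ~ "unknown fit_status",
    bad_ok ~ "ok record without valid log10_ic50 / hill_slope in (0, 2)",
    bad_cens ~ "censored record carries a log10_ic50",
    bad_ri ~ "non-integer replicate_index",
    .default = ""
  )
  problems <- tibble::tibble(line = which(bad) + 1L, message = msg[bad])
  out <- tibble::tibble(
    site_id = raw$site_id, platform_id = raw$platform_id,
    drug_id = raw$drug_id, current_type = raw$current_type,
    replicate_index = ri, log10_ic50 = lg, hill_slope = hs,
    fit_status = st
  )[!bad, , drop = FALSE]
  if (nrow(problems) > 0) {
    warning(nrow(problems), " row(s) rejected while reading '", path,
            "' (see attr(., 'problems'))")
  }
  attr(out, "problems") <- problems
  out
}

#' Write a long-format per-site IC50 table
#'
#' @param records Long IC50 table (see [fit_hill_all()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ic50_table <- function(records, path) {
  out <- tibble::tibble(
    site_id = records$site_id, platform_id = records$platform_id,
    drug_id = records$drug_id, current_type = records$current_type,
    replicate_index = records$replicate_index,
    log10_ic50_molar = records$log10_ic50,
    hill_slope = records$hill_slope,
    fit_status = records$fit_status
  )
  readr::write_csv(out, path)
  invisible(path)
}
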