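#' Write a trial data set to CSV
#'
#' One row per patient-day with columns `patient_id, day, block, period,
#' treatment, <covariates...>, <outcome>, missing`. Design columns
#' (`patient_id`, `day`, `block`, `period`, `treatment`) are always
#' emitted — the schedule is known by design even for missing days — while
#' measurement cells of masked rows are written as `NA`. UTF-8, comma
#' separated, `NA` for missing.
#'
#' @param data A long trial tibble.
#' @param path Output CSV path.
#' @param manifest Also write a JSON run manifest next to the CSV.
#' @param seed Seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, manifest = TRUE, seed = NULL) {
  out <- tibble::as_tibble(data)
  keys <- c("patient_id", "day", "block", "period", "treatment", "missing")
  value_cols <- setdiff(names(out), keys)
  for (cl in value_cols) out[[cl]][out$missing] <- NA
  readr::write_csv(out, path, na = "NA")
  if (manifest) {
    cfg <- attr(data, "config")
    write_manifest(path, command = "write_trial_csv", seed = seed %||% attr(data, "seed"),
                   config = cfg)
  }
  invisible(path)
}

#' Read a trial data set from CSV
#'
#' Inverse of [write_trial_csv()]: validates the mandatory columns
#' (`patient_id`, `day`, `treatment`, and the outcome), sorts days within
#' patient, marks rows with a missing outcome (or an explicit `missing`
#' column) as masked, and keeps any unknown columns as covariates.
#'
#' @param path CSV file path.
#' @param outcome Outcome column name, default `"pain"`.
#' @return A long trial tibble.
#' @export
read_trial_csv <- function(path, outcome = "pain") {
  if (!file.exists(path)) {
    abort(paste0("Trial CSV not found: ", path), class = "nof1_argument_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  mandatory <- c("patient_id", "day", "treatment", outcome)
  absent <- setdiff(mandatory, names(df))
  if (length(absent)) {
    abort(paste0("Trial CSV lacks mandatory column(s): ",
                 paste(absent, collapse = ", ")),
          class = "nof1_schema_error")
  }
  if (anyDuplicated(df[, c("patient_id", "day")])) {
    abort("Duplicate (patient_id, day) rows in trial CSV.",
          class = "nof1_schema_error")
  }
  df <- dplyr::arrange(df, .data$patient_id, .data$day)
  if (!"missing" %in% names(df)) df$missing <- FALSE
  df$missing <- df$missing | is.na(df[[outcome]])
  df$missing <- ifelse(is.na(df$missing), TRUE, df$missing)
  dplyr::relocate(df, "missing", .after = dplyr::last_col())
}

#' Write an analysis result or results table
#'
#' Single estimates go to JSON (keys `method`, `estimate`, `se` plus
#' method-specific details); Monte-Carlo tables go to tidy CSV with a
#' stable column order. A JSON run manifest is written next to the output.
#'
#' @param result An `nof1_estimate` or `nof1_mc` table.
#' @param path Output path (`.json` for estimates, `.csv` for tables).
#' @param seed Seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, seed = NULL) {
  if (inherits(result, "nof1_estimate")) {
    details <- result$details
    details <- details[setdiff(names(details), c("samples1", "samples2"))]
    payload <- c(list(method = result$method, estimate = result$estimate,
                      se = result$se, n_patients = result$n_patients,
                      n_obs = result$n_obs),
                 details)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else if (inherits(result, "nof1_mc")) {
    readr::write_csv(tibble::as_tibble(result), path)
  } else {
    abort("`result` must be an nof1_estimate or an nof1_mc table.",
          class = "nof1_argument_error")
  }
  write_manifest(path, command = "write_results", seed = seed)
  invisible(path)
}

#' Read a Monte-Carlo results table written by [write_results()]
#' @param path CSV path.
#' @return An `nof1_mc` tibble.
#' @export
read_results_csv <- function(path) {
  out <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      method = readr::col_character(),
      missing = readr::col_logical(),
      degraded = readr::col_logical(),
      mean_estimate = readr::col_double(),
      sd_estimate = readr::col_double(),
      mean_se = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  class(out) <- c("nof1_mc", class(out))
  out
}

write_manifest <- function(path, command, seed = NULL, config = NULL) {
  manifest <- list(
    tool = "nofonesim",
    version = as.character(utils::packageVersion("nofonesim")),
    command = command,
    output = basename(path),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(unclass(config)) else NULL,
    config = if (!is.null(config)) unclass(config) else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
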