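# CSV/JSON plumbing. All floating-point CSV output is written at 6
# significant digits for byte-stable files across platforms.

fmt6 <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- NA
  trimws(out)
}

write_table_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write model outputs to CSV
#'
#' Thin writers for the package's tabular outputs, all at fixed
#' 6-significant-digit formatting: concentration curves (`time_hr`,
#' `level_pg_ml`), sensitivity results, uncertainty bands, cohort fits
#' and cohort tables.
#'
#' @param x The object to write (a `concentration_curve`,
#'   `sensitivity_result`, `uncertainty_band`, the `fits` data.frame of
#'   [fit_cohort()], or a `cohort_table`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "concentration_curve") || is.data.frame(x))
  write_table_csv(x, path)
}

#' @rdname write_curve_csv
#' @export
write_sensitivity_csv <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_result"))
  write_table_csv(x, path)
}

#' @rdname write_curve_csv
#' @export
write_band_csv <- function(x, path) {
  stopifnot(inherits(x, "uncertainty_band"))
  write_table_csv(x, path)
}

#' @rdname write_curve_csv
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  keep <- intersect(c("subject_id", "biomarker", "timepoint_label",
                      "time_hr", "level_pg_ml", "Vd_ml"), names(x))
  write_table_csv(x[keep], path)
}

#' @rdname write_curve_csv
#' @export
write_truth_csv <- function(x, path) {
  write_table_csv(truth_report(x), path)
}

#' Read a long-format cohort table from CSV
#'
#' Expects columns `subject_id`, `biomarker`, `timepoint_label`,
#' `level_pg_ml`, and optionally `time_hr` and `Vd_ml` — the format
#' emitted by [write_cohort_csv()] and consumed by [fit_cohort()].
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "biomarker", "timepoint_label", "level_pg_ml")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Serialize kinetic parameters and scenarios to JSON (and back)
#'
#' @param params A [kinetic_params()] object.
#' @param scenario An [injury_scenario()] object.
#' @param path File path, or `NULL` to return the JSON string.
#' @param json JSON text or file path to read.
#' @return Writers: the path (or JSON string). Readers: the restored
#'   object.
#' @export
model_to_json <- function(params, scenario, path = NULL) {
  check_params(params); check_scenario(scenario)
  obj <- list(params = unclass(params), scenario = unclass(scenario))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  list(params = kinetic_params(obj$params$ka, obj$params$ke, obj$params$F),
       scenario = injury_scenario(obj$scenario$D0, obj$scenario$Vd,
                                  obj$scenario$t0))
}
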