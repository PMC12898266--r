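# Readers and writers: long-format measurement CSV, patient table CSV,
# target YAML, scenario YAML, parameter-table CSV, model-report TSV and the
# run-summary JSON.

iso_to_day <- function(x, what, file) {
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- which(is.na(d))
  if (length(bad))
    stop(sprintf("%s: malformed %s on data row(s) %s", file, what,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  as.numeric(d)
}

#' Read a long-format measurement CSV
#'
#' Columns `patient_id`, `cm_name`, `date` (ISO-8601) and `value`. Dates are
#' converted to integer day numbers (date resolution; all engine arithmetic
#' is in whole days).
#'
#' @param path CSV file path.
#' @return `data.table` with `patient_id`, `cm_name`, `day`, `value`.
#' @export
read_measurements <- function(path) {
  dt <- fread(path)
  need <- c("patient_id", "cm_name", "date", "value")
  if (!all(need %in% names(dt)))
    stop(path, ": measurement CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  dt[, day := iso_to_day(date, "date", path)]
  val <- suppressWarnings(as.numeric(dt$value))
  bad <- which(!is.finite(val))
  if (length(bad))
    stop(sprintf("%s: non-numeric value on data row(s) %s", path,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  dt[, .(patient_id = as.character(patient_id), cm_name, day, value = val)]
}

#' Read a patient table CSV
#'
#' Columns `patient_id`, `index_date` (ISO-8601), `death60`, and optionally
#' `age`, `charl_2yr`, `charl_ever`, `elix_2yr`, `elix_ever`.
#'
#' @param path CSV file path.
#' @return `data.table` with `index_day` replacing `index_date`.
#' @export
read_patients <- function(path) {
  dt <- fread(path)
  need <- c("patient_id", "index_date", "death60")
  if (!all(need %in% names(dt)))
    stop(path, ": patient CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(dt$death60 %in% c(0, 1)))
    stop(path, ": death60 must be 0/1", call. = FALSE)
  dt[, index_day := iso_to_day(index_date, "index_date", path)]
  dt[, index_date := NULL]
  dt[, patient_id := as.character(patient_id)]
  dt[]
}

#' Read target specifications from YAML
#'
#' A map `cm_name -> {low, high}` (either bound may be omitted), e.g.
#' \preformatted{SBP: {high: 140}
#' HCT: {low: 38, high: 52}}
#'
#' @param path YAML file path.
#' @return Named list of [target_spec()].
#' @export
read_targets <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) stop(path, ": empty target file", call. = FALSE)
  out <- lapply(names(y), function(cm) {
    spec <- y[[cm]]
    target_spec(cm,
                low = if (!is.null(spec$low)) spec$low else NA,
                high = if (!is.null(spec$high)) spec$high else NA)
  })
  names(out) <- names(y)
  out
}

#' Write target specifications to YAML
#' @param targets Named list of [target_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  y <- lapply(targets, function(t) {
    spec <- list()
    if (!is.na(t$low)) spec$low <- t$low
    if (!is.na(t$high)) spec$high <- t$high
    spec
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write the per-patient parameter table
#'
#' One row per patient, one column per `<CM><Parameter>` candidate, missing
#' cells empty.
#'
#' @param dm A `design_matrix` (or any table with `patient_id` and candidate
#'   columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(dm, path) {
  cols <- c("patient_id", intersect(candidate_column_names(attr(dm, "cms",
                                      exact = TRUE) %||% cm_codes()),
                                    names(dm)))
  fwrite(as.data.table(dm)[, cols, with = FALSE], path, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model report TSV
#'
#' Tables with columns `Parameter`, `Coefficient`, `StdErr`, `pValue`,
#' `CI95lo`, `CI95hi`.
#'
#' @param fit An `ll_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(fit, path) {
  fwrite(coef_table(fit), path, sep = "\t")
  invisible(path)
}

#' Write the run-level JSON summary
#' @param summary Named list (n_used, AUROCs, comparisons, config echo...).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a simulation scenario from YAML
#'
#' The YAML can override any part of [default_scenario()]: top-level
#' `missing_cm_prob`, the `visit` fields, the `outcome` model (`intercept`,
#' and named maps `coefs`, `centers`, `scales`) and per-measurement
#' `trajectories` fields. `base: "null"` starts from [null_scenario()]
#' instead.
#'
#' @param path YAML file path.
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (identical(y$base, "null")) null_scenario() else default_scenario()
  if (!is.null(y$missing_cm_prob)) {
    stopifnot(y$missing_cm_prob >= 0, y$missing_cm_prob < 1)
    base$missing_cm_prob <- y$missing_cm_prob
  }
  if (!is.null(y$visit)) {
    v <- utils::modifyList(unclass(base$visit), y$visit)
    base$visit <- visit_model(v$base_rate, v$abnormal_mult,
                              unlist(v$fu_years_range))
  }
  if (!is.null(y$trajectories)) {
    for (cm in names(y$trajectories)) {
      if (!cm %in% names(base$trajectories))
        stop("read_scenario: unknown measurement in trajectories: ", cm)
      t <- utils::modifyList(unclass(base$trajectories[[cm]]),
                             y$trajectories[[cm]])
      base$trajectories[[cm]] <- do.call(trajectory_model, t)
    }
  }
  if (!is.null(y$outcome)) {
    o <- unclass(base$outcome)
    if (!is.null(y$outcome$intercept)) o$intercept <- y$outcome$intercept
    for (f in c("coefs", "centers", "scales", "comorbid_coefs"))
      if (!is.null(y$outcome[[f]])) o[[f]] <- unlist(y$outcome[[f]])
    if (!is.null(y$outcome$age_coef)) o$age_coef <- y$outcome$age_coef
    base$outcome <- do.call(outcome_model, o)
  }
  base
}

# small stable hash for logging which configuration produced a run
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
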