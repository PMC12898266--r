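# Core data model: longitudinal measurement series, treatment targets,
# abnormality and interval classification, index-date truncation, BMI.

#' Clinical measurements tracked by the package
#'
#' The eleven routinely collected vital signs and laboratory analytes the
#' modelling pipeline summarizes: systolic and diastolic blood pressure,
#' oxygen saturation, body mass index, estimated glomerular filtration rate,
#' serum albumin, hematocrit, alanine aminotransferase, glycosylated
#' hemoglobin, and HDL/LDL cholesterol.
#'
#' @return Character vector of the 11 measurement codes.
#' @export
cm_codes <- function() {
  c("SBP", "DBP", "O2Sat", "BMI", "eGFR", "Alb", "HCT", "ALT", "A1c",
    "HDL", "LDL")
}

#' The 13 per-measurement parameters, in attribute order
#'
#' One scalar per clinical attribute is synthesized from a patient's complete
#' value set for a measurement: most recent value (current control); days and
#' number of readings not at goal (chronicity); abnormal area under the curve
#' and time-weighted average (disease burden); duration and count of the
#' current abnormal run and longest multi-reading run (refractoriness);
#' number of abnormal clusters (tendency to relapse); coefficient of
#' variation and mean absolute consecutive difference (lability); net change
#' and fractional deviation from the 3-value lagging mean (temporal trends).
#'
#' @return Character vector of the 13 parameter names.
#' @export
parameter_names <- function() {
  c("Value1",
    "FUDaysNotAtGoal", "NumNotAtGoal",
    "AbnAUC", "TimeWtAvg",
    "TimeNotAtGoal", "CtNotAtGoal", "MaxClustDays",
    "NumClust",
    "CoeffVar", "MeanValDiff",
    "NetChange", "Lag3Dev")
}

#' Clinical attribute of each parameter
#'
#' @return Named character vector mapping parameter name to one of the seven
#'   attributes: `control`, `chronicity`, `burden`, `refractoriness`,
#'   `relapse`, `lability`, `trends`.
#' @export
parameter_attributes <- function() {
  c(Value1 = "control",
    FUDaysNotAtGoal = "chronicity", NumNotAtGoal = "chronicity",
    AbnAUC = "burden", TimeWtAvg = "burden",
    TimeNotAtGoal = "refractoriness", CtNotAtGoal = "refractoriness",
    MaxClustDays = "refractoriness",
    NumClust = "relapse",
    CoeffVar = "lability", MeanValDiff = "lability",
    NetChange = "trends", Lag3Dev = "trends")
}

#' Attribute entry order for the stepwise main model
#'
#' Modelling starts with current control (the most recent values) and adds
#' the remaining attribute sets in succession.
#'
#' @return Character vector of the 7 attribute labels.
#' @export
attribute_order <- function() {
  c("control", "chronicity", "burden", "refractoriness", "relapse",
    "lability", "trends")
}

#' Create a treatment target specification
#'
#' A value is abnormal when it is strictly below `low` or strictly above
#' `high`; values exactly at a bound count as normal. At least one bound must
#' be given.
#'
#' @param cm_name Measurement code the target applies to.
#' @param low Lower bound, or `NA` for none.
#' @param high Upper bound, or `NA` for none.
#' @return An object of class `target_spec`.
#' @examples
#' sbp <- target_spec("SBP", high = 140)
#' is_abnormal(c(150, 140, 120), sbp)
#' @export
target_spec <- function(cm_name, low = NA_real_, high = NA_real_) {
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (is.na(low) && is.na(high))
    stop("target_spec: at least one of 'low'/'high' must be given for ",
         cm_name)
  if (!is.na(low) && !is.na(high) && low >= high)
    stop("target_spec: low bound must be below high bound for ", cm_name)
  structure(list(cm_name = as.character(cm_name), low = low, high = high),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  lo <- if (is.na(x$low)) "-" else format(x$low)
  hi <- if (is.na(x$high)) "-" else format(x$high)
  cat(sprintf("<target_spec> %s: normal range [%s, %s]\n", x$cm_name, lo, hi))
  invisible(x)
}

#' Default treatment targets for the 11 measurements
#'
#' Conventional adult outpatient thresholds, shipped as editable defaults
#' (every analysis should confirm them against local practice): SBP > 140
#' mmHg, DBP > 90 mmHg, O2Sat < 95 %, BMI > 30 kg/m2, eGFR < 60
#' mL/min/1.73m2, serum albumin < 3.5 g/dL, HCT outside 38-52 %, ALT > 40
#' U/L, A1c > 7 %, HDL < 40 mg/dL, LDL > 130 mg/dL. The albumin target
#' assumes serum albumin in g/dL; if your source records urinary albumin the
#' direction and scale are different and the target must be overridden.
#'
#' @return Named list of [target_spec()] objects, one per measurement code.
#' @export
default_targets <- function() {
  list(
    SBP   = target_spec("SBP",   high = 140),
    DBP   = target_spec("DBP",   high = 90),
    O2Sat = target_spec("O2Sat", low  = 95),
    BMI   = target_spec("BMI",   high = 30),
    eGFR  = target_spec("eGFR",  low  = 60),
    Alb   = target_spec("Alb",   low  = 3.5),
    HCT   = target_spec("HCT",   low  = 38, high = 52),
    ALT   = target_spec("ALT",   high = 40),
    A1c   = target_spec("A1c",   high = 7),
    HDL   = target_spec("HDL",   low  = 40),
    LDL   = target_spec("LDL",   high = 130)
  )
}

#' Is a value outside its treatment target?
#'
#' Strict inequalities: a value exactly at a bound is normal.
#'
#' @param value Numeric vector of measurement values.
#' @param target A [target_spec()].
#' @return Logical vector, `TRUE` where abnormal.
#' @export
is_abnormal <- function(value, target) {
  stopifnot(inherits(target, "target_spec"), all(is.finite(value)))
  lo <- if (is.na(target$low)) -Inf else target$low
  hi <- if (is.na(target$high)) Inf else target$high
  value < lo | value > hi
}

#' Construct a measurement series for one patient and one measurement
#'
#' Readings are sorted by day; same-day duplicates are resolved by keeping
#' the last-entered value for that day (with a warning), so spans between
#' successive readings are always well defined. Days are whole numbers
#' (dates); intra-day times should be floored to the date before ingestion.
#'
#' @param patient_id Patient identifier.
#' @param cm_name Measurement code.
#' @param day Integer-valued vector of days since an arbitrary epoch.
#' @param value Numeric vector of measurement values, same length as `day`.
#' @return An object of class `cm_series` with fields `patient_id`,
#'   `cm_name`, `day`, `value`.
#' @export
cm_series <- function(patient_id, cm_name, day = integer(), value = numeric()) {
  day <- as.numeric(day)
  value <- as.numeric(value)
  stopifnot(length(day) == length(value))
  if (length(day)) {
    if (any(!is.finite(day)) || any(day != round(day)))
      stop("cm_series: days must be whole numbers")
    if (any(!is.finite(value)))
      stop("cm_series: values must be finite")
    o <- order(day)            # stable: same-day entries keep input order
    day <- day[o]; value <- value[o]
    dup <- duplicated(day, fromLast = TRUE)
    if (any(dup)) {
      warning(sprintf(
        "cm_series(%s/%s): %d same-day duplicate reading(s) dropped (kept last)",
        patient_id, cm_name, sum(dup)))
      day <- day[!dup]; value <- value[!dup]
    }
  }
  structure(list(patient_id = patient_id, cm_name = as.character(cm_name),
                 day = day, value = value),
            class = "cm_series")
}

#' @export
print.cm_series <- function(x, ...) {
  cat(sprintf("<cm_series> patient %s, %s: %d reading(s)", x$patient_id,
              x$cm_name, length(x$day)))
  if (length(x$day))
    cat(sprintf(" over days %s..%s", format(x$day[1]),
                format(x$day[length(x$day)])))
  cat("\n")
  invisible(x)
}

#' @export
length.cm_series <- function(x) length(x$day)

#' Classify the interval between two successive readings
#'
#' Each reading is paired with the preceding one. Days between successive
#' abnormal readings are not at goal; between normal readings, at goal;
#' normal then abnormal is worsening; abnormal then normal is improving.
#'
#' @param prev_day,prev_value Day and value of the earlier reading.
#' @param next_day,next_value Day and value of the later reading.
#' @param target A [target_spec()].
#' @return List with `label` (one of `"AT_GOAL"`, `"NOT_AT_GOAL"`,
#'   `"WORSENING"`, `"IMPROVING"`) and `span_days`.
#' @export
classify_interval <- function(prev_day, prev_value, next_day, next_value,
                              target) {
  if (next_day < prev_day)
    stop("classify_interval: readings out of order (upstream sorting bug)")
  a1 <- is_abnormal(prev_value, target)
  a2 <- is_abnormal(next_value, target)
  label <- if (a1 && a2) "NOT_AT_GOAL"
    else if (!a1 && !a2) "AT_GOAL"
    else if (!a1 && a2) "WORSENING"
    else "IMPROVING"
  list(label = label, span_days = next_day - prev_day)
}

#' Truncate a series at the index date minus a blackout window
#'
#' Only readings taken at least `blackout_days` before the index date are
#' kept (day <= index_day - blackout_days, boundary retained). The default
#' 14-day blackout excludes readings that may reflect the pre-symptomatic
#' phase of the index illness.
#'
#' @param series A [cm_series()].
#' @param index_day Index (anchoring event) day.
#' @param blackout_days Nonnegative number of days before the index date to
#'   exclude; default 14.
#' @return A `cm_series` containing only the retained readings (possibly
#'   empty).
#' @export
truncate_at_index <- function(series, index_day, blackout_days = 14) {
  stopifnot(inherits(series, "cm_series"), blackout_days >= 0)
  cutoff <- index_day - blackout_days
  keep <- series$day <= cutoff
  series$day <- series$day[keep]
  series$value <- series$value[keep]
  series
}

#' Derive a BMI series from height and weight series
#'
#' One BMI reading is produced per weight reading as weight / height^2, using
#' the most recent height on or before the weight's day (height is
#' quasi-static, so forward fill is the standard convention). Weight readings
#' with no prior height are skipped; nonpositive heights or weights are
#' rejected with a warning.
#'
#' @param heights `cm_series` of heights in meters.
#' @param weights `cm_series` of weights in kilograms.
#' @return A `cm_series` with `cm_name = "BMI"` (kg/m2).
#' @examples
#' h <- cm_series(1, "height", 0, 1.80)
#' w <- cm_series(1, "weight", 50, 81.0)
#' derive_bmi_series(h, w)$value  # 25
#' @export
derive_bmi_series <- function(heights, weights) {
  stopifnot(inherits(heights, "cm_series"), inherits(weights, "cm_series"))
  bmi_from_vectors(heights$day, heights$value, weights$day, weights$value,
                   weights$patient_id)
}

bmi_from_vectors <- function(hd, hv, wd, wv, patient_id) {
  ok_h <- hv > 0
  if (!all(ok_h))
    warning(sprintf("derive_bmi_series: %d nonpositive height(s) rejected",
                    sum(!ok_h)))
  hd <- hd[ok_h]; hv <- hv[ok_h]
  ok_w <- wv > 0
  if (!all(ok_w))
    warning(sprintf("derive_bmi_series: %d nonpositive weight(s) rejected",
                    sum(!ok_w)))
  wd <- wd[ok_w]; wv <- wv[ok_w]
  if (!length(hd) || !length(wd))
    return(cm_series(patient_id, "BMI"))
  i <- findInterval(wd, hd)          # most recent height on/before each weight
  has_h <- i >= 1
  cm_series(patient_id, "BMI",
            day = wd[has_h],
            value = wv[has_h] / hv[i[has_h]]^2)
}

#' Derive BMI readings for a whole measurement table
#'
#' Applies the [derive_bmi_series()] rule per patient to a long-format table
#' containing `height` (meters) and `weight` (kilograms) rows: one BMI
#' reading per weight, using the most recent height on or before it. The
#' returned table has the height/weight rows replaced by `BMI` rows.
#'
#' @param measurements Long table with columns `patient_id`, `cm_name`,
#'   `day`, `value`; `cm_name` values `height` and `weight` are consumed.
#' @return The measurement table with `BMI` rows in place of
#'   height/weight.
#' @export
derive_bmi_table <- function(measurements) {
  dt <- as.data.table(measurements)
  hw <- c("height", "weight")
  if (!any(dt$cm_name %in% hw)) return(dt)
  rest <- dt[!cm_name %in% hw]
  ids <- unique(dt[cm_name %in% hw, patient_id])
  bmi <- rbindlist(lapply(ids, function(id) {
    h <- dt[patient_id == id & cm_name == "height"][order(day)]
    w <- dt[patient_id == id & cm_name == "weight"][order(day)]
    s <- bmi_from_vectors(h$day, h$value, w$day, w$value, id)
    if (!length(s$day)) return(NULL)
    data.table(patient_id = id, cm_name = "BMI", day = s$day,
               value = s$value)
  }))
  out <- rbindlist(list(rest, bmi), use.names = TRUE)
  setorder(out, patient_id, cm_name, day)
  out[]
}
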