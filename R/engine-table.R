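# Cohort-scale parameter derivation: one vectorized pass over the long
# measurement table, producing the same 13 parameters per patient x CM as
# batch_derive()/the running summary (tested to agree elementwise).

targets_table <- function(targets) {
  stopifnot(is.list(targets), length(targets) > 0)
  dt <- rbindlist(lapply(targets, function(t) {
    stopifnot(inherits(t, "target_spec"))
    data.table(cm_name = t$cm_name,
               low = if (is.na(t$low)) -Inf else t$low,
               high = if (is.na(t$high)) Inf else t$high)
  }))
  if (anyDuplicated(dt$cm_name))
    stop("duplicate target specifications")
  dt
}


#' Derive the 13 parameters for every patient and measurement in a cohort
#'
#' Vectorized equivalent of running [batch_derive()] on every patient x
#' measurement series of a long-format table. Readings are sorted by day
#' within each series; same-day duplicates keep the last-entered value (one
#' warning reports the total dropped). Series for measurements without a
#' target specification are rejected.
#'
#' @param measurements `data.frame`/`data.table` with columns `patient_id`,
#'   `cm_name`, `day`, `value` (long format).
#' @param targets Named list of [target_spec()], e.g. [default_targets()].
#' @param mode Time-weighted-average mode (see [compute_time_wt_avg()]).
#' @return `data.table` with one row per patient x measurement present in
#'   the input and one column per parameter (see [parameter_names()]);
#'   missing parameters are `NA`.
#' @export
derive_parameter_table <- function(measurements, targets = default_targets(),
                                   mode = c("full", "abnormal")) {
  mode <- match.arg(mode)
  dt <- as.data.table(measurements)
  need <- c("patient_id", "cm_name", "day", "value")
  if (!all(need %in% names(dt)))
    stop("measurements must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) == 0)
    stop("derive_parameter_table: no readings")
  tg <- targets_table(targets)
  unknown <- setdiff(unique(dt$cm_name), tg$cm_name)
  if (length(unknown))
    stop("no target specification for measurement(s): ",
         paste(unknown, collapse = ", "))
  dt <- dt[, .(patient_id, cm_name, day = as.numeric(day),
               value = as.numeric(value))]
  if (anyNA(dt$day) || any(!is.finite(dt$value)))
    stop("derive_parameter_table: non-finite day or value")
  setorder(dt, patient_id, cm_name, day)

  pid <- dt$patient_id; cm <- dt$cm_name
  nr <- nrow(dt)
  new_grp <- c(TRUE, pid[-1] != pid[-nr] | cm[-1] != cm[-nr])
  same_day <- !new_grp & c(FALSE, dt$day[-1] == dt$day[-nr])
  if (any(same_day)) {
    # keep the last-entered reading of each same-day run (sort was stable)
    drop <- c(same_day[-1], FALSE)
    warning(sprintf(
      "derive_parameter_table: %d same-day duplicate reading(s) dropped (kept last)",
      sum(drop)))
    dt <- dt[!drop]
    pid <- dt$patient_id; cm <- dt$cm_name
    nr <- nrow(dt)
    new_grp <- c(TRUE, pid[-1] != pid[-nr] | cm[-1] != cm[-nr])
  }

  m <- match(cm, tg$cm_name)
  core <- derive_params_core(dt$day, dt$value, new_grp,
                             tg$low[m], tg$high[m], mode)
  starts <- which(new_grp)
  out <- data.table(patient_id = pid[starts], cm_name = cm[starts])
  cbind(out, core)
}

# engine core: single C++ pass; rows must be grouped (new_grp marks group
# starts), day-sorted within group, one reading per day, bounds lo/hi aligned
derive_params_core <- function(day, value, new_grp, lo, hi, mode = "full") {
  m <- derive_core_cpp(as.numeric(day), as.numeric(value), as.logical(new_grp),
                       as.numeric(lo), as.numeric(hi),
                       identical(mode, "full"))
  out <- as.data.table(m)
  setnames(out, parameter_names())
  out[, NumNotAtGoal := as.integer(NumNotAtGoal)]
  out[, CtNotAtGoal := as.integer(CtNotAtGoal)]
  out[, NumClust := as.integer(NumClust)]
  out
}

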