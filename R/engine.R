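# Parameter engine: derive the 13 parameters for one measurement series,
# either in one pass over the full series (batch) or incrementally via a
# running summary updated whenever a new value arrives.

excess <- function(value, target) {
  lo <- if (is.na(target$low)) -Inf else target$low
  hi <- if (is.na(target$high)) Inf else target$high
  pmax(value - hi, 0) + pmax(lo - value, 0)
}

#' Trapezoidal area under a measurement series
#'
#' Simple trapezoidal estimate over the raw readings, without interpolation,
#' extrapolation or curve fitting, including all readings from the first to
#' the last value. Units are measurement-unit x days.
#'
#' @param series A [cm_series()].
#' @return The area, or `NA` when fewer than 2 readings exist.
#' @export
compute_auc <- function(series) {
  n <- length(series$day)
  if (n < 2) return(NA_real_)
  d <- series$day; v <- series$value
  sum((v[-n] + v[-1]) / 2 * diff(d))
}

#' Trapezoidal area outside the treatment target
#'
#' The excess curve e(v) = max(v - high, 0) + max(low - v, 0) is evaluated at
#' the readings only (no threshold-crossing interpolation) and integrated by
#' trapezoids; a segment that crosses the bound therefore contributes a
#' half-triangle based on the endpoint excesses. A disease-burden measure
#' that, unlike the raw area, cannot be large merely because follow-up is
#' long while values stay at goal.
#'
#' @param series A [cm_series()].
#' @param target A [target_spec()].
#' @return The abnormal area (unit x days), or `NA` when fewer than 2
#'   readings exist.
#' @export
compute_abn_auc <- function(series, target) {
  n <- length(series$day)
  if (n < 2) return(NA_real_)
  e <- excess(series$value, target)
  sum((e[-n] + e[-1]) / 2 * diff(series$day))
}

#' Time-weighted average of a measurement
#'
#' AUC divided by total days of follow-up. Because spacing between readings
#' enters the numerator, the estimate is robust to the tendency to measure a
#' CM more often when it is abnormal, which biases the raw mean toward the
#' abnormal side. With `mode = "abnormal"` the abnormal-area variant
#' (AbnAUC over follow-up) is returned instead.
#'
#' @param series A [cm_series()].
#' @param target A [target_spec()]; only needed for `mode = "abnormal"`.
#' @param mode `"full"` (default) or `"abnormal"`.
#' @return The average, or `NA` when fewer than 2 readings or zero follow-up
#'   span.
#' @export
compute_time_wt_avg <- function(series, target = NULL,
                                mode = c("full", "abnormal")) {
  mode <- match.arg(mode)
  n <- length(series$day)
  if (n < 2) return(NA_real_)
  span <- series$day[n] - series$day[1]
  if (span <= 0) return(NA_real_)
  a <- if (mode == "full") compute_auc(series)
       else compute_abn_auc(series, target)
  a / span
}

#' Chronicity: days and readings not at goal
#'
#' Successive reading pairs classified abnormal-to-abnormal contribute their
#' span to `fu_days_not_at_goal`; worsening and improving intervals belong to
#' neither the at-goal nor the not-at-goal total. `num_not_at_goal` counts
#' all readings outside the target.
#'
#' @param series A [cm_series()].
#' @param target A [target_spec()].
#' @return List with `fu_days_not_at_goal` and `num_not_at_goal`.
#' @export
compute_chronicity <- function(series, target) {
  n <- length(series$day)
  if (n == 0)
    return(list(fu_days_not_at_goal = 0, num_not_at_goal = 0L))
  a <- is_abnormal(series$value, target)
  fu <- if (n >= 2) sum(diff(series$day)[a[-n] & a[-1]]) else 0
  list(fu_days_not_at_goal = fu, num_not_at_goal = sum(a))
}

#' Detect clusters of consecutive abnormal readings
#'
#' A cluster is a maximal run of consecutive abnormal readings: it begins
#' with a change from a normal to an abnormal value (or with an abnormal
#' first reading) and terminates with the next normal value. A run still
#' abnormal at the final reading is returned open. Cluster duration is the
#' span from the first to the last abnormal reading of the run; the
#' terminating normal reading's day is not included (the improving interval
#' is classified separately).
#'
#' @param series A [cm_series()].
#' @param target A [target_spec()].
#' @return `data.frame` with one row per cluster, columns `start_day`,
#'   `last_abnormal_day`, `count`, `duration_days`, `open`, in time order.
#' @export
detect_clusters <- function(series, target) {
  n <- length(series$day)
  empty <- data.frame(start_day = numeric(), last_abnormal_day = numeric(),
                      count = integer(), duration_days = numeric(),
                      open = logical())
  if (n == 0) return(empty)
  a <- is_abnormal(series$value, target)
  if (!any(a)) return(empty)
  starts <- a & c(TRUE, !a[-n])
  id <- cumsum(starts)
  idx_a <- which(a)
  grp <- id[idx_a]
  first_i <- idx_a[!duplicated(grp)]
  last_i <- idx_a[!duplicated(grp, fromLast = TRUE)]
  data.frame(
    start_day = series$day[first_i],
    last_abnormal_day = series$day[last_i],
    count = as.integer(tabulate(grp)[unique(grp)]),
    duration_days = series$day[last_i] - series$day[first_i],
    open = last_i == n & a[n]
  )
}

#' Refractoriness of the current abnormal state
#'
#' `time_not_at_goal` and `ct_not_at_goal` describe the open cluster - the
#' consecutive days and readings not at goal leading up to the most recent
#' reading - and are therefore only defined for patients whose measurement is
#' abnormal at that time; otherwise both are missing. `max_clust_days` is the
#' longest duration among clusters with at least 2 consecutive abnormal
#' readings (missing when no such cluster exists).
#'
#' @param clusters Cluster table from [detect_clusters()].
#' @param last_reading_abnormal Is the most recent reading abnormal?
#' @return List with `time_not_at_goal`, `ct_not_at_goal`, `max_clust_days`
#'   (each possibly `NA`).
#' @export
compute_refractoriness <- function(clusters, last_reading_abnormal) {
  if (last_reading_abnormal) {
    open <- clusters[clusters$open, , drop = FALSE]
    if (nrow(open) != 1L)
      stop("compute_refractoriness: last reading abnormal but no open cluster",
           " (engine bug)")
    tng <- open$duration_days
    ctg <- open$count
  } else {
    if (any(clusters$open))
      stop("compute_refractoriness: open cluster but last reading normal",
           " (engine bug)")
    tng <- NA_real_
    ctg <- NA_integer_
  }
  eligible <- clusters$count >= 2L
  mcd <- if (any(eligible)) max(clusters$duration_days[eligible]) else NA_real_
  list(time_not_at_goal = tng, ct_not_at_goal = ctg, max_clust_days = mcd)
}

#' Lability: coefficient of variation and mean consecutive difference
#'
#' `coeff_var` is the grand (sample) standard deviation over the grand mean
#' of all values in the record; `mean_val_diff` is the average absolute
#' difference between consecutive pairs. Both need at least 2 readings;
#' `coeff_var` is additionally missing when the mean is zero.
#'
#' @param series A [cm_series()].
#' @return List with `coeff_var` and `mean_val_diff` (each possibly `NA`).
#' @export
compute_lability <- function(series) {
  n <- length(series$day)
  if (n < 2) return(list(coeff_var = NA_real_, mean_val_diff = NA_real_))
  m <- mean(series$value)
  cv <- if (m == 0) NA_real_ else sd(series$value) / m
  list(coeff_var = cv,
       mean_val_diff = sum(abs(diff(series$value))) / (n - 1))
}

#' Temporal trends: net change and short-term deviation
#'
#' `net_change` is the most recent minus the first value (0 for a single
#' reading). `lag3_dev` is the fractional deviation of the most recent value
#' from the mean of the 3 readings immediately preceding it,
#' (Value1 - Lag3Mean) / Lag3Mean; it requires at least 3 lagging values
#' (n >= 4) and a nonzero lagging mean, otherwise it is missing.
#'
#' @param series A [cm_series()].
#' @return List with `net_change` and `lag3_dev`.
#' @export
compute_trends <- function(series) {
  n <- length(series$day)
  if (n == 0) return(list(net_change = NA_real_, lag3_dev = NA_real_))
  v <- series$value
  nc <- v[n] - v[1]
  l3 <- NA_real_
  if (n >= 4) {
    m <- mean(v[(n - 3):(n - 1)])
    if (m != 0) l3 <- (v[n] - m) / m
  }
  list(net_change = nc, lag3_dev = l3)
}

#' Empty running summary
#'
#' The running summary holds the incremental state from which all 13
#' parameters can be read at any time; it is advanced with
#' [update_summary()] whenever a new value is added to the set, so a
#' patient's status relative to any measurement can be assessed at any point
#' in time without reprocessing the whole record.
#'
#' @param target A [target_spec()].
#' @return An object of class `running_summary`.
#' @export
new_running_summary <- function(target) {
  structure(list(
    target = target,
    n = 0L,
    first_day = NA_real_, first_value = NA_real_,
    last_day = NA_real_, last_value = NA_real_,
    sum = 0, sum_sq = 0,
    auc = 0, abn_auc = 0,
    fu_days_not_at_goal = 0, num_not_at_goal = 0L,
    sum_abs_consec_diff = 0,
    lag_buffer = numeric(),      # up to 3 values preceding the current one
    last_abnormal = FALSE,
    cluster_start = NA_real_, cluster_last = NA_real_, cluster_count = 0L,
    num_clust = 0L,
    max_clust_days = NA_real_    # over clusters with count >= 2, incl. open
  ), class = "running_summary")
}

#' @export
print.running_summary <- function(x, ...) {
  cat(sprintf("<running_summary> %s: n=%d", x$target$cm_name, x$n))
  if (x$n > 0)
    cat(sprintf(", days %s..%s, last value %s, clusters %d",
                format(x$first_day), format(x$last_day),
                format(x$last_value), x$num_clust))
  cat("\n")
  invisible(x)
}

#' Advance a running summary with one new reading
#'
#' Appends one reading (readings must arrive in day order) and updates every
#' accumulator: sums for the grand mean and standard deviation, trapezoidal
#' areas, not-at-goal day and reading counts, the lag buffer, and the
#' cluster state machine (normal to abnormal opens a cluster, abnormal to
#' abnormal extends it, abnormal to normal closes it).
#'
#' @param rs A `running_summary`.
#' @param day Whole-numbered day of the new reading.
#' @param value Finite value of the new reading.
#' @return The advanced `running_summary`.
#' @export
update_summary <- function(rs, day, value) {
  stopifnot(inherits(rs, "running_summary"), is.finite(value))
  if (rs$n > 0L && day <= rs$last_day)
    stop("update_summary: out-of-order append (day ", day,
         " after ", rs$last_day, "); upstream sorting bug")
  a <- is_abnormal(value, rs$target)
  if (rs$n == 0L) {
    rs$first_day <- day; rs$first_value <- value
  } else {
    span <- day - rs$last_day
    rs$auc <- rs$auc + (rs$last_value + value) / 2 * span
    e_prev <- excess(rs$last_value, rs$target)
    e_new <- excess(value, rs$target)
    rs$abn_auc <- rs$abn_auc + (e_prev + e_new) / 2 * span
    if (rs$last_abnormal && a)
      rs$fu_days_not_at_goal <- rs$fu_days_not_at_goal + span
    rs$sum_abs_consec_diff <- rs$sum_abs_consec_diff + abs(value - rs$last_value)
    rs$lag_buffer <- tail(c(rs$lag_buffer, rs$last_value), 3)
  }
  # cluster transitions
  if (a) {
    if (rs$last_abnormal && rs$n > 0L) {
      rs$cluster_last <- day
      rs$cluster_count <- rs$cluster_count + 1L
    } else {
      rs$cluster_start <- day
      rs$cluster_last <- day
      rs$cluster_count <- 1L
      rs$num_clust <- rs$num_clust + 1L
    }
    if (rs$cluster_count >= 2L) {
      dur <- rs$cluster_last - rs$cluster_start
      if (is.na(rs$max_clust_days) || dur > rs$max_clust_days)
        rs$max_clust_days <- dur
    }
    rs$num_not_at_goal <- rs$num_not_at_goal + 1L
  } else if (rs$last_abnormal) {
    # cluster closed; its duration is already folded into max_clust_days
    rs$cluster_start <- NA_real_; rs$cluster_last <- NA_real_
    rs$cluster_count <- 0L
  }
  rs$last_abnormal <- a
  rs$n <- rs$n + 1L
  rs$last_day <- day
  rs$last_value <- value
  rs$sum <- rs$sum + value
  rs$sum_sq <- rs$sum_sq + value * value
  rs
}

#' Read the 13-parameter vector off a running summary
#'
#' Applies every missingness rule: area- and dispersion-based parameters need
#' at least 2 readings, `lag3_dev` needs 3 lagging values, the open-cluster
#' refractoriness fields are missing unless the most recent reading is
#' abnormal, and `max_clust_days` is missing without a 2+-reading cluster.
#' With no readings at all, every field is missing.
#'
#' @param rs A `running_summary`.
#' @param mode Time-weighted-average mode, `"full"` or `"abnormal"` (see
#'   [compute_time_wt_avg()]).
#' @return Named list of the 13 parameters, class `cm_parameters`.
#' @export
finalize_summary <- function(rs, mode = c("full", "abnormal")) {
  mode <- match.arg(mode)
  n <- rs$n
  p <- empty_parameters()
  if (n == 0L) return(p)
  p$Value1 <- rs$last_value
  p$FUDaysNotAtGoal <- rs$fu_days_not_at_goal
  p$NumNotAtGoal <- rs$num_not_at_goal
  if (n >= 2L) {
    p$AbnAUC <- rs$abn_auc
    span <- rs$last_day - rs$first_day
    if (span > 0)
      p$TimeWtAvg <- (if (mode == "full") rs$auc else rs$abn_auc) / span
    mean_v <- rs$sum / n
    var_v <- (rs$sum_sq - n * mean_v^2) / (n - 1)
    if (mean_v != 0) p$CoeffVar <- sqrt(max(var_v, 0)) / mean_v
    p$MeanValDiff <- rs$sum_abs_consec_diff / (n - 1)
  }
  if (rs$last_abnormal) {
    p$TimeNotAtGoal <- rs$cluster_last - rs$cluster_start
    p$CtNotAtGoal <- rs$cluster_count
  }
  p$MaxClustDays <- rs$max_clust_days
  p$NumClust <- rs$num_clust
  p$NetChange <- rs$last_value - rs$first_value
  if (n >= 4L) {
    l3 <- mean(rs$lag_buffer)
    if (l3 != 0) p$Lag3Dev <- (rs$last_value - l3) / l3
  }
  p
}

empty_parameters <- function() {
  structure(list(
    Value1 = NA_real_,
    FUDaysNotAtGoal = NA_real_, NumNotAtGoal = NA_integer_,
    AbnAUC = NA_real_, TimeWtAvg = NA_real_,
    TimeNotAtGoal = NA_real_, CtNotAtGoal = NA_integer_,
    MaxClustDays = NA_real_,
    NumClust = NA_integer_,
    CoeffVar = NA_real_, MeanValDiff = NA_real_,
    NetChange = NA_real_, Lag3Dev = NA_real_
  ), class = "cm_parameters")
}

#' @export
print.cm_parameters <- function(x, ...) {
  cat("<cm_parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' Derive the 13 parameters from a full series in one pass
#'
#' Batch counterpart of the running-summary path: recomputes every parameter
#' directly from the complete sorted series. The two paths agree exactly on
#' counts and day totals and to 1e-9 relative tolerance on real-valued
#' parameters; the batch path doubles as the reference oracle for the
#' incremental one.
#'
#' @param series A [cm_series()].
#' @param target A [target_spec()].
#' @param mode Time-weighted-average mode (see [compute_time_wt_avg()]).
#' @return Named list of the 13 parameters, class `cm_parameters`.
#' @examples
#' s <- cm_series(1, "SBP", c(0, 10, 20, 30), c(130, 150, 160, 135))
#' batch_derive(s, target_spec("SBP", high = 140))
#' @export
batch_derive <- function(series, target, mode = c("full", "abnormal")) {
  mode <- match.arg(mode)
  n <- length(series$day)
  p <- empty_parameters()
  if (n == 0L) return(p)
  v <- series$value
  p$Value1 <- v[n]
  chron <- compute_chronicity(series, target)
  p$FUDaysNotAtGoal <- chron$fu_days_not_at_goal
  p$NumNotAtGoal <- as.integer(chron$num_not_at_goal)
  if (n >= 2L) {
    p$AbnAUC <- compute_abn_auc(series, target)
    p$TimeWtAvg <- compute_time_wt_avg(series, target, mode)
  }
  clusters <- detect_clusters(series, target)
  refr <- compute_refractoriness(clusters,
                                 is_abnormal(v[n], target))
  p$TimeNotAtGoal <- refr$time_not_at_goal
  p$CtNotAtGoal <- refr$ct_not_at_goal
  p$MaxClustDays <- refr$max_clust_days
  p$NumClust <- nrow(clusters)
  lab <- compute_lability(series)
  p$CoeffVar <- lab$coeff_var
  p$MeanValDiff <- lab$mean_val_diff
  tr <- compute_trends(series)
  p$NetChange <- tr$net_change
  p$Lag3Dev <- tr$lag3_dev
  p
}
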