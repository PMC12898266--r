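# Synthetic EHR cohort generator: irregular visit times whose intensity
# increases while the latent measurement is abnormal, per-measurement
# missingness, and a binary 60-day mortality outcome driven by a known
# logistic model on the engine's own derived parameters.

#' Latent trajectory model for one measurement
#'
#' Each patient's latent curve is a patient-specific baseline plus a linear
#' drift (per year, signed toward the abnormal side for positive disease
#' progression) plus transient relapse excursions: a Poisson process of
#' episodes, each shifting the latent value toward abnormality by a random
#' magnitude for an exponentially distributed duration. Observed readings
#' add Gaussian measurement noise.
#'
#' @param cm_name Measurement code.
#' @param base_mean,base_sd Baseline distribution across patients (native
#'   units).
#' @param drift_mean,drift_sd Linear drift distribution (units per year).
#' @param noise_sd Measurement noise standard deviation.
#' @param relapse_rate Excursion rate (episodes per year).
#' @param relapse_mag_mean,relapse_mag_sd Excursion magnitude distribution
#'   (units; applied toward the abnormal side).
#' @param relapse_dur_mean Mean excursion duration (days).
#' @param direction `+1` when abnormal means high (e.g. SBP), `-1` when
#'   abnormal means low (e.g. O2Sat).
#' @return A `trajectory_model` list.
#' @export
trajectory_model <- function(cm_name, base_mean, base_sd, drift_mean,
                             drift_sd, noise_sd, relapse_rate,
                             relapse_mag_mean, relapse_mag_sd,
                             relapse_dur_mean, direction) {
  stopifnot(base_sd >= 0, drift_sd >= 0, noise_sd >= 0, relapse_rate >= 0,
            relapse_mag_sd >= 0, relapse_dur_mean > 0,
            direction %in% c(-1, 1))
  structure(list(cm_name = cm_name, base_mean = base_mean, base_sd = base_sd,
                 drift_mean = drift_mean, drift_sd = drift_sd,
                 noise_sd = noise_sd, relapse_rate = relapse_rate,
                 relapse_mag_mean = relapse_mag_mean,
                 relapse_mag_sd = relapse_mag_sd,
                 relapse_dur_mean = relapse_dur_mean,
                 direction = direction),
            class = "trajectory_model")
}

#' Visit process model
#'
#' Visits are an inhomogeneous Poisson process: `base_rate` per year while
#' the latent value is at goal, multiplied by `abnormal_mult` while it is
#' abnormal (clinicians remeasure what worries them — the sampling bias the
#' time-weighted average corrects). Follow-up length is uniform on
#' `fu_years_range`.
#'
#' @param base_rate Visits per year while at goal (> 0).
#' @param abnormal_mult Intensity multiplier while abnormal (>= 1).
#' @param fu_years_range Length-2 range of follow-up in years.
#' @return A `visit_model` list.
#' @export
visit_model <- function(base_rate = 1.5, abnormal_mult = 2.5,
                        fu_years_range = c(4, 10)) {
  stopifnot(base_rate > 0, abnormal_mult >= 1, length(fu_years_range) == 2,
            fu_years_range[1] > 0, diff(fu_years_range) >= 0)
  structure(list(base_rate = base_rate, abnormal_mult = abnormal_mult,
                 fu_years_range = fu_years_range), class = "visit_model")
}

#' Outcome model on derived parameters
#'
#' The 60-day mortality indicator is Bernoulli with logit equal to
#' `intercept` plus a linear combination of standardized derived parameters
#' (z = (x - center) / scale with the scenario's fixed centers and scales;
#' patients missing a parameter contribute 0 for that term, i.e. the
#' centered mean) plus optional age and comorbidity-score effects.
#'
#' @param intercept Log-odds intercept.
#' @param coefs Named numeric vector of log-odds per standardized unit;
#'   names are `<CM><Parameter>` candidate columns.
#' @param centers,scales Named numeric vectors (same names as `coefs`) used
#'   for standardization.
#' @param age_coef Log-odds per year of age (default 0).
#' @param comorbid_coefs Named log-odds per score point for `charl_2yr`,
#'   `charl_ever`, `elix_2yr`, `elix_ever` (default all 0).
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(intercept, coefs = numeric(),
                          centers = numeric(), scales = numeric(),
                          age_coef = 0,
                          comorbid_coefs = c(charl_2yr = 0, charl_ever = 0,
                                             elix_2yr = 0, elix_ever = 0)) {
  if (length(coefs)) {
    stopifnot(!is.null(names(coefs)),
              all(names(coefs) %in% candidate_column_names()),
              all(names(coefs) %in% names(centers)),
              all(names(coefs) %in% names(scales)),
              all(scales[names(coefs)] > 0))
  }
  structure(list(intercept = intercept, coefs = coefs, centers = centers,
                 scales = scales, age_coef = age_coef,
                 comorbid_coefs = comorbid_coefs),
            class = "outcome_model")
}

#' Default simulation scenario
#'
#' Emulates a high-burden chronic-disease cohort: every measurement drifts
#' toward its abnormal side over a 4-12 year follow-up, with relapse
#' excursions and abnormality-intensified visits, so that the complete-case
#' fraction over all 143 candidate columns is substantial (the open-cluster
#' refractoriness parameters are only observed for patients abnormal at the
#' most recent reading). Six parameters spread over six attributes carry
#' outcome signal: O2SatValue1 (-), SBPTimeWtAvg (+), A1cNumClust (+),
#' eGFRNetChange (-), HCTCoeffVar (+) and AlbFUDaysNotAtGoal (+), on
#' standardized scales, with a marginal 60-day death rate of roughly 8%.
#' Centers and scales are fixed scenario constants (calibrated once against
#' this generator's defaults), so the implied raw-scale coefficients are
#' known exactly; see [true_raw_coefficients()].
#'
#' @param missing_cm_prob Probability a patient's series for a measurement
#'   is entirely absent (independently per measurement); default 0.02.
#' @return A `sim_scenario` list with `trajectories`, `visit`, `outcome`,
#'   `missing_cm_prob`.
#' @export
default_scenario <- function(missing_cm_prob = 0.02) {
  traj <- list(
    SBP   = trajectory_model("SBP",   133, 8,    4.0,  1.2, 7,    0.30, 18, 6,   180, +1),
    DBP   = trajectory_model("DBP",    84, 5,    3.0,  0.8, 5,    0.25, 12, 4,   150, +1),
    O2Sat = trajectory_model("O2Sat", 95.3, 0.9, -0.60, 0.25, 0.9, 0.20, 2.5, 1.0, 120, -1),
    BMI   = trajectory_model("BMI",   29.5, 2.5,  0.60, 0.15, 1.0, 0.15, 2.5, 1.0, 240, +1),
    eGFR  = trajectory_model("eGFR",   64, 8,   -3.2,  1.2, 6,    0.25, 12, 4,   180, -1),
    Alb   = trajectory_model("Alb",   3.55, 0.25, -0.09, 0.03, 0.25, 0.20, 0.5, 0.2, 150, -1),
    HCT   = trajectory_model("HCT",   39.5, 2.5, -0.90, 0.30, 1.8, 0.25, 4, 1.5, 150, -1),
    ALT   = trajectory_model("ALT",    38, 8,    2.5,  1.0, 7,    0.30, 25, 8,   120, +1),
    A1c   = trajectory_model("A1c",   7.0, 0.6,  0.22, 0.08, 0.5, 0.50, 1.2, 0.4, 150, +1),
    HDL   = trajectory_model("HDL",    40, 5,   -1.2,  0.5, 4,    0.20, 8, 3,    180, -1),
    LDL   = trajectory_model("LDL",   128, 15,   6.0,  2.0, 12,   0.25, 35, 12,  150, +1)
  )
  coefs <- c(O2SatValue1 = -0.60, SBPTimeWtAvg = 0.80, A1cNumClust = 0.40,
             eGFRNetChange = -0.40, HCTCoeffVar = 0.45,
             AlbFUDaysNotAtGoal = 0.60)
  centers <- c(O2SatValue1 = 91.1, SBPTimeWtAvg = 150, A1cNumClust = 2.4,
               eGFRNetChange = -20, HCTCoeffVar = 0.081,
               AlbFUDaysNotAtGoal = 1500)
  scales <- c(O2SatValue1 = 2.5, SBPTimeWtAvg = 10, A1cNumClust = 1.5,
              eGFRNetChange = 14, HCTCoeffVar = 0.027,
              AlbFUDaysNotAtGoal = 900)
  structure(list(
    trajectories = traj,
    visit = visit_model(),
    outcome = outcome_model(intercept = qlogis(0.055), coefs = coefs,
                            centers = centers, scales = scales),
    missing_cm_prob = missing_cm_prob
  ), class = "sim_scenario")
}

#' Null scenario: outcome independent of every parameter
#'
#' Same longitudinal structure as [default_scenario()], with all outcome
#' coefficients zero and an intercept giving a 5.44% marginal death rate.
#'
#' @inheritParams default_scenario
#' @return A `sim_scenario`.
#' @export
null_scenario <- function(missing_cm_prob = 0.02) {
  sc <- default_scenario(missing_cm_prob)
  sc$outcome <- outcome_model(intercept = qlogis(0.0544))
  sc
}

#' Raw-scale true coefficients implied by a scenario
#'
#' The outcome model applies its coefficients to standardized parameters
#' z = (x - center)/scale; on the raw parameter scale the same model has
#' slope coef/scale and intercept `intercept - sum(coef * center / scale)`.
#' These are the values a correctly specified logistic fit on the raw
#' candidate columns estimates.
#'
#' @param scenario A `sim_scenario`.
#' @return List with `intercept` and named vector `coefs` (raw scale).
#' @export
true_raw_coefficients <- function(scenario) {
  om <- scenario$outcome
  if (!length(om$coefs))
    return(list(intercept = om$intercept, coefs = numeric()))
  nm <- names(om$coefs)
  raw <- om$coefs / om$scales[nm]
  list(intercept = om$intercept - sum(om$coefs * om$centers[nm] / om$scales[nm]),
       coefs = setNames(as.numeric(raw), nm))
}

split_candidate_name <- function(name) {
  for (p in parameter_names()) {
    hit <- endsWith(name, p)
    cm <- substr(name, 1, nchar(name) - nchar(p))
    if (any(hit & cm %in% cm_codes()))
      return(list(cm = cm[hit & cm %in% cm_codes()][1], param = p))
  }
  stop("not a candidate column name: ", name)
}

#' Simulate a synthetic cohort
#'
#' Generates patients with irregular, abnormality-intensified visit times
#' for each measurement, derives the true 13-parameter vectors with the
#' package's own engine, and draws the 60-day mortality outcome from the
#' scenario's logistic model on those parameters. Comorbidity scores are
#' Poisson draws whose rate grows with the patient's true metabolic burden,
#' so the baseline comparator models have realistic (but not
#' outcome-defining) signal. Fully reproducible for a given seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param scenario A `sim_scenario`, e.g. [default_scenario()].
#' @param seed Integer seed.
#' @param keep_trace Keep the generator's internal trace (excursion log and
#'   per-series candidate/accepted visit counts split by latent abnormality)
#'   in the result's `truth`? Default `FALSE`.
#' @return An object of class `synthetic_cohort`: list with
#'   \describe{
#'     \item{patients}{`data.table`: `patient_id`, `age`, `charl_2yr`,
#'       `charl_ever`, `elix_2yr`, `elix_ever`, `index_day`, `death60`.}
#'     \item{measurements}{long `data.table`: `patient_id`, `cm_name`,
#'       `day`, `value`, sorted, ending >= 14 days before `index_day`.}
#'     \item{truth}{list: `parameter_table` (the engine's parameter vectors
#'       the outcome was drawn from), `lp` and `p_death` per patient, the
#'       `scenario`, and optionally `trace`.}
#'   }
#' @export
simulate_cohort <- function(n_patients, scenario = default_scenario(),
                            seed = 1L, keep_trace = FALSE) {
  stopifnot(n_patients >= 1, inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  vm <- scenario$visit
  n <- as.integer(n_patients)
  pid <- sprintf("P%06d", seq_len(n))
  age <- pmin(pmax(round(rnorm(n, 62, 14)), 20), 100)
  fu_years <- runif(n, vm$fu_years_range[1], vm$fu_years_range[2])
  fu_days <- round(fu_years * 365)
  if (any(fu_days <= 0)) stop("degenerate follow-up configuration")
  index_day <- fu_days + 14L

  lam_max <- vm$base_rate * vm$abnormal_mult / 365   # per day
  mult <- vm$abnormal_mult

  series_list <- vector("list", length(scenario$trajectories))
  trace_list <- if (keep_trace) vector("list", length(series_list))
  exc_list <- if (keep_trace) vector("list", length(series_list))

  for (ci in seq_along(scenario$trajectories)) {
    tm <- scenario$trajectories[[ci]]
    lo <- -Inf; hi <- Inf
    # abnormality of the *latent* value uses the same default target bounds
    tgt <- default_targets()[[tm$cm_name]]
    if (!is.null(tgt)) {
      if (!is.na(tgt$low)) lo <- tgt$low
      if (!is.na(tgt$high)) hi <- tgt$high
    }
    b <- rnorm(n, tm$base_mean, tm$base_sd)
    s <- rnorm(n, tm$drift_mean, tm$drift_sd)
    k <- rpois(n, tm$relapse_rate * fu_years)
    kmax <- max(k, 0L)
    ex_start <- ex_end <- ex_mag <- NULL
    if (kmax > 0) {
      tot <- sum(k)
      epid <- rep.int(seq_len(n), k)
      est <- runif(tot) * fu_days[epid]
      edur <- rexp(tot, 1 / tm$relapse_dur_mean)
      emag <- abs(rnorm(tot, tm$relapse_mag_mean, tm$relapse_mag_sd)) *
        tm$direction
      # k-th excursion per patient, as aligned per-patient columns
      kk <- sequence(k)
      ex_start <- ex_end <- ex_mag <- matrix(NA_real_, n, kmax)
      ex_start[cbind(epid, kk)] <- est
      ex_end[cbind(epid, kk)] <- est + edur
      ex_mag[cbind(epid, kk)] <- emag
    }
    m <- rpois(n, lam_max * fu_days)
    cpid <- rep.int(seq_len(n), m)
    t <- runif(sum(m)) * fu_days[cpid]
    latent <- b[cpid] + s[cpid] * t / 365
    if (kmax > 0) {
      for (j in seq_len(kmax)) {
        stj <- ex_start[, j][cpid]
        inwin <- !is.na(stj) & t >= stj & t < ex_end[, j][cpid]
        if (any(inwin))
          latent[inwin] <- latent[inwin] + ex_mag[, j][cpid][inwin]
      }
    }
    abn_lat <- latent < lo | latent > hi
    accept <- runif(length(t)) < (1 + (mult - 1) * abn_lat) / mult
    missing_series <- runif(n) < scenario$missing_cm_prob
    keep <- accept & !missing_series[cpid]
    sdt <- data.table(pidx = cpid[keep], day = floor(t[keep]),
                      value = latent[keep] + rnorm(sum(keep), 0, tm$noise_sd))
    setorder(sdt, pidx, day)
    nsd <- nrow(sdt)
    if (nsd > 1) {
      same <- sdt$pidx[-1] == sdt$pidx[-nsd] & sdt$day[-1] == sdt$day[-nsd]
      if (any(same)) sdt <- sdt[!c(same, FALSE)]   # keep last of same-day run
    }
    sdt[, cmi := ci]
    series_list[[ci]] <- sdt
    if (keep_trace) {
      tr <- data.table(pidx = cpid, abn = abn_lat, acc = accept)
      tr <- tr[, .(cand_abn = sum(abn), cand_norm = sum(!abn),
                   acc_abn = sum(abn & acc), acc_norm = sum(!abn & acc)),
               by = pidx]
      tr[, cm_name := tm$cm_name]
      trace_list[[ci]] <- tr
      if (kmax > 0) {
        exdt <- data.table(pidx = epid, start = est, end = est + edur,
                           mag = emag, cm_name = tm$cm_name)
        exdt <- exdt[!missing_series[pidx]]
        exc_list[[ci]] <- exdt
      }
    }
  }

  mi <- rbindlist(series_list)
  if (!nrow(mi))
    stop("simulate_cohort: no readings generated (degenerate configuration)")
  setorder(mi, pidx, cmi, day)          # integer keys: fast radix sort
  cms <- names(scenario$trajectories)
  nr <- nrow(mi)
  new_grp <- c(TRUE, mi$pidx[-1] != mi$pidx[-nr] | mi$cmi[-1] != mi$cmi[-nr])
  tgl <- default_targets()
  lo_by_cm <- vapply(cms, function(x)
    if (!is.null(tgl[[x]]) && !is.na(tgl[[x]]$low)) tgl[[x]]$low else -Inf,
    numeric(1))
  hi_by_cm <- vapply(cms, function(x)
    if (!is.null(tgl[[x]]) && !is.na(tgl[[x]]$high)) tgl[[x]]$high else Inf,
    numeric(1))
  core <- derive_params_core(as.numeric(mi$day), mi$value, new_grp,
                             lo_by_cm[mi$cmi], hi_by_cm[mi$cmi], "full")
  starts <- which(new_grp)
  params <- cbind(data.table(patient_id = pid[mi$pidx[starts]],
                             cm_name = cms[mi$cmi[starts]]), core)
  meas <- mi[, .(patient_id = pid[pidx], cm_name = cms[cmi],
                 day = as.numeric(day), value)]

  # linear predictor from the TRUE derived parameters
  om <- scenario$outcome
  lp_cm <- rep(om$intercept, n)
  names(lp_cm) <- pid
  if (length(om$coefs)) {
    for (nm in names(om$coefs)) {
      sp <- split_candidate_name(nm)
      x <- params[cm_name == sp$cm,
                  setNames(get(sp$param), patient_id)]
      z <- (x - om$centers[nm]) / om$scales[nm]
      z[is.na(z)] <- 0
      contrib <- setNames(rep(0, n), pid)
      contrib[names(z)] <- z
      lp_cm <- lp_cm + om$coefs[nm] * contrib
    }
  }
  burden <- lp_cm - om$intercept
  charl_2yr <- rpois(n, exp(0.2 + 0.4 * burden))
  charl_ever <- charl_2yr + rpois(n, 0.8)
  elix_2yr <- rpois(n, exp(0.4 + 0.3 * burden))
  elix_ever <- elix_2yr + rpois(n, 1.2)

  lp <- lp_cm + om$age_coef * age +
    om$comorbid_coefs["charl_2yr"] * charl_2yr +
    om$comorbid_coefs["charl_ever"] * charl_ever +
    om$comorbid_coefs["elix_2yr"] * elix_2yr +
    om$comorbid_coefs["elix_ever"] * elix_ever
  p_death <- plogis(unname(lp))
  death60 <- rbinom(n, 1L, p_death)

  patients <- data.table(patient_id = pid, age = as.numeric(age),
                         charl_2yr = charl_2yr, charl_ever = charl_ever,
                         elix_2yr = elix_2yr, elix_ever = elix_ever,
                         index_day = index_day, death60 = death60)
  truth <- list(parameter_table = params,
                lp = data.table(patient_id = pid, lp = unname(lp),
                                p_death = p_death),
                scenario = scenario)
  if (keep_trace) {
    tr <- rbindlist(trace_list)
    tr[, patient_id := pid[pidx]]
    truth$trace <- tr[, .(patient_id, cm_name, cand_abn, cand_norm,
                          acc_abn, acc_norm)]
    exs <- exc_list[!vapply(exc_list, is.null, TRUE)]
    if (length(exs)) {
      ex <- rbindlist(exs)
      ex[, patient_id := pid[pidx]]
      truth$excursions <- ex[, .(patient_id, cm_name, start, end, mag)]
    } else {
      truth$excursions <- data.table(patient_id = character(),
                                     cm_name = character(), start = numeric(),
                                     end = numeric(), mag = numeric())
    }
  }
  structure(list(patients = patients, measurements = meas, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d readings over %d measurements, %.1f%% died\n",
    nrow(x$patients), nrow(x$measurements),
    length(unique(x$measurements$cm_name)),
    100 * mean(x$patients$death60)))
  invisible(x)
}

#' True parameter vectors for one simulated patient
#'
#' Reads the ground-truth parameter vectors (computed by the engine on the
#' generated series, the same values that drove the outcome draw) for one
#' patient.
#'
#' @param cohort A `synthetic_cohort`.
#' @param patient_id One patient identifier.
#' @return Named list of `cm_parameters`, one per measurement the patient
#'   has.
#' @export
oracle_parameters <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tab <- cohort$truth$parameter_table[cohort$truth$parameter_table$patient_id ==
                                        patient_id]
  if (!nrow(tab)) stop("unknown patient: ", patient_id)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    p <- empty_parameters()
    for (nm in parameter_names()) p[[nm]] <- tab[[nm]][i]
    p
  })
  names(out) <- tab$cm_name
  out
}
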