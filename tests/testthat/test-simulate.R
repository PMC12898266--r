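# Synthetic cohort generator: determinism, outcome link, visit
# intensification, missingness, and agreement with the generator's own
# excursion log.

test_that("simulation is reproducible for a fixed seed", {
  a <- simulate_cohort(100, default_scenario(), seed = 7)
  b <- simulate_cohort(100, default_scenario(), seed = 7)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$patients, b$patients)
  c <- simulate_cohort(100, default_scenario(), seed = 8)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("series are sorted, deduplicated and end before the blackout", {
  co <- simulate_cohort(150, default_scenario(), seed = 42)
  m <- co$measurements
  key <- paste(m$patient_id, m$cm_name)
  # within every series, days strictly increase (sorted, deduplicated)
  same_series <- key[-1] == key[-length(key)]
  expect_true(all(diff(m$day)[same_series] > 0))
  idx <- co$patients$index_day[match(m$patient_id, co$patients$patient_id)]
  expect_true(all(m$day <= idx - 14))
})

test_that("with zero coefficients the death rate follows the intercept", {
  sc <- null_scenario()
  sc$outcome <- outcome_model(intercept = qlogis(0.05))
  co <- simulate_cohort(20000, sc, seed = 123)
  rate <- mean(co$patients$death60)
  se <- sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("visit intensity scales with the abnormal multiplier", {
  sc <- default_scenario()
  sc$visit <- visit_model(base_rate = 2, abnormal_mult = 3)
  co <- simulate_cohort(400, sc, seed = 9, keep_trace = TRUE)
  tr <- co$truth$trace
  # candidate times are uniform at the max rate, so candidate counts estimate
  # person-time in each latent state; acceptance fractions give the rates
  rate_ratio <- (sum(tr$acc_abn) / sum(tr$cand_abn)) /
    (sum(tr$acc_norm) / sum(tr$cand_norm))
  expect_lt(abs(rate_ratio - 3), 0.25)

  sc$visit <- visit_model(base_rate = 2, abnormal_mult = 1)
  co1 <- simulate_cohort(400, sc, seed = 9, keep_trace = TRUE)
  tr1 <- co1$truth$trace
  ratio1 <- (sum(tr1$acc_abn) / sum(tr1$cand_abn)) /
    (sum(tr1$acc_norm) / sum(tr1$cand_norm))
  expect_lt(abs(ratio1 - 1), 0.05)
})

test_that("per-measurement missingness compounds across the 11 CMs", {
  p_miss <- 0.15
  co <- simulate_cohort(2000, default_scenario(missing_cm_prob = p_miss),
                        seed = 31)
  n_cms <- co$measurements[, data.table::uniqueN(cm_name), by = patient_id]
  frac_any_missing <- mean(n_cms$V1 < 11) +
    (2000 - nrow(n_cms)) / 2000          # patients with no series at all
  expected <- 1 - (1 - p_miss)^11
  expect_lt(abs(frac_any_missing - expected), 0.03)
})

test_that("oracle parameters inherit the engine's invariants", {
  co <- simulate_cohort(50, default_scenario(), seed = 77)
  for (pid in co$patients$patient_id[1:10]) {
    op <- oracle_parameters(co, pid)
    for (p in op) {
      expect_length(unclass(p), 13)
      expect_lte(p$NumClust, p$NumNotAtGoal)
      if (!is.na(p$MaxClustDays))
        expect_lte(p$MaxClustDays, p$FUDaysNotAtGoal)
      if (!is.na(p$TimeWtAvg)) {
        expect_gte(p$AbnAUC, 0)
      }
    }
  }
})

test_that("cluster counts are bounded by the generated excursion count", {
  # a quiescent trajectory (no drift, baseline far inside the target) whose
  # only abnormality source is the excursion process: every cluster then
  # falls inside an excursion window, so NumClust <= #excursions
  sc <- default_scenario()
  sc$trajectories <- list(
    SBP = trajectory_model("SBP", base_mean = 115, base_sd = 3,
                           drift_mean = 0, drift_sd = 0, noise_sd = 2,
                           relapse_rate = 0.4, relapse_mag_mean = 45,
                           relapse_mag_sd = 3, relapse_dur_mean = 120,
                           direction = +1))
  sc$outcome <- outcome_model(intercept = qlogis(0.05))
  sc$missing_cm_prob <- 0
  co <- simulate_cohort(300, sc, seed = 55, keep_trace = TRUE)
  exc_n <- co$truth$excursions[, .N, by = patient_id]
  pt <- co$truth$parameter_table
  k <- exc_n$N[match(pt$patient_id, exc_n$patient_id)]
  k[is.na(k)] <- 0
  expect_true(all(pt$NumClust <= k))
  expect_true(all(pt$NumClust[k == 0] == 0))
})

test_that("abnormality-driven oversampling biases the raw mean, not TimeWtAvg", {
  co <- simulate_cohort(600, default_scenario(), seed = 2024)
  m <- data.table::as.data.table(co$measurements)
  raw <- m[, .(raw_mean = mean(value), n = .N), by = .(patient_id, cm_name)]
  pt <- co$truth$parameter_table[, .(patient_id, cm_name, TimeWtAvg)]
  j <- pt[raw, on = c("patient_id", "cm_name")]
  j <- j[!is.na(TimeWtAvg) & n >= 4]
  dir <- c(SBP = 1, DBP = 1, O2Sat = -1, BMI = 1, eGFR = -1, Alb = -1,
           HCT = -1, ALT = 1, A1c = 1, HDL = -1, LDL = 1)
  bias <- dir[j$cm_name] * (j$raw_mean - j$TimeWtAvg)
  expect_gt(median(bias), 0)
})

test_that("outcome models reject coefficients outside the candidate set", {
  expect_error(outcome_model(0, coefs = c(NotAColumn = 1),
                             centers = c(NotAColumn = 0),
                             scales = c(NotAColumn = 1)))
  expect_silent(outcome_model(0, coefs = c(SBPValue1 = 0.2),
                              centers = c(SBPValue1 = 140),
                              scales = c(SBPValue1 = 10)))
})

test_that("raw-scale coefficients match the standardized outcome model", {
  sc <- default_scenario()
  tr <- true_raw_coefficients(sc)
  om <- sc$outcome
  nm <- names(om$coefs)
  expect_equal(tr$coefs, setNames(as.numeric(om$coefs / om$scales[nm]), nm))
  # the two parameterizations give the same linear predictor for any x
  x <- om$centers[nm] + 1.7 * om$scales[nm]
  lp_std <- om$intercept + sum(om$coefs * 1.7)
  lp_raw <- tr$intercept + sum(tr$coefs * x)
  expect_equal(lp_std, lp_raw, tolerance = 1e-12)
})
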