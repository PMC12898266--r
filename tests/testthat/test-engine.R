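# Parameter engine: per-operation oracles, missingness rules, and the
# incremental/batch/table equivalence contracts.

test_that("trapezoidal areas and time-weighted average match hand oracles", {
  s <- worked_series()
  tg <- worked_target()
  expect_equal(compute_auc(s), 4425)              # 1400 + 1550 + 1475
  expect_equal(compute_abn_auc(s, tg), 300)       # 50 + 150 + 100
  expect_equal(compute_time_wt_avg(s), 147.5)     # 4425 / 30

  # rectangle: constant series integrates to c * T
  const <- cm_series("P1", "SBP", c(0, 35), c(120, 120))
  expect_equal(compute_auc(const), 120 * 35)
  expect_equal(compute_time_wt_avg(const), 120)

  # linear segment: midpoint
  lin <- cm_series("P1", "SBP", c(0, 10), c(100, 200))
  expect_equal(compute_time_wt_avg(lin), 150)

  # all-at-goal series has zero abnormal area
  expect_equal(compute_abn_auc(const, tg), 0)
  # constant excess 10 over 10 days
  exc <- cm_series("P1", "SBP", c(0, 10), c(150, 150))
  expect_equal(compute_abn_auc(exc, tg), 100)

  single <- cm_series("P1", "SBP", 0, 130)
  expect_true(is.na(compute_auc(single)))
  expect_true(is.na(compute_abn_auc(single, tg)))
  expect_true(is.na(compute_time_wt_avg(single)))
})

test_that("abnormal-AUC mode divides the excess area by follow-up", {
  s <- worked_series()
  expect_equal(compute_time_wt_avg(s, worked_target(), mode = "abnormal"),
               300 / 30)
})

test_that("chronicity counts only abnormal-to-abnormal spans and abnormal readings", {
  tg <- worked_target()
  expect_equal(compute_chronicity(worked_series(), tg),
               list(fu_days_not_at_goal = 10, num_not_at_goal = 2L))
  allnorm <- cm_series("P1", "SBP", c(0, 10, 30), c(120, 125, 130))
  expect_equal(compute_chronicity(allnorm, tg),
               list(fu_days_not_at_goal = 0, num_not_at_goal = 0L))
  allabn <- cm_series("P1", "SBP", c(0, 10, 30), c(150, 150, 150))
  expect_equal(compute_chronicity(allabn, tg),
               list(fu_days_not_at_goal = 30, num_not_at_goal = 3L))
})

test_that("cluster detection implements the open/closed run rules", {
  tg <- worked_target()
  cl <- detect_clusters(worked_series(), tg)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start_day, 10)
  expect_equal(cl$last_abnormal_day, 20)
  expect_equal(cl$count, 2L)
  expect_equal(cl$duration_days, 10)
  expect_false(cl$open)

  # abnormal first reading opens a cluster; a final abnormal run stays open
  s2 <- cm_series("P1", "SBP", c(0, 10, 20), c(150, 130, 150))
  cl2 <- detect_clusters(s2, tg)
  expect_equal(cl2$count, c(1L, 1L))
  expect_equal(cl2$open, c(FALSE, TRUE))

  expect_equal(nrow(detect_clusters(
    cm_series("P1", "SBP", c(0, 10), c(120, 125)), tg)), 0)
})

test_that("refractoriness fields follow the stated missingness rules", {
  tg <- worked_target()
  # last reading normal: open-cluster fields missing, max over 2+ runs kept
  r <- compute_refractoriness(detect_clusters(worked_series(), tg), FALSE)
  expect_true(is.na(r$time_not_at_goal))
  expect_true(is.na(r$ct_not_at_goal))
  expect_equal(r$max_clust_days, 10)

  # open cluster spanning days 10..25
  s <- cm_series("P1", "SBP", c(0, 10, 25), c(130, 150, 160))
  r2 <- compute_refractoriness(detect_clusters(s, tg), TRUE)
  expect_equal(r2$time_not_at_goal, 15)
  expect_equal(r2$ct_not_at_goal, 2L)
  expect_equal(r2$max_clust_days, 15)

  # only isolated single abnormal readings: everything missing
  s3 <- cm_series("P1", "SBP", c(0, 10, 20), c(150, 130, 150))
  s3 <- truncate_at_index(s3, 10 + 14)   # keep (150, 130): last normal
  r3 <- compute_refractoriness(detect_clusters(s3, tg), FALSE)
  expect_true(all(is.na(unlist(r3))))

  expect_error(compute_refractoriness(
    detect_clusters(worked_series(), tg), TRUE), "engine bug")
})

test_that("lability and trend parameters match hand oracles", {
  s <- worked_series()
  lab <- compute_lability(s)
  expect_equal(lab$coeff_var, 13.768926 / 143.75, tolerance = 1e-6)
  expect_equal(lab$mean_val_diff, (20 + 10 + 25) / 3)
  tr <- compute_trends(s)
  expect_equal(tr$net_change, 5)
  expect_equal(tr$lag3_dev, (135 - 440 / 3) / (440 / 3))

  const <- cm_series("P1", "SBP", c(0, 10, 20, 30), rep(100, 4))
  expect_equal(compute_lability(const), list(coeff_var = 0, mean_val_diff = 0))
  expect_equal(compute_trends(const), list(net_change = 0, lag3_dev = 0))

  single <- cm_series("P1", "SBP", 0, 130)
  expect_true(all(is.na(unlist(compute_lability(single)))))
  expect_equal(compute_trends(single)$net_change, 0)

  three <- cm_series("P1", "SBP", c(0, 10, 20), c(100, 110, 120))
  expect_true(is.na(compute_trends(three)$lag3_dev))
})

test_that("running summary walks the cluster state machine correctly", {
  tg <- worked_target()
  rs <- new_running_summary(tg)
  rs <- update_summary(rs, 0, 130)
  expect_equal(rs$n, 1L)
  expect_equal(rs$last_value, 130)
  expect_equal(rs$num_clust, 0L)

  rs <- update_summary(rs, 10, 150)
  rs <- update_summary(rs, 20, 160)
  expect_equal(rs$cluster_start, 10)
  expect_equal(rs$cluster_last, 20)
  expect_equal(rs$cluster_count, 2L)
  expect_true(rs$last_abnormal)

  rs <- update_summary(rs, 30, 135)
  expect_equal(rs$num_clust, 1L)
  expect_equal(rs$cluster_count, 0L)
  expect_equal(rs$max_clust_days, 10)

  expect_error(update_summary(rs, 25, 130), "out-of-order")
})

test_that("finalize applies every missingness rule at n = 1", {
  tg <- worked_target()
  rs <- update_summary(new_running_summary(tg), 0, 130)
  p <- finalize_summary(rs)
  expect_equal(p$Value1, 130)
  expect_equal(p$NumNotAtGoal, 0L)
  expect_equal(p$NetChange, 0)
  for (f in c("AbnAUC", "TimeWtAvg", "CoeffVar", "MeanValDiff", "Lag3Dev",
              "TimeNotAtGoal", "CtNotAtGoal", "MaxClustDays"))
    expect_true(is.na(p[[f]]), label = f)
  expect_length(unclass(p), 13)
  expect_named(unclass(p), parameter_names())
})

test_that("empty input yields an all-missing vector on both paths", {
  tg <- worked_target()
  p1 <- finalize_summary(new_running_summary(tg))
  p2 <- batch_derive(cm_series("P1", "SBP"), tg)
  expect_true(all(is.na(unlist(p1))))
  expect_true(all(is.na(unlist(p2))))
})

test_that("worked series assembles the full 13-parameter vector", {
  p <- batch_derive(worked_series(), worked_target())
  expect_equal(p$Value1, 135)
  expect_equal(p$FUDaysNotAtGoal, 10)
  expect_equal(p$NumNotAtGoal, 2L)
  expect_equal(p$AbnAUC, 300)
  expect_equal(p$TimeWtAvg, 147.5)
  expect_true(is.na(p$TimeNotAtGoal))
  expect_true(is.na(p$CtNotAtGoal))
  expect_equal(p$MaxClustDays, 10)
  expect_equal(p$NumClust, 1L)
  expect_equal(p$CoeffVar, 0.09578384, tolerance = 1e-7)
  expect_equal(p$MeanValDiff, 18.333333, tolerance = 1e-7)
  expect_equal(p$NetChange, 5)
  expect_equal(p$Lag3Dev, -0.07954545, tolerance = 1e-7)
})

test_that("incremental and batch derivations agree on random series", {
  set.seed(20240901)
  for (i in 1:300) {
    tg <- random_target()
    s <- random_series()
    expect_parameters_equal(incremental_derive(s, tg), batch_derive(s, tg))
  }
})

test_that("table path agrees with batch_derive series by series", {
  set.seed(5150)
  cms <- sprintf("CM%02d", 0:6)
  targets <- lapply(cms, random_target)
  names(targets) <- cms
  rows <- list()
  specs <- list()
  for (i in 1:120) {
    cm <- sample(cms, 1)
    s <- random_series(id = sprintf("P%03d", i), cm = cm)
    specs[[i]] <- list(series = s, target = targets[[cm]])
    rows[[i]] <- data.frame(patient_id = s$patient_id, cm_name = s$cm_name,
                            day = s$day, value = s$value)
  }
  tab <- derive_parameter_table(do.call(rbind, rows), targets)
  for (sp in specs) {
    row <- tab[tab$patient_id == sp$series$patient_id &
                 tab$cm_name == sp$series$cm_name]
    expect_equal(nrow(row), 1)
    got <- as.list(row[, -(1:2)])
    expect_parameters_equal(got, batch_derive(sp$series, sp$target))
  }
})

test_that("collinear insertion leaves AUC-based parameters unchanged", {
  # readings added exactly on the segment between two existing readings move
  # the raw mean but not the trapezoidal area or the time-weighted average
  set.seed(99)
  for (i in 1:40) {
    s <- random_series(n = sample(3:10, 1))
    n <- length(s$day)
    j <- sample(seq_len(n - 1), 1)
    if (s$day[j + 1] - s$day[j] < 2) next
    mid_day <- s$day[j] + sample(seq_len(s$day[j + 1] - s$day[j] - 1), 1)
    f <- (mid_day - s$day[j]) / (s$day[j + 1] - s$day[j])
    mid_val <- s$value[j] + f * (s$value[j + 1] - s$value[j])
    s2 <- cm_series(s$patient_id, s$cm_name, c(s$day, mid_day),
                    c(s$value, mid_val))
    expect_equal(compute_auc(s2), compute_auc(s), tolerance = 1e-12)
    expect_equal(compute_time_wt_avg(s2), compute_time_wt_avg(s),
                 tolerance = 1e-12)
  }
})

test_that("order bounds hold on random series", {
  set.seed(314)
  for (i in 1:100) {
    tg <- random_target()
    s <- random_series(n = sample(2:15, 1))
    p <- batch_derive(s, tg)
    expect_gte(p$TimeWtAvg, min(s$value))
    expect_lte(p$TimeWtAvg, max(s$value))
    expect_gte(p$AbnAUC, 0)
    expect_lte(p$NumClust, p$NumNotAtGoal)
    if (!is.na(p$CtNotAtGoal)) expect_lte(p$CtNotAtGoal, p$NumNotAtGoal)
    if (!is.na(p$MaxClustDays)) expect_lte(p$MaxClustDays, p$FUDaysNotAtGoal)
  }
})

test_that("parameters are scale-equivariant", {
  set.seed(2718)
  for (i in 1:50) {
    s <- random_series(n = sample(2:12, 1))
    tg <- target_spec("SBP", low = 130, high = 150)
    c_ <- runif(1, 0.2, 5)
    s2 <- cm_series(s$patient_id, s$cm_name, s$day, s$value * c_)
    tg2 <- target_spec("SBP", low = 130 * c_, high = 150 * c_)
    p <- batch_derive(s, tg)
    p2 <- batch_derive(s2, tg2)
    for (f in c("Value1", "TimeWtAvg", "MeanValDiff", "NetChange", "AbnAUC"))
      expect_equal(p2[[f]], c_ * p[[f]], tolerance = 1e-9, label = f)
    for (f in c("CoeffVar", "Lag3Dev", "FUDaysNotAtGoal", "NumNotAtGoal",
                "NumClust", "TimeNotAtGoal", "CtNotAtGoal", "MaxClustDays")) {
      if (is.na(p[[f]])) expect_true(is.na(p2[[f]]), label = f)
      else expect_equal(p2[[f]], p[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("a constant at-goal series zeroes every activity parameter", {
  s <- cm_series("P1", "SBP", c(0, 30, 90, 200), rep(120, 4))
  p <- batch_derive(s, worked_target())
  expect_equal(p$FUDaysNotAtGoal, 0)
  expect_equal(p$NumNotAtGoal, 0L)
  expect_equal(p$AbnAUC, 0)
  expect_equal(p$NumClust, 0L)
  expect_equal(p$CoeffVar, 0)
  expect_equal(p$MeanValDiff, 0)
  expect_equal(p$NetChange, 0)
})
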