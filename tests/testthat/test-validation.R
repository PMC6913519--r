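test_that("the split halves cohorts evenly and deterministically", {
  pr <- demo_prepared(5000, 9)
  sp <- split_cohort(pr, seed = 13)
  expect_length(intersect(sp$derivation, sp$validation), 0)
  expect_setequal(c(sp$derivation, sp$validation), pr$subject_id)
  n_cohorts <- length(unique(pr$cohort_id))
  expect_lte(abs(length(sp$derivation) - length(sp$validation)), n_cohorts)
  expect_identical(split_cohort(pr, seed = 13)$derivation, sp$derivation)
  expect_false(identical(split_cohort(pr, seed = 14)$derivation,
                         sp$derivation))
  # per-cohort derivation proportions stay near one half
  der <- pr[pr$subject_id %in% sp$derivation, ]
  for (co in unique(pr$cohort_id)) {
    ntot <- sum(pr$cohort_id == co)
    if (ntot >= 200) {
      frac <- sum(der$cohort_id == co) / ntot
      expect_gte(frac, 0.45)
      expect_lte(frac, 0.55)
    }
  }
  # a singleton cohort lands in the derivation half with a warning
  one <- pr[1:11, ]
  one$cohort_id <- c(rep("big", 10), "solo")
  expect_warning(sp1 <- split_cohort(one, seed = 1), "solo")
  expect_true(one$subject_id[11] %in% sp1$derivation)
})

test_that("cell RMSE obeys its closed forms", {
  pr <- demo_prepared(5000, 9)
  elig <- pr[pr$age_baseline >= 35 & pr$age_baseline <= 70, ]
  set.seed(2)
  cells <- average_cells(runif(nrow(elig), 0, 0.4), elig, ci = FALSE)
  expect_identical(rmse_cells(cells, cells), 0)
  shifted <- cells
  shifted$p0 <- shifted$p0 + 1
  expect_equal(rmse_cells(cells, shifted), 1)
  empty <- cells
  empty$p0 <- NA_real_
  expect_error(rmse_cells(cells, empty), "shared")
})

test_that("uncensored pseudo-values reduce to event indicators", {
  time <- seq(0.5, 30, length.out = 60)
  cause <- rep(1L, 60)  # everyone fails from the cause of interest
  pv <- pseudo_values(time, cause, t = 15)
  expect_equal(pv, as.numeric(time <= 15))
  expect_equal(mean(pv), nonhdlrisk:::aj_cif1_at(time, cause, 15))
  expect_error(pseudo_values(time[1:10], cause[1:10], 5), "n < 50")
})

test_that("pseudo-value means track the Aalen-Johansen estimate", {
  pr <- demo_prepared(5000, 9)[1:250, ]
  pv <- pseudo_values(pr$followup_years, pr$event_cause, 20)
  aj <- nonhdlrisk:::aj_cif1_at(pr$followup_years, pr$event_cause, 20)
  expect_lt(abs(mean(pv) - aj), 5e-3)
  # the internal estimator agrees with the survfit-based curve
  curve <- aalen_johansen(pr)
  row <- max(which(curve$time <= 20))
  expect_equal(aj, curve$cif_cvd[row], tolerance = 1e-12)
})

test_that("a well-specified model calibrates on pseudo-values", {
  m <- demo_model()
  pr <- demo_prepared()
  elig <- pr[pr$age_baseline >= 35 & pr$age_baseline <= 70, ]
  set.seed(33)
  sub <- elig[sample.int(nrow(elig), 1500), ]
  pred <- predict_cvd_risk(sub, m, years = 20)
  cal <- pseudo_value_calibration(sub, pred, timeframe = 20)
  expect_s3_class(cal, "calibration_curve")
  qs <- quantile(pred, c(0.05, 0.95))
  central <- cal$predicted >= qs[1] & cal$predicted <= qs[2]
  dev <- abs(cal$observed[central] - cal$predicted[central])
  expect_lt(max(dev, na.rm = TRUE), 0.05)
})

test_that("a random score has no cross-validated discrimination", {
  pr <- demo_prepared(3000, 6)
  set.seed(91)
  c_rand <- suppressWarnings(cindex_cv(
    pr, timeframe = 20, folds = 2, seed = 3,
    predict_fun = function(train, test, timeframe, step) {
      runif(nrow(test))
    }))
  expect_lt(abs(c_rand - 0.5), 0.06)
  expect_length(attr(c_rand, "folds"), 2L)
})

test_that("perfectly separating scores give concordance one", {
  # all subjects fail, no censoring, score reverses the failure order
  rec <- prepare_cohort(make_records(time = seq(1, 30, length.out = 60),
                                     cause = rep(1L, 60)))
  c_perf <- cindex_cv(rec, timeframe = 40, folds = 2, seed = 1,
                      predict_fun = function(train, test, timeframe, step) {
                        -test$followup_years
                      })
  expect_equal(as.numeric(c_perf), 1)
})

test_that("a lipid effect raises cross-validated discrimination", {
  cfg_null <- default_config()
  cfg_null$cvd_hazard$loghr[["nonhdl"]] <- 0
  cfg_strong <- default_config()
  cfg_strong$cvd_hazard$loghr[["nonhdl"]] <- 0.4
  c_null <- c_strong <- numeric(3)
  for (i in 1:3) {
    pr0 <- prepare_cohort(generate_cohort(cfg_null, n = 3000,
                                          seed = 400 + i))
    pr1 <- prepare_cohort(generate_cohort(cfg_strong, n = 3000,
                                          seed = 400 + i))
    c_null[i] <- suppressWarnings(cindex_cv(pr0, timeframe = 20,
                                            folds = 2, seed = 3))
    c_strong[i] <- suppressWarnings(cindex_cv(pr1, timeframe = 20,
                                              folds = 2, seed = 3))
  }
  expect_gt(mean(c_strong), mean(c_null))
})

test_that("leave-one-cohort-out agreement returns one RMSE per cohort", {
  pr <- demo_prepared(20000, 42)
  keep <- pr$cohort_id %in% c("C01", "C02")
  two <- pr[keep, , drop = FALSE]
  out <- suppressWarnings(loco_rmse(two, seed = 2))
  expect_identical(nrow(out), 2L)
  expect_true(all(out$rmse > 0))
  one <- pr[pr$cohort_id == "C01", , drop = FALSE]
  out1 <- suppressWarnings(loco_rmse(one, seed = 2))
  expect_identical(nrow(out1), 1L)
  expect_equal(out1$rmse,
               suppressWarnings(derivation_validation_rmse(one,
                                                           seed = 2))$rmse)
})
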