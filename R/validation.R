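#' Split a pooled cohort into derivation and validation halves
#'
#' Simple random halving within each cohort, so every cohort is
#' represented in both datasets. Deterministic given the seed. A cohort
#' of size 1 goes to the derivation half with a warning.
#'
#' @param records Subject table.
#' @param seed Integer seed.
#' @return A list of class `"split_result"` with `derivation` and
#'   `validation` subject-id vectors and the `seed`.
#' @export
split_cohort <- function(records, seed = 1L) {
  check_records(records)
  singles <- names(which(table(records$cohort_id) == 1L))
  if (length(singles) > 0L) {
    warning(sprintf("cohort(s) of size 1 assigned to derivation: %s",
                    paste(singles, collapse = ", ")))
  }
  der <- with_seed(seed, {
    unlist(lapply(split(records$subject_id, records$cohort_id),
                  function(ids) {
                    ids <- sample(ids)
                    ids[seq_len(ceiling(length(ids) / 2))]
                  }), use.names = FALSE)
  })
  structure(list(derivation = sort(der),
                 validation = sort(setdiff(records$subject_id, der)),
                 seed = seed),
            class = "split_result")
}

#' RMSE between two cell-probability tables
#'
#' Root mean square error over the cells shared (non-missing) by the two
#' tables, in percentage points.
#'
#' @param cells_der,cells_val Cell tables from [average_cells()] with
#'   matching keys and `p0` in percent.
#' @return RMSE in %.
#' @export
rmse_cells <- function(cells_der, cells_val) {
  keys <- c("sex", "age_group", "non_hdl_cat", "rf_burden")
  m <- merge(cells_der[, c(keys, "p0")], cells_val[, c(keys, "p0")],
             by = keys, suffixes = c("_der", "_val"))
  ok <- !is.na(m$p0_der) & !is.na(m$p0_val)
  if (!any(ok)) stop("no shared non-empty cells", call. = FALSE)
  sqrt(mean((m$p0_der[ok] - m$p0_val[ok])^2))
}

#' Derivation/validation agreement of the lifetime-risk model
#'
#' Runs the full lifetime-risk pipeline independently in the two halves
#' of a within-cohort random split — cause-specific Cox models, Weibull
#' baselines, subject-level probabilities of CVD by 75, cell averages —
#' and reports the cell-probability RMSE between the halves.
#'
#' @param records Prepared cohort table.
#' @param seed Seed for the split.
#' @param step Integration step for [predict_cvd_by_75()].
#' @return List with `rmse` (%), the two cell tables, and the split.
#' @export
derivation_validation_rmse <- function(records, seed = 1L, step = 0.05) {
  check_records(records, prepared = TRUE)
  sp <- split_cohort(records, seed)
  half_cells <- function(ids) {
    half <- records[records$subject_id %in% ids, , drop = FALSE]
    model <- fit_cause_specific_models(half)
    elig <- half$age_baseline >= model$eligible_ages[1L] &
      half$age_baseline <= model$eligible_ages[2L]
    elig_rows <- half[elig, , drop = FALSE]
    p <- predict_cvd_by_75(elig_rows, model, step = step)
    average_cells(p, elig_rows, ci = FALSE)
  }
  cells_der <- half_cells(sp$derivation)
  cells_val <- half_cells(sp$validation)
  list(rmse = rmse_cells(cells_der, cells_val),
       cells_der = cells_der, cells_val = cells_val, split = sp)
}

#' Leave-one-cohort-out agreement
#'
#' Generalisation of the split agreement: each cohort in turn serves as
#' the validation set against a model fitted on the remaining cohorts.
#' With a single cohort this reduces to the plain within-cohort split
#' RMSE.
#'
#' @inheritParams derivation_validation_rmse
#' @return Data frame with one row per held-out cohort and its RMSE (%).
#' @export
loco_rmse <- function(records, seed = 1L, step = 0.05) {
  check_records(records, prepared = TRUE)
  cohorts <- unique(as.character(records$cohort_id))
  if (length(cohorts) < 2L) {
    return(data.frame(cohort = cohorts,
                      rmse = derivation_validation_rmse(records, seed,
                                                        step)$rmse))
  }
  fit_cells <- function(rows) {
    model <- fit_cause_specific_models(rows)
    elig <- rows$age_baseline >= 35 & rows$age_baseline <= 70
    rows <- rows[elig, , drop = FALSE]
    average_cells(predict_cvd_by_75(rows, model, step = step), rows,
                  ci = FALSE)
  }
  out <- lapply(cohorts, function(co) {
    inside <- records$cohort_id == co
    data.frame(cohort = co,
               rmse = rmse_cells(fit_cells(records[!inside, , drop = FALSE]),
                                 fit_cells(records[inside, , drop = FALSE])))
  })
  do.call(rbind, out)
}

#' Cross-validated concordance of the lifetime-risk model
#'
#' Harrell-type C-index of predicted CVD risk over a fixed timeframe
#' against observed outcomes, with 10-fold cross-validation: the
#' cause-specific model is refitted on each training set and evaluated on
#' the held-out fold. Competing (non-CVD death) events are treated as
#' non-events censored at their event time, and pairs are truncated at
#' the timeframe.
#'
#' @param records Prepared cohort table.
#' @param timeframe Prediction horizon, years (> 0).
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @param step Integration step.
#' @param predict_fun Optional scoring function
#'   `function(train, test, timeframe, step)` returning one risk score per
#'   test row; defaults to fitting [fit_cause_specific_models()] on the
#'   training rows and predicting with [predict_cvd_risk()]. Injectable so
#'   reference scores (e.g. random noise) can be benchmarked through the
#'   same machinery.
#' @return Mean concordance across folds, with per-fold values as
#'   attribute `"folds"`.
#' @export
cindex_cv <- function(records, timeframe, folds = 10L, seed = 1L,
                      step = 0.05, predict_fun = NULL) {
  if (is.null(predict_fun)) {
    predict_fun <- function(train, test, timeframe, step) {
      model <- fit_cause_specific_models(train)
      predict_cvd_risk(test, model, years = timeframe, step = step)
    }
  }
  check_records(records, prepared = TRUE)
  stopifnot(timeframe > 0)
  n <- nrow(records)
  fold_id <- with_seed(seed, {
    # stratify fold assignment by cohort x sex so every training set
    # retains all Cox strata
    st <- interaction(records$cohort_id, records$sex, drop = TRUE)
    id <- integer(n)
    for (lev in levels(st)) {
      idx <- which(st == lev)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  cvals <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    ev <- records$event_cause[test] == 1L &
      records$followup_years[test] <= timeframe
    if (!any(ev)) {
      warning(sprintf("fold %d has no events within the timeframe; skipped",
                      f))
      next
    }
    pred <- predict_fun(records[!test, , drop = FALSE],
                        records[test, , drop = FALSE], timeframe, step)
    tt <- pmin(records$followup_years[test], timeframe)
    cf <- survival::concordance(
      survival::Surv(tt, ev) ~ pred,
      data = data.frame(tt = tt, ev = as.integer(ev), pred = pred),
      reverse = TRUE)
    cvals[f] <- cf$concordance
  }
  out <- mean(cvals, na.rm = TRUE)
  attr(out, "folds") <- cvals
  out
}

#' Jackknife pseudo-values of the cumulative incidence of CVD
#'
#' For subject i, `PV_i = n * F(t) - (n - 1) * F_(-i)(t)` where `F` is
#' the Aalen-Johansen cumulative incidence of cause 1 and `F_(-i)` its
#' leave-one-out recomputation. Without censoring or competing events the
#' pseudo-value equals the subject's 0/1 event indicator at `t`.
#'
#' @param time Follow-up times.
#' @param cause Event causes (0 censored, 1 CVD, 2 competing).
#' @param t Evaluation time.
#' @return Numeric vector of pseudo-values (may fall outside `[0, 1]`).
#' @export
pseudo_values <- function(time, cause, t) {
  n <- length(time)
  if (n < 50L) {
    stop("pseudo-values are unstable for n < 50", call. = FALSE)
  }
  full <- aj_cif1_at(time, cause, t)
  loo <- vapply(seq_len(n), function(i) {
    aj_cif1_at(time[-i], cause[-i], t)
  }, numeric(1))
  n * full - (n - 1) * loo
}

#' Pseudo-value calibration curve
#'
#' Smooths jackknife pseudo-values of the observed cumulative incidence
#' at the timeframe against model-predicted risks with a local-linear
#' smoother (loess, degree 1, span 0.75), returning the calibration curve
#' on a 100-point grid of predicted risk. A well-calibrated model tracks
#' the diagonal.
#'
#' @param records Prepared cohort rows.
#' @param predictions Predicted risks over the timeframe (proportions),
#'   one per row.
#' @param timeframe Evaluation time, years.
#' @param sex Optional `"female"`/`"male"` restriction.
#' @param span Loess span.
#' @return Data frame of class `"calibration_curve"` with columns
#'   `predicted`, `observed`, `timeframe`, `sex`; the subject-level
#'   pseudo-values are attached as attribute `"pseudo_values"`.
#' @export
pseudo_value_calibration <- function(records, predictions, timeframe,
                                     sex = NULL, span = 0.75) {
  check_records(records)
  stopifnot(length(predictions) == nrow(records))
  if (!is.null(sex)) {
    keep <- records$sex == sex
    records <- records[keep, , drop = FALSE]
    predictions <- predictions[keep]
  }
  pv <- pseudo_values(records$followup_years, records$event_cause,
                      timeframe)
  sm <- loess(pv ~ pred, data = data.frame(pv = pv, pred = predictions),
              degree = 1, span = span,
              family = "gaussian")
  grid <- seq(min(predictions), max(predictions), length.out = 100L)
  out <- data.frame(predicted = grid,
                    observed = predict(sm, newdata = data.frame(pred = grid)),
                    timeframe = timeframe,
                    sex = sex %||% "all")
  attr(out, "pseudo_values") <- pv
  class(out) <- c("calibration_curve", "data.frame")
  out
}
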