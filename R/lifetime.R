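# Weibull baseline hazard with a fixed log-hazard offset, fitted by
# maximum likelihood on left-truncated (entry age, exit age, event) data:
#   h(a) = (k/lambda) * (a/lambda)^(k-1) * exp(offset_i)
# This is the parametric step of the lifetime-risk model: the Cox linear
# predictor enters as the per-subject offset, so the two Weibull
# parameters describe the stratum baseline on the age scale.
fit_weibull_baseline <- function(entry, exit, event, offset) {
  stopifnot(length(entry) == length(exit), all(exit > entry))
  w <- exp(offset)
  negll <- function(par) {
    k <- exp(par[1L]); lam <- exp(par[2L])
    H <- function(a) (a / lam)^k
    ll <- sum(event * (log(k) - log(lam) + (k - 1) * log(exit / lam) +
                         offset)) -
      sum(w * (H(exit) - H(entry)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list(c(log(5), log(stats::median(exit) * 1.2)),
                 c(log(2), log(stats::median(exit) * 1.5)),
                 c(log(8), log(max(exit))))
  best <- NULL
  for (s in starts) {
    opt <- try(optim(s, negll, method = "BFGS",
                     control = list(maxit = 500)), silent = TRUE)
    if (!inherits(opt, "try-error") &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("Weibull baseline fit failed", call. = FALSE)
  c(shape = exp(best$par[1L]), scale = exp(best$par[2L]))
}

#' Cause-specific Cox models with Weibull baseline hazards
#'
#' Fits the two cause-specific proportional-hazards models underlying the
#' lifetime-risk tool: a Cox model for CVD events and one for non-CVD
#' death, both on the age timescale (delayed entry at baseline age),
#' stratified by cohort and sex, with non-HDL cholesterol, BMI and
#' systolic blood pressure coded as natural cubic splines and a sex x
#' non-HDL interaction. Per stratum (sex x cohort) and cause, a Weibull
#' baseline hazard is then fitted by maximum likelihood on the
#' left-truncated age data with each subject's Cox linear predictor as a
#' fixed multiplicative offset on the hazard. Strata with fewer than
#' `min_stratum_events` events of a cause fall back to the pooled-sex x
#' cause Weibull fit (with a warning).
#'
#' @param records Prepared cohort table.
#' @param min_stratum_events Minimum events for a stratum-specific
#'   Weibull fit (default 25).
#' @param winsor,breaks Passed to [fit_stratified_cox()].
#' @return An object of class `"cause_specific_model"`: `$cox_cvd`,
#'   `$cox_death` (a `"nonhdl_coxfit"` or `NULL` when no competing deaths
#'   are present), `$baselines` (data frame sex/cohort/cause/shape/scale),
#'   `$horizon` (75), `$eligible_ages` (35-70).
#' @export
fit_cause_specific_models <- function(records, min_stratum_events = 25L,
                                      winsor = c(1.6, 8.5),
                                      breaks = nonhdl_breaks_mmol()) {
  check_records(records, prepared = TRUE)
  cox_cvd <- fit_stratified_cox(records, exposure = "spline",
                                interactions = "sex", cause = 1L,
                                winsor = winsor, breaks = breaks,
                                smooth_bmi_sbp = TRUE)
  cox_death <- tryCatch(
    fit_stratified_cox(records, exposure = "spline",
                       interactions = "sex", cause = 2L,
                       winsor = winsor, breaks = breaks,
                       smooth_bmi_sbp = TRUE),
    error = function(e) {
      warning("non-CVD death model degenerate (no competing events); ",
              "lifetime risk will be computed without competing mortality")
      NULL
    })

  records <- records[records$followup_years > 0, , drop = FALSE]
  entry <- records$age_baseline
  exit <- records$age_baseline + records$followup_years
  sexes <- levels(droplevels(records$sex))
  cohorts <- sort(unique(as.character(records$cohort_id)))

  baselines <- list()
  for (cause in 1:2) {
    cox <- if (cause == 1L) cox_cvd else cox_death
    if (is.null(cox)) next
    eta <- cox_linear_predictor(cox, records)
    event <- as.integer(records$event_cause == cause)
    for (s in sexes) {
      sx <- records$sex == s
      pooled <- fit_weibull_baseline(entry[sx], exit[sx], event[sx],
                                     eta[sx])
      for (co in cohorts) {
        idx <- sx & records$cohort_id == co
        nev <- sum(event[idx])
        use_pooled <- nev < min_stratum_events
        par <- if (use_pooled) {
          pooled
        } else {
          fit_weibull_baseline(entry[idx], exit[idx], event[idx], eta[idx])
        }
        baselines[[length(baselines) + 1L]] <- data.frame(
          sex = s, cohort = co, cause = cause,
          shape = unname(par["shape"]), scale = unname(par["scale"]),
          n_events = nev, pooled = use_pooled)
      }
    }
  }
  baselines <- do.call(rbind, baselines)
  npool <- sum(baselines$pooled)
  if (npool > 0L) {
    warning(sprintf(
      "%d stratum/cause baseline(s) had < %d events; pooled-sex Weibull used",
      npool, min_stratum_events))
  }
  structure(list(cox_cvd = cox_cvd, cox_death = cox_death,
                 baselines = baselines, horizon = 75,
                 eligible_ages = c(35, 70), breaks = breaks),
            class = "cause_specific_model")
}

#' @export
print.cause_specific_model <- function(x, ...) {
  cat("Cause-specific Cox + Weibull lifetime-risk model\n")
  cat(sprintf("  CVD fit: n = %d, events = %d\n", x$cox_cvd$n,
              x$cox_cvd$n_events))
  if (is.null(x$cox_death)) {
    cat("  non-CVD death fit: degenerate (no competing events)\n")
  } else {
    cat(sprintf("  non-CVD death fit: n = %d, events = %d\n",
                x$cox_death$n, x$cox_death$n_events))
  }
  cat(sprintf("  Weibull baselines: %d strata x cause\n",
              nrow(x$baselines)))
  invisible(x)
}

baseline_params <- function(model, sex, cohort, cause) {
  b <- model$baselines
  row <- b$sex == sex & b$cohort == cohort & b$cause == cause
  if (!any(row)) {
    # cohort unseen at fit time: use the pooled-sex parameters
    row <- b$sex == sex & b$cause == cause
    if (!any(row)) return(NULL)
    row <- which(row)[1L]
  }
  b[row, , drop = FALSE][1L, ]
}

# Piecewise product-integral of the two-cause model on a uniform age grid
# (step <= `step`): within each interval the cause-specific cumulative
# hazard increments come from the closed-form Weibull H, and the interval
# failure mass exp(-A)(1-exp(-dH_tot)) is apportioned to causes by their
# hazard increments. The scheme conserves F1 + F2 + S = 1 exactly.
predict_cif_components <- function(records, model, horizon_age = 75,
                                   horizon_years = NULL, step = 0.05) {
  check_records(records, prepared = TRUE)
  n <- nrow(records)
  eta1 <- cox_linear_predictor(model$cox_cvd, records)
  eta2 <- if (is.null(model$cox_death)) rep(-Inf, n)
          else cox_linear_predictor(model$cox_death, records)
  F1 <- F2 <- S <- numeric(n)
  key <- paste(records$sex, records$cohort_id, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    s <- as.character(records$sex[idx[1L]])
    co <- as.character(records$cohort_id[idx[1L]])
    b1 <- baseline_params(model, s, co, 1L)
    b2 <- baseline_params(model, s, co, 2L)
    a0 <- records$age_baseline[idx]
    span <- if (is.null(horizon_years)) horizon_age - a0
            else rep(horizon_years, length(idx))
    if (any(span <= 0)) stop("horizon must exceed baseline age",
                             call. = FALSE)
    m <- pmax(ceiling(span / step), 1L)
    h <- span / m
    w1 <- exp(eta1[idx])
    w2 <- if (is.null(b2)) rep(0, length(idx)) else exp(eta2[idx])
    Hw <- function(a, b) (a / b$scale)^b$shape
    acc <- numeric(length(idx))
    f1 <- f2 <- numeric(length(idx))
    for (j in seq_len(max(m))) {
      act <- j <= m
      up <- a0 + (j - 1) * h
      u <- a0 + j * h
      dH1 <- ifelse(act, w1 * (Hw(u, b1) - Hw(up, b1)), 0)
      dH2 <- if (is.null(b2)) 0 else
        ifelse(act, w2 * (Hw(u, b2) - Hw(up, b2)), 0)
      dHt <- dH1 + dH2
      mass <- exp(-acc) * (-expm1(-dHt))
      frac1 <- ifelse(dHt > 0, dH1 / dHt, 0)
      f1 <- f1 + mass * frac1
      f2 <- f2 + mass * (1 - frac1)
      acc <- acc + dHt
    }
    F1[idx] <- f1; F2[idx] <- f2; S[idx] <- exp(-acc)
  }
  list(cif_cvd = F1, cif_death = F2, surv = S)
}

#' Probability of a CVD event by age 75
#'
#' For each subject aged 35-70 at baseline, integrates the fitted
#' cause-specific hazards from the baseline age to 75:
#' F1(75 | a0) = int_a0^75 S(u | a0) h1(u) du with
#' S(u | a0) = exp(-int_a0^u (h1 + h2)), where h_c is the stratum Weibull
#' baseline hazard times exp(Cox linear predictor of cause c). The
#' integral is evaluated on a uniform age grid (default step 0.05 years)
#' by a piecewise product-integral that conserves total probability
#' exactly.
#'
#' @param records Prepared cohort rows with baseline ages in `[35, 70]`.
#' @param model A `"cause_specific_model"`.
#' @param step Age-grid step, years.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_cvd_by_75 <- function(records, model, step = 0.05) {
  stopifnot(inherits(model, "cause_specific_model"))
  a0 <- records$age_baseline
  lo <- model$eligible_ages[1L]; hi <- model$eligible_ages[2L]
  if (any(a0 < lo | a0 > hi)) {
    stop(sprintf("baseline age outside [%g, %g]: prediction restricted to ages eligible for the by-75 horizon",
                 lo, hi), call. = FALSE)
  }
  predict_cif_components(records, model, horizon_age = model$horizon,
                         step = step)$cif_cvd
}

#' CVD risk over a fixed horizon in years
#'
#' Same integration as [predict_cvd_by_75()] but from the baseline age to
#' baseline age + `years` (used for timeframe-specific discrimination and
#' calibration).
#'
#' @inheritParams predict_cvd_by_75
#' @param years Prediction horizon in years (> 0).
#' @return Numeric vector of probabilities.
#' @export
predict_cvd_risk <- function(records, model, years, step = 0.05) {
  stopifnot(inherits(model, "cause_specific_model"), years > 0)
  predict_cif_components(records, model, horizon_years = years,
                         step = step)$cif_cvd
}

#' Individual cumulative-incidence curve on the age grid
#'
#' @param record A single prepared subject row.
#' @param model A `"cause_specific_model"`.
#' @param step Age-grid step, years.
#' @param horizon Final age (default the model horizon, 75).
#' @return Data frame with columns `age`, `cif_cvd`, `cif_death`, `surv`
#'   (cumulative from the baseline age; first row is the baseline age
#'   with zero incidence).
#' @export
predict_cif_curve <- function(record, model, step = 0.05, horizon = NULL) {
  stopifnot(inherits(model, "cause_specific_model"), nrow(record) == 1L)
  horizon <- horizon %||% model$horizon
  a0 <- record$age_baseline
  stopifnot(horizon > a0)
  eta1 <- cox_linear_predictor(model$cox_cvd, record)
  b1 <- baseline_params(model, as.character(record$sex),
                        as.character(record$cohort_id), 1L)
  b2 <- baseline_params(model, as.character(record$sex),
                        as.character(record$cohort_id), 2L)
  m <- max(ceiling((horizon - a0) / step), 1L)
  ages <- a0 + (horizon - a0) * (0:m) / m
  Hw <- function(a, b) (a / b$scale)^b$shape
  dH1 <- exp(eta1) * diff(Hw(ages, b1))
  dH2 <- if (is.null(b2)) rep(0, m) else {
    eta2 <- cox_linear_predictor(model$cox_death, record)
    exp(eta2) * diff(Hw(ages, b2))
  }
  dHt <- dH1 + dH2
  s_before <- exp(-c(0, cumsum(dHt)[-m]))
  mass <- s_before * (-expm1(-dHt))
  frac1 <- ifelse(dHt > 0, dH1 / dHt, 0)
  data.frame(age = ages,
             cif_cvd = c(0, cumsum(mass * frac1)),
             cif_death = c(0, cumsum(mass * (1 - frac1))),
             surv = c(1, exp(-cumsum(dHt))))
}

#' Average predicted probabilities into risk-circle cells
#'
#' Averages subject-level probabilities of CVD by 75 within the 60 cells
#' of sex x baseline age group (<45, 45-59, >=60) x non-HDL category x
#' risk-factor burden (0-1 vs >=2 of: daily smoking, arterial
#' hypertension, diabetes, obesity). 95% confidence intervals come from a
#' cohort-stratified nonparametric bootstrap over subjects (percentile
#' method).
#'
#' @param predictions Probabilities (proportions in `[0, 1]`), one per row
#'   of `records`.
#' @param records The prepared rows the predictions belong to (eligible
#'   subjects, baseline age 35-70).
#' @param ci Compute bootstrap confidence intervals.
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame with one row per cell: `sex`, `age_group`,
#'   `non_hdl_cat`, `rf_burden`, `n`, `p0` (%), `ci_low`, `ci_high` (%),
#'   `mean_non_hdl_adj`, `mean_age`. Empty cells carry `NA` estimates.
#' @export
average_cells <- function(predictions, records, ci = TRUE, n_boot = 500L,
                          seed = 1L) {
  check_records(records, prepared = TRUE)
  stopifnot(length(predictions) == nrow(records),
            all(predictions >= 0 & predictions <= 1))
  ncat <- length(nonhdl_breaks_mmol()) + 1L
  cell <- interaction(records$sex, records$age_group,
                      factor(records$non_hdl_cat, levels = seq_len(ncat)),
                      records$rf_burden, sep = "|", drop = FALSE)
  code <- as.integer(cell)
  K <- nlevels(cell)
  sums <- function(idx) {
    s <- rowsum(c(predictions[idx], rep(0, K)),
                c(code[idx], seq_len(K)))[, 1L]
    n <- tabulate(code[idx], K)
    ifelse(n > 0L, s / pmax(n, 1L), NA_real_)
  }
  all_idx <- seq_len(nrow(records))
  p0 <- sums(all_idx)
  n_cell <- tabulate(code, K)

  keys <- do.call(rbind, strsplit(levels(cell), "|", fixed = TRUE))
  out <- data.frame(
    sex = factor(keys[, 1L], levels = c("female", "male")),
    age_group = factor(keys[, 2L], levels = c("<45", "45-59", ">=60")),
    non_hdl_cat = as.integer(keys[, 3L]),
    rf_burden = factor(keys[, 4L], levels = c("0-1", ">=2")),
    n = n_cell,
    p0 = 100 * p0,
    ci_low = NA_real_, ci_high = NA_real_,
    mean_non_hdl_adj = as.numeric(tapply(records$non_hdl_adj, cell, mean)),
    mean_age = as.numeric(tapply(records$age_baseline, cell, mean)))

  if (ci && n_boot > 0L) {
    by_cohort <- split(all_idx, records$cohort_id)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(by_cohort, function(ix) {
          ix[sample.int(length(ix), replace = TRUE)]
        }), use.names = FALSE)
        sums(idx)
      }, numeric(K))
    })
    qs <- apply(boot, 1L, function(v) {
      if (all(is.na(v))) c(NA_real_, NA_real_)
      else quantile(v, probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    })
    out$ci_low <- 100 * qs[1L, ]
    out$ci_high <- 100 * qs[2L, ]
    out$ci_low[is.na(out$p0)] <- NA_real_
    out$ci_high[is.na(out$p0)] <- NA_real_
  }
  ord <- order(out$sex, out$age_group, out$rf_burden, out$non_hdl_cat)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
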