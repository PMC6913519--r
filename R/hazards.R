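# Design-matrix builder shared by the association models and the
# cause-specific lifetime-risk models. Spline bases are natural cubic
# (splines::ns); knot locations are fixed at fit time and stored in the
# spec so linear predictors for new data reproduce the fitted basis
# exactly.

winsorize <- function(x, bounds) pmin(pmax(x, bounds[1L]), bounds[2L])

spline_basis <- function(x, spec) {
  splines::ns(winsorize(x, spec$boundary), knots = spec$knots,
              Boundary.knots = spec$boundary)
}

make_spline_spec <- function(x, boundary = NULL, probs = c(0.25, 0.5, 0.75)) {
  if (is.null(boundary)) boundary <- range(x)
  list(knots = unname(quantile(winsorize(x, boundary), probs)),
       boundary = boundary)
}

build_design <- function(records, spec) {
  ncat <- length(spec$breaks) + 1L
  male <- as.integer(records$sex == "male")
  cols <- list()

  if (spec$exposure == "categorical") {
    cat_i <- assign_category(records$non_hdl_adj, spec$breaks)
    for (c in 2:ncat) cols[[sprintf("cat%d", c)]] <- as.integer(cat_i == c)
    expo_names <- sprintf("cat%d", 2:ncat)
  } else {
    if (is.null(spec$nonhdl_spline)) {
      spec$nonhdl_spline <- make_spline_spec(records$non_hdl_adj,
                                             spec$winsor)
    }
    B <- spline_basis(records$non_hdl_adj, spec$nonhdl_spline)
    for (j in seq_len(ncol(B))) cols[[sprintf("sp%d", j)]] <- B[, j]
    expo_names <- sprintf("sp%d", seq_len(ncol(B)))
  }

  if ("sex" %in% spec$interactions) {
    for (nm in expo_names) cols[[paste0("m_", nm)]] <- male * cols[[nm]]
  }
  if ("age_group" %in% spec$interactions) {
    ag <- age_group_of(records$age_baseline)
    cols[["ag45_59"]] <- as.integer(ag == "45-59")
    cols[["ag60"]] <- as.integer(ag == ">=60")
    for (nm in expo_names) {
      cols[[paste0("ag45_59_", nm)]] <- cols[["ag45_59"]] * cols[[nm]]
      cols[[paste0("ag60_", nm)]] <- cols[["ag60"]] * cols[[nm]]
    }
  }

  cols[["smoking"]] <- records$smoking
  cols[["diabetes"]] <- records$diabetes
  cols[["antihypertensive_med"]] <- records$antihypertensive_med
  if (isTRUE(spec$smooth_bmi_sbp)) {
    if (is.null(spec$bmi_spline)) spec$bmi_spline <- make_spline_spec(records$bmi)
    if (is.null(spec$sbp_spline)) spec$sbp_spline <- make_spline_spec(records$sbp)
    Bb <- spline_basis(records$bmi, spec$bmi_spline)
    Bs <- spline_basis(records$sbp, spec$sbp_spline)
    for (j in seq_len(ncol(Bb))) cols[[sprintf("bmi_sp%d", j)]] <- Bb[, j]
    for (j in seq_len(ncol(Bs))) cols[[sprintf("sbp_sp%d", j)]] <- Bs[, j]
  } else {
    cols[["bmi"]] <- records$bmi
    cols[["sbp"]] <- records$sbp
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, spec = spec)
}

#' Stratified Cox model for non-HDL cholesterol and CVD
#'
#' Fits a multivariable Cox proportional-hazards model on the age
#' timescale (entry at baseline age, exit at event/censoring age — left
#' truncation), stratified by cohort and sex, with Efron tie handling.
#' The exposure is adjusted non-HDL cholesterol, coded either as the five
#' guideline categories (category 1 as reference) or as a natural cubic
#' spline with three interior knots at the exposure quartiles and
#' boundary knots at the winsorisation bounds. Adjustment covariates:
#' smoking, diabetes, BMI, systolic blood pressure, antihypertensive
#' medication. Optional interactions of the exposure with sex and with
#' baseline age group (<45, 45-59, >=60) are coded as male x exposure and
#' age-group x exposure product terms (sex and cohort main effects are
#' absorbed by the stratification).
#'
#' @param records Prepared cohort table (see [prepare_cohort()]).
#' @param exposure `"categorical"` or `"spline"`.
#' @param interactions Character subset of `c("sex", "age_group")`.
#' @param cause Event cause treated as failure (1 = CVD, 2 = non-CVD
#'   death); the other cause is censored (cause-specific hazard model).
#' @param winsor Winsorisation bounds for the spline coding, mmol/L.
#' @param breaks Category boundaries, mmol/L.
#' @param smooth_bmi_sbp Spline-code BMI and systolic blood pressure
#'   (used by the lifetime-risk model) instead of entering them linearly.
#' @return An object of class `"nonhdl_coxfit"`: list with the underlying
#'   `survival::coxph` fit (`$fit`), the design `$spec`, and `$n_events`.
#' @export
fit_stratified_cox <- function(records,
                               exposure = c("categorical", "spline"),
                               interactions = character(),
                               cause = 1L,
                               winsor = c(1.6, 8.5),
                               breaks = nonhdl_breaks_mmol(),
                               smooth_bmi_sbp = FALSE) {
  exposure <- match.arg(exposure)
  check_records(records, prepared = TRUE)
  stopifnot(all(interactions %in% c("sex", "age_group")))

  keep <- records$followup_years > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d record(s) with zero follow-up", sum(!keep)))
    records <- records[keep, , drop = FALSE]
  }
  status <- as.integer(records$event_cause == cause)
  stratum <- interaction(records$cohort_id, records$sex, drop = TRUE)
  ev_per_stratum <- tapply(status, stratum, sum)
  dead_strata <- names(ev_per_stratum)[ev_per_stratum == 0L]
  if (length(dead_strata) > 0L) {
    warning(sprintf("dropping %d stratum/strata with zero events: %s",
                    length(dead_strata),
                    paste(dead_strata, collapse = ", ")))
    keep <- !(as.character(stratum) %in% dead_strata)
    records <- records[keep, , drop = FALSE]
    status <- status[keep]
  }
  if (sum(status) == 0L) stop("no events of the requested cause",
                              call. = FALSE)

  spec <- list(exposure = exposure, interactions = interactions,
               winsor = winsor, breaks = breaks,
               smooth_bmi_sbp = smooth_bmi_sbp,
               nonhdl_spline = NULL, bmi_spline = NULL, sbp_spline = NULL)
  d <- build_design(records, spec)
  df <- data.frame(.entry = records$age_baseline,
                   .exit = records$age_baseline + records$followup_years,
                   .status = status,
                   .cohort = records$cohort_id,
                   .sex = records$sex,
                   d$X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.entry, .exit, .status) ~",
    paste(colnames(d$X), collapse = " + "),
    "+ survival::strata(.cohort, .sex)"))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  structure(list(fit = fit, spec = d$spec, n = nrow(records),
                 n_events = sum(status), cause = cause,
                 timescale = "age", ties = "efron"),
            class = "nonhdl_coxfit")
}

#' @export
coef.nonhdl_coxfit <- function(object, ...) coef(object$fit)

#' @export
vcov.nonhdl_coxfit <- function(object, ...) vcov(object$fit)

#' @export
print.nonhdl_coxfit <- function(x, ...) {
  cat(sprintf(
    "Stratified Cox model (age timescale, %s ties): %s exposure\n",
    x$ties, x$spec$exposure))
  cat(sprintf("  n = %d, events (cause %d) = %d\n", x$n, x$cause,
              x$n_events))
  if (length(x$spec$interactions) > 0L) {
    cat("  interactions:", paste(x$spec$interactions, collapse = ", "), "\n")
  }
  print(signif(coef(x), 4))
  invisible(x)
}

# Linear predictor for new data under a stored design spec (uncentered).
cox_linear_predictor <- function(object, records) {
  X <- build_design(records, object$spec)$X
  beta <- coef(object$fit)
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

wald_block_test <- function(beta, V, idx) {
  b <- beta[idx]
  stat <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE], b))
  list(statistic = stat, df = length(idx),
       p_value = pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Hazard-ratio table for the categorical non-HDL exposure
#'
#' Assembles sex-specific (and optionally age-group-specific) hazard
#' ratios per non-HDL category against the reference category 1, with
#' Wald 95% confidence intervals from linear combinations of the fitted
#' coefficients. When age-group rows are requested, a Wald test of the
#' age-group x category interaction block is attached as attribute
#' `"interaction_test"`.
#'
#' @param fit A `"nonhdl_coxfit"` with categorical exposure.
#' @param by_age_group Emit rows per baseline age group (requires the
#'   `"age_group"` interaction in the fit).
#' @return Data frame with columns `sex`, `age_group`, `category`, `hr`,
#'   `ci_low`, `ci_high`.
#' @export
categorical_hr_table <- function(fit, by_age_group = FALSE) {
  stopifnot(inherits(fit, "nonhdl_coxfit"))
  if (fit$spec$exposure != "categorical") {
    stop("hazard-ratio table requires a categorical-exposure fit",
         call. = FALSE)
  }
  beta <- coef(fit)
  V <- vcov(fit)
  ncat <- length(fit$spec$breaks) + 1L
  sexes <- if ("sex" %in% fit$spec$interactions) c("female", "male") else "all"
  has_ag <- "age_group" %in% fit$spec$interactions
  if (by_age_group && !has_ag) {
    stop("fit does not contain the age_group interaction terms",
         call. = FALSE)
  }
  # without age-group rows, the plain category coefficients are the
  # reference age group's effects when the interaction is in the model
  groups <- if (by_age_group) c("<45", "45-59", ">=60")
            else if (has_ag) "<45" else "all"

  rows <- list()
  for (s in sexes) for (g in groups) for (c in seq_len(ncat)) {
    if (c == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age_group = g, category = 1L, hr = 1, ci_low = 1,
        ci_high = 1)
      next
    }
    terms <- sprintf("cat%d", c)
    if (s == "male") terms <- c(terms, sprintf("m_cat%d", c))
    if (g == "45-59") terms <- c(terms, sprintf("ag45_59_cat%d", c))
    if (g == ">=60") terms <- c(terms, sprintf("ag60_cat%d", c))
    miss <- setdiff(terms, names(beta))
    if (length(miss) > 0L) {
      stop(sprintf("fit is missing coefficient(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    z <- as.numeric(names(beta) %in% terms)
    est <- sum(beta[terms])
    se <- sqrt(drop(t(z) %*% V %*% z))
    rows[[length(rows) + 1L]] <- data.frame(
      sex = s, age_group = g, category = c, hr = exp(est),
      ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se))
  }
  out <- do.call(rbind, rows)
  if (by_age_group) {
    idx <- grep("^ag(45_59|60)_cat", names(beta))
    attr(out, "interaction_test") <- wald_block_test(beta, V, idx)
  }
  out
}

#' Continuous hazard-ratio curve from the spline-coded fit
#'
#' Evaluates HR(x) = exp(s(x) - s(reference)) along a grid of non-HDL
#' cholesterol values, with delta-method 95% confidence bands. Inputs are
#' clamped to the winsorisation bounds; the reference (default
#' 2.6 mmol/L) is assigned HR exactly 1.
#'
#' @param fit A `"nonhdl_coxfit"` with spline exposure.
#' @param reference Reference non-HDL value, mmol/L; must lie within the
#'   winsorisation bounds.
#' @param grid Evaluation grid (default 200 points across the bounds).
#' @return Data frame with columns `sex`, `non_hdl`, `hr`, `ci_low`,
#'   `ci_high`.
#' @export
spline_hr_curve <- function(fit, reference = 2.6, grid = NULL) {
  stopifnot(inherits(fit, "nonhdl_coxfit"))
  if (fit$spec$exposure != "spline") {
    stop("hazard-ratio curve requires a spline-exposure fit", call. = FALSE)
  }
  w <- fit$spec$winsor
  if (reference < w[1L] || reference > w[2L]) {
    stop(sprintf("reference %.2f outside winsorisation bounds [%.2f, %.2f]",
                 reference, w[1L], w[2L]), call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(w[1L], w[2L], length.out = 200L)
  grid <- winsorize(grid, w)
  beta <- coef(fit)
  V <- vcov(fit)
  B <- spline_basis(grid, fit$spec$nonhdl_spline)
  Bref <- spline_basis(reference, fit$spec$nonhdl_spline)
  D <- sweep(B, 2L, drop(Bref))
  sp_names <- sprintf("sp%d", seq_len(ncol(B)))
  sexes <- if ("sex" %in% fit$spec$interactions) c("female", "male") else "all"
  out <- lapply(sexes, function(s) {
    terms <- sp_names
    Dfull <- D
    if (s == "male") {
      terms <- c(sp_names, paste0("m_", sp_names))
      Dfull <- cbind(D, D)
    }
    est <- drop(Dfull %*% beta[terms])
    se <- sqrt(rowSums((Dfull %*% V[terms, terms]) * Dfull))
    data.frame(sex = s, non_hdl = grid, hr = exp(est),
               ci_low = exp(est - 1.96 * se),
               ci_high = exp(est + 1.96 * se))
  })
  do.call(rbind, out)
}
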