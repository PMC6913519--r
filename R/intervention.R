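#' Treatment-benefit parameters
#'
#' Parameters of the hypothetical lipid-lowering benefit model. The
#' expected proportional risk reduction per mmol/L of cholesterol lowered
#' after `t` years of treatment is
#' `r(t) = 1 - exp(-0.249 + (t - 5) * (-0.0152))`, a trial-derived
#' duration-dependent effect anchored at 5 years. The modelled
#' intervention reduces baseline non-HDL cholesterol by 30% or 50%, and
#' treatment is assumed to run from the baseline age to the age-75
#' horizon.
#'
#' @param reduction_fraction Fractional non-HDL reduction, 0.5 (default)
#'   or 0.3 (any value in (0, 1) is accepted).
#' @return A list of class `"treatment_params"` with `intercept`
#'   (-0.249), `slope_per_year` (-0.0152), `reference_duration` (5 years),
#'   `reduction_fraction` and `horizon` (75).
#' @export
treatment_params <- function(reduction_fraction = 0.5) {
  if (reduction_fraction <= 0 || reduction_fraction >= 1) {
    stop("reduction_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  structure(list(intercept = -0.249, slope_per_year = -0.0152,
                 reference_duration = 5,
                 reduction_fraction = reduction_fraction, horizon = 75),
            class = "treatment_params")
}

#' Proportional risk reduction per mmol/L for a treatment duration
#'
#' Evaluates `r(t) = 1 - exp(intercept + (t - 5) * slope_per_year)`,
#' increasing in treatment duration `t`.
#'
#' @param treatment_years Non-negative treatment duration(s), years.
#' @param params A [treatment_params()] list.
#' @return Proportional risk reduction(s) per mmol/L, in (0, 1).
#' @examples
#' proportional_reduction(5) # 1 - exp(-0.249) = 0.2204
#' @export
proportional_reduction <- function(treatment_years,
                                   params = treatment_params()) {
  if (any(treatment_years < 0)) {
    stop("treatment duration must be non-negative", call. = FALSE)
  }
  1 - exp(params$intercept +
            (treatment_years - params$reference_duration) *
              params$slope_per_year)
}

#' Probability of CVD by 75 under hypothetical non-HDL reduction
#'
#' Scales an untreated probability `p0` by the relative risk of reducing
#' non-HDL cholesterol by the configured fraction from the baseline age
#' to 75. The per-mmol/L effects compound: with an absolute reduction of
#' `delta = reduction_fraction * non_hdl_adj` mmol/L sustained for
#' `t = 75 - age_baseline` years, `RR = (1 - r(t))^delta` and
#' `p1 = p0 * RR`.
#'
#' @param p0 Untreated probability(ies), proportions in `[0, 1]`.
#' @param non_hdl_adj Adjusted baseline non-HDL cholesterol, mmol/L.
#' @param age_baseline Baseline age(s) in `[35, 70]` years.
#' @param params A [treatment_params()] list.
#' @return Treated probability(ies) `p1 <= p0`.
#' @export
treated_probability <- function(p0, non_hdl_adj, age_baseline,
                                params = treatment_params()) {
  stopifnot(all(p0 >= 0 & p0 <= 1))
  if (any(age_baseline < 35 | age_baseline > 70)) {
    stop("baseline age must lie in [35, 70]", call. = FALSE)
  }
  t <- params$horizon - age_baseline
  r <- proportional_reduction(t, params)
  delta <- params$reduction_fraction * non_hdl_adj
  p0 * (1 - r)^delta
}

#' Risk difference, number needed to treat and relative risk reduction
#'
#' Cell-level treatment-benefit summaries from untreated and treated
#' average probabilities in percent: `RD = p0 - p1`, `NNT = 100 / RD`
#' (infinite when RD is 0) and `RRR = RD / p0` (0 when `p0` is 0).
#' Display columns round NNT to one decimal and RRR to two.
#'
#' @param p0_cell,p1_cell Average probabilities in percent, with
#'   `0 <= p1 <= p0 <= 100` elementwise.
#' @return Data frame with columns `rd` (%), `nnt`, `rrr` and rounded
#'   `nnt_display`, `rrr_display`.
#' @examples
#' nnt_rrr(15.6, 3.6) # NNT 8.3, RRR 0.77
#' @export
nnt_rrr <- function(p0_cell, p1_cell) {
  stopifnot(all(p0_cell >= 0 & p0_cell <= 100, na.rm = TRUE),
            all(p1_cell >= 0, na.rm = TRUE))
  if (any(p1_cell > p0_cell + 1e-12, na.rm = TRUE)) {
    stop("treated probability exceeds untreated probability", call. = FALSE)
  }
  rd <- p0_cell - p1_cell
  nnt <- ifelse(rd > 0, 100 / rd, Inf)
  rrr <- ifelse(p0_cell > 0, rd / p0_cell, 0)
  data.frame(rd = rd, nnt = nnt, rrr = rrr,
             nnt_display = round(nnt, 1), rrr_display = round(rrr, 2))
}

#' Treated cumulative-incidence curve, forced monotone
#'
#' Applies the duration-dependent relative risk pointwise along an
#' untreated CIF on the age grid: at age `u`,
#' `p1(u) = cif0(u) * (1 - r(u - age_baseline))^delta`. Because the
#' relative risk deepens with treatment duration, the raw product can
#' decrease with age; the returned curve is its running maximum so the
#' output remains a valid (non-decreasing) cumulative incidence.
#'
#' @param cif0 Data frame with columns `age` (sorted increasing, all
#'   `>= age_baseline`) and `cif_cvd`, e.g. from [predict_cif_curve()].
#' @param age_baseline Age at treatment start, years.
#' @param non_hdl_adj Adjusted baseline non-HDL cholesterol, mmol/L.
#' @param params A [treatment_params()] list.
#' @return `cif0` with a `cif_cvd_treated` column appended.
#' @export
treated_cif_curve <- function(cif0, age_baseline, non_hdl_adj,
                              params = treatment_params()) {
  stopifnot(is.data.frame(cif0), all(c("age", "cif_cvd") %in% names(cif0)))
  if (is.unsorted(cif0$age)) {
    stop("age grid must be sorted increasing", call. = FALSE)
  }
  if (any(cif0$age < age_baseline - 1e-9)) {
    stop("curve extends below the baseline age", call. = FALSE)
  }
  t <- pmax(cif0$age - age_baseline, 0)
  r <- proportional_reduction(t, params)
  delta <- params$reduction_fraction * non_hdl_adj
  raw <- cif0$cif_cvd * (1 - r)^delta
  cif0$cif_cvd_treated <- cummax(raw)
  cif0
}

#' Treatment-benefit table over the risk-circle cells
#'
#' Computes subject-level treated probabilities, averages untreated and
#' treated probabilities within the 60 risk-circle cells, and derives the
#' cell-wise risk difference, NNT and RRR.
#'
#' @param predictions Untreated subject-level probabilities (proportions).
#' @param records Prepared rows of the eligible subjects.
#' @param params A [treatment_params()] list.
#' @param ci,n_boot,seed Passed to [average_cells()].
#' @return Data frame: cell keys, `n`, `p0`, `p1` (%, with bootstrap CIs
#'   `p0_ci_low/high`, `p1_ci_low/high` when `ci = TRUE`), `rd`, `nnt`,
#'   `rrr` and the rounded display columns.
#' @export
benefit_table <- function(predictions, records,
                          params = treatment_params(), ci = FALSE,
                          n_boot = 500L, seed = 1L) {
  p1 <- treated_probability(predictions, records$non_hdl_adj,
                            records$age_baseline, params)
  cells0 <- average_cells(predictions, records, ci = ci, n_boot = n_boot,
                          seed = seed)
  cells1 <- average_cells(p1, records, ci = ci, n_boot = n_boot,
                          seed = seed)
  out <- cells0[, c("sex", "age_group", "non_hdl_cat", "rf_burden", "n")]
  out$p0 <- cells0$p0
  out$p1 <- cells1$p0
  if (ci) {
    out$p0_ci_low <- cells0$ci_low; out$p0_ci_high <- cells0$ci_high
    out$p1_ci_low <- cells1$ci_low; out$p1_ci_high <- cells1$ci_high
  }
  ok <- !is.na(out$p0)
  ben <- nnt_rrr(out$p0[ok], out$p1[ok])
  for (cn in names(ben)) {
    out[[cn]] <- NA_real_
    out[[cn]][ok] <- ben[[cn]]
  }
  out
}
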