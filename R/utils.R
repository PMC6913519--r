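#' @importFrom stats rnorm rbinom runif rexp qnorm pnorm quantile sd
#'   setNames complete.cases aggregate loess predict coef vcov
#'   pchisq optim median as.formula
#' @importFrom tools md5sum
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

# Required columns of a subject table; `prepared` additionally requires the
# lipid-preparation columns.
check_records <- function(records, prepared = FALSE) {
  need <- c("subject_id", "cohort_id", "sex", "age_baseline", "bmi", "sbp",
            "smoking", "diabetes", "hypertension", "antihypertensive_med",
            "lipid_lowering_med", "total_chol", "hdl_chol",
            "followup_years", "event_cause")
  if (prepared) need <- c(need, "non_hdl", "non_hdl_adj", "non_hdl_cat")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("subject table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$followup_years < 0)) {
    stop("followup_years must be non-negative", call. = FALSE)
  }
  if (!all(records$event_cause %in% c(0L, 1L, 2L))) {
    stop("event_cause must be 0 (censored), 1 (CVD) or 2 (non-CVD death)",
         call. = FALSE)
  }
  invisible(records)
}

# Baseline age groups used throughout: <45, 45-59, >=60.
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 45, 60, Inf), right = FALSE,
      labels = c("<45", "45-59", ">=60"))
}

# Count of modifiable risk factors: daily smoking, arterial hypertension,
# diabetes, obesity (BMI >= 30 kg/m^2); burden dichotomised at >= 2.
rf_burden_of <- function(records) {
  n <- records$smoking + records$hypertension + records$diabetes +
    as.integer(records$bmi >= 30)
  factor(ifelse(n >= 2L, ">=2", "0-1"), levels = c("0-1", ">=2"))
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
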