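# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

demo_prepared <- function(n = 20000L, seed = 42L) {
  cached(sprintf("prep_%d_%d", n, seed),
         prepare_cohort(generate_cohort(n = n, seed = seed)))
}

demo_model <- function(n = 20000L, seed = 42L) {
  cached(sprintf("model_%d_%d", n, seed),
         suppressWarnings(fit_cause_specific_models(demo_prepared(n, seed))))
}

# Minimal valid subject table around given follow-up times and causes.
make_records <- function(time, cause, sex = "female", age_baseline = 50,
                         cohort_id = "C01") {
  n <- length(time)
  data.frame(
    subject_id = seq_len(n),
    cohort_id = rep_len(cohort_id, n),
    sex = factor(rep_len(sex, n), levels = c("female", "male")),
    age_baseline = rep_len(age_baseline, n),
    exam_year = 2000L, bmi = 25, sbp = 120,
    smoking = 0L, diabetes = 0L, hypertension = 0L,
    antihypertensive_med = 0L, lipid_lowering_med = 0L,
    total_chol = 5.6, hdl_chol = 1.3, ldl_chol = 3.7, weight = 1,
    followup_years = time, event_cause = as.integer(cause))
}

# Generator configuration with all covariate effects and frailty removed.
null_effect_config <- function() {
  cfg <- default_config()
  cfg$cvd_hazard$loghr[] <- 0
  cfg$death_hazard$loghr[] <- 0
  cfg$cohort_frailty_sd <- 0
  cfg
}

# Configuration whose CVD hazard uses exact per-category log hazard ratios.
categorical_truth_config <- function(loghr = c(0, 0.1, 0.35, 0.55, 0.8)) {
  cfg <- default_config()
  cfg$cvd_hazard$exposure_type <- "categorical"
  cfg$cvd_hazard$category_loghr <- loghr
  cfg
}

# Hand-built cause-specific model with fixed Weibull baselines and all Cox
# coefficients zero (so the linear predictor vanishes and the hazards are
# exactly the baselines). `b1`/`b2` are c(shape, scale); b2 = NULL drops
# the competing cause.
fake_model <- function(b1, b2 = NULL) {
  spec <- list(
    exposure = "spline", interactions = "sex", winsor = c(1.6, 8.5),
    breaks = nonhdl_breaks_mmol(), smooth_bmi_sbp = TRUE,
    nonhdl_spline = list(knots = c(3.5, 4.3, 5.2), boundary = c(1.6, 8.5)),
    bmi_spline = list(knots = c(23, 26, 29), boundary = c(15, 45)),
    sbp_spline = list(knots = c(115, 128, 142), boundary = c(80, 220)))
  proto <- prepare_cohort(make_records(1, 0L))
  X <- nonhdlrisk:::build_design(proto, spec)$X
  zero_fit <- function() {
    structure(list(fit = list(coefficients = setNames(numeric(ncol(X)),
                                                      colnames(X))),
                   spec = spec, n = 1L, n_events = 1L, cause = 1L,
                   timescale = "age", ties = "efron"),
              class = "nonhdl_coxfit")
  }
  rows <- expand.grid(sex = c("female", "male"), cohort = "C01",
                      cause = 1L, stringsAsFactors = FALSE)
  rows$shape <- b1[1L]; rows$scale <- b1[2L]
  rows$n_events <- 100L; rows$pooled <- FALSE
  baselines <- rows
  cox_death <- NULL
  if (!is.null(b2)) {
    rows2 <- rows
    rows2$cause <- 2L; rows2$shape <- b2[1L]; rows2$scale <- b2[2L]
    baselines <- rbind(rows, rows2)
    cox_death <- zero_fit()
  }
  structure(list(cox_cvd = zero_fit(), cox_death = cox_death,
                 baselines = baselines, horizon = 75,
                 eligible_ages = c(35, 70), breaks = nonhdl_breaks_mmol()),
            class = "cause_specific_model")
}
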