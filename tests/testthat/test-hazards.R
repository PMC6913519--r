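test_that("null lipid effect yields category HRs compatible with 1", {
  cfg <- default_config()
  cfg$cvd_hazard$loghr[["nonhdl"]] <- 0
  pr <- prepare_cohort(generate_cohort(cfg, n = 20000, seed = 81))
  fit <- suppressWarnings(fit_stratified_cox(pr, exposure = "categorical"))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- abs(beta / se)[sprintf("cat%d", 2:5)]
  expect_true(all(z < 3.29))  # 99.9% bands around the true null
})

test_that("category log-HR estimates recover a categorical truth", {
  truth <- c(0, 0.1, 0.35, 0.55, 0.8)
  pr <- prepare_cohort(generate_cohort(categorical_truth_config(truth),
                                       n = 30000, seed = 4))
  fit <- suppressWarnings(fit_stratified_cox(pr, exposure = "categorical"))
  est <- coef(fit)[sprintf("cat%d", 2:5)]
  expect_lt(max(abs(est - truth[2:5])), 0.3)
  expect_true(all(diff(est) > 0))
})

test_that("estimates are invariant to stratum duplication and relabelling", {
  pr <- demo_prepared(5000, 9)
  one <- suppressWarnings(fit_stratified_cox(pr, exposure = "categorical"))
  # two identical copies in two pseudo-cohorts: same partial-likelihood
  # maximiser as the single fit
  two <- pr
  two$subject_id <- two$subject_id + nrow(pr)
  two$cohort_id <- paste0(two$cohort_id, "_copy")
  both <- rbind(pr, two)
  fit2 <- suppressWarnings(fit_stratified_cox(both,
                                              exposure = "categorical"))
  expect_equal(coef(fit2), coef(one), tolerance = 1e-6)
  # relabelling cohorts leaves the stratified fit unchanged
  rel <- pr
  rel$cohort_id <- factor(paste0("Z", rel$cohort_id))
  fit3 <- suppressWarnings(fit_stratified_cox(rel,
                                              exposure = "categorical"))
  expect_equal(unname(coef(fit3)), unname(coef(one)), tolerance = 1e-10)
})

test_that("the fitted partial likelihood improves on the null model", {
  fit <- suppressWarnings(fit_stratified_cox(demo_prepared(5000, 9),
                                             exposure = "categorical"))
  expect_gte(fit$fit$loglik[2], fit$fit$loglik[1])
})

test_that("HR table assembly obeys reference and interaction contrasts", {
  pr <- demo_prepared()
  fit <- suppressWarnings(
    fit_stratified_cox(pr, exposure = "categorical",
                       interactions = c("sex", "age_group")))
  tab <- categorical_hr_table(fit, by_age_group = TRUE)
  expect_identical(nrow(tab), 2L * 3L * 5L)
  ref <- tab[tab$category == 1L, ]
  expect_true(all(ref$hr == 1 & ref$ci_low == 1 & ref$ci_high == 1))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  # male rows equal female log-HR plus the interaction coefficient
  beta <- coef(fit)
  f45 <- tab[tab$sex == "female" & tab$age_group == "<45" &
               tab$category == 3L, "hr"]
  m45 <- tab[tab$sex == "male" & tab$age_group == "<45" &
               tab$category == 3L, "hr"]
  expect_equal(log(m45) - log(f45), unname(beta["m_cat3"]))
  it <- attr(tab, "interaction_test")
  expect_identical(it$df, 8L)
  expect_true(it$p_value >= 0 && it$p_value <= 1)
  # without age-group rows the table is labelled by the reference group
  tab0 <- categorical_hr_table(fit, by_age_group = FALSE)
  expect_true(all(tab0$age_group == "<45"))
  plain <- suppressWarnings(fit_stratified_cox(pr,
                                               exposure = "categorical"))
  expect_error(categorical_hr_table(plain, by_age_group = TRUE),
               "age_group")
})

test_that("spline HR curve recovers a log-linear truth and winsorises", {
  pr <- demo_prepared()
  fit <- suppressWarnings(fit_stratified_cox(pr, exposure = "spline"))
  beta_true <- default_config()$cvd_hazard$loghr[["nonhdl"]]
  cur <- spline_hr_curve(fit, reference = 2.6,
                         grid = seq(2.6, 8.5, by = 0.05))
  expect_equal(cur$hr[cur$non_hdl == 2.6], 1, tolerance = 1e-12)
  # true log-linear curve exp(beta (x - 2.6)) inside the 95% band on the
  # well-populated central range
  central <- cur$non_hdl >= 2.6 & cur$non_hdl <= 6.5
  truth <- exp(beta_true * (cur$non_hdl - 2.6))
  expect_true(all(truth[central] >= cur$ci_low[central] &
                    truth[central] <= cur$ci_high[central]))
  # inputs beyond the bounds are clamped
  hi <- spline_hr_curve(fit, grid = c(8.5, 10))
  expect_equal(hi$hr[2], hi$hr[1])
  expect_error(spline_hr_curve(fit, reference = 1.0), "bounds")
  expect_error(spline_hr_curve(suppressWarnings(
    fit_stratified_cox(pr, exposure = "categorical"))), "spline")
})

test_that("confidence intervals attain nominal coverage in small samples", {
  truth <- c(0, 0.1, 0.35, 0.55, 0.8)
  cfg <- categorical_truth_config(truth)
  cfg$n_cohorts <- 2L
  set.seed(60)
  seeds <- sample.int(1e6, 200)
  covered <- vapply(seeds, function(s) {
    pr <- prepare_cohort(generate_cohort(cfg, n = 1500, seed = s))
    fit <- suppressWarnings(fit_stratified_cox(pr,
                                               exposure = "categorical"))
    b <- coef(fit)["cat5"]
    se <- sqrt(vcov(fit)["cat5", "cat5"])
    truth[5] >= b - 1.96 * se && truth[5] <= b + 1.96 * se
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
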