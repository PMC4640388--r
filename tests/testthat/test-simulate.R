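test_that("simulation is reproducible and seed-isolated", {
  m <- ydr_model()
  spec <- cohort_spec(n_subjects = 2000, random_seed = 7,
                      baseline_10yr_risk = 0.02)
  a <- suppressWarnings(simulate_cohort(spec, m))
  b <- suppressWarnings(simulate_cohort(spec, m))
  expect_identical(a, b)
  # a different seed changes the draw
  spec2 <- cohort_spec(n_subjects = 2000, random_seed = 8,
                       baseline_10yr_risk = 0.02)
  expect_false(identical(suppressWarnings(simulate_cohort(spec2, m))$chd_10yr, a$chd_10yr))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(suppressWarnings(simulate_cohort(spec, m))); after <- runif(5)
  expect_identical(before, after)
})

test_that("null effects reproduce the baseline incidence", {
  m <- ydr_model(binary_params(0.5, 1.0))
  spec <- cohort_spec(n_subjects = 20000, random_seed = 3,
                      baseline_10yr_risk = 0.021,
                      age_effect_or_per_year = 1.0)
  coh <- simulate_cohort(spec, m)
  ci <- binom.test(sum(coh$chd_10yr), nrow(coh),
                   conf.level = 0.99)$conf.int
  expect_gt(0.021, ci[1])
  expect_lt(0.021, ci[2])
})

test_that("factor levels are drawn at the specified prevalences", {
  m <- ydr_model(prevalence_source = "nhs")
  spec <- cohort_spec(n_subjects = 50000, random_seed = 21,
                      prevalence_source = "nhs",
                      baseline_10yr_risk = 0.003)
  coh <- suppressWarnings(simulate_cohort(spec, m))
  p <- m$params
  app <- ydrisk:::applicability_matrix(m, coh$age,
                                       smoking_level = coh$smoking)
  for (fid in unique(p$factor_id)) {
    rows <- p[p$factor_id == fid, ]
    obs <- coh[[fid]][app[, fid]]
    for (k in seq_len(nrow(rows))) {
      ci <- binom.test(sum(obs == rows$level_id[k]), length(obs),
                       conf.level = 0.999)$conf.int
      expect_gt(rows$nhs_prevalence[k], ci[1])
      expect_lt(rows$nhs_prevalence[k], ci[2])
    }
  }
})

test_that("baseline calibration matches closed forms and large-n checks", {
  # single null factor, no age effect: baseline equals the target exactly
  m0 <- ydr_model(binary_params(0.5, 1.0))
  spec0 <- cohort_spec(n_subjects = 100, random_seed = 2,
                       age_effect_or_per_year = 1.0)
  expect_equal(calibrate_baseline(spec0, m0, target = 0.021), 0.021,
               tolerance = 1e-6)
  # binary factor P=0.5, RR=2: expected risk is 1.5 b, so b = target/1.5
  m1 <- ydr_model(binary_params(0.5, 2.0))
  expect_equal(calibrate_baseline(spec0, m1, target = 0.03), 0.02,
               tolerance = 2e-3)
  # full consensus model: simulating at the calibrated baseline with an
  # independent seed lands within Monte-Carlo error of the target
  m <- ydr_model()
  spec <- cohort_spec(n_subjects = 100000, random_seed = 77,
                      prevalence_source = "nhs")
  b <- calibrate_baseline(spec, m, target = 0.021)
  spec_b <- cohort_spec(n_subjects = 100000, random_seed = 1234,
                        prevalence_source = "nhs", baseline_10yr_risk = b)
  coh <- suppressWarnings(simulate_cohort(spec_b, m))
  se <- sqrt(0.021 * 0.979 / nrow(coh))
  expect_lt(abs(mean(coh$chd_10yr) - 0.021), 3 * se)
  # unattainable target errors
  expect_error(calibrate_baseline(spec0, m0, target = 0.9999),
               "unattainable")
})

test_that("risk clamping is counted and warned about", {
  m <- ydr_model(binary_params(0.5, 10))
  spec <- cohort_spec(n_subjects = 500, random_seed = 9,
                      baseline_10yr_risk = 0.3)
  expect_warning(coh <- simulate_cohort(spec, m), "clamped")
  expect_gt(attr(coh, "clamped_n"), 0)
})

test_that("exclusion filters drop exactly the stated subjects", {
  m <- ydr_model(binary_params())
  raw <- data.frame(
    subject_id = 1:10, age = rep(50, 10),
    f1 = c("yes", "no", "yes", "no", "yes", "no", "yes", "no", "yes", "no"),
    chd_10yr = 0L,
    ffq_missing_items = c(0, 0, 0, 10, 0, 0, 2, 0, 0, 9),
    kcal_per_day = c(450, 3600, 2000, 2000, 500, 3500, 1800, 2100, 1900, 2200),
    prior_heart_disease = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  )
  out <- apply_exclusion_filters(raw, m)
  expect_equal(nrow(out), 6)
  log <- attr(out, "exclusion_log")
  expect_equal(log$n[log$reason == "prior_heart_disease"], 1)
  expect_equal(log$n[log$reason == "ffq_missing_items_ge10"], 1)
  expect_equal(log$n[log$reason == "kcal_outside_500_3500"], 2)
  expect_equal(log$n[log$reason == "retained"], 6)
  # kcal exactly 500 and 3500 are retained (strict thresholds)
  expect_true(all(c(500, 3500) %in% out$kcal_per_day))
  # all-clean table passes unchanged
  clean <- raw[raw$subject_id %in% c(5, 6, 7, 8, 9), ]
  out2 <- apply_exclusion_filters(clean, m)
  expect_equal(nrow(out2), 5)
  # a missing applicable factor is its own exclusion reason
  clean$f1[2] <- NA
  out3 <- apply_exclusion_filters(clean, m)
  expect_equal(nrow(out3), 4)
  log3 <- attr(out3, "exclusion_log")
  expect_equal(log3$n[log3$reason == "missing_risk_factor"], 1)
})

test_that("simulated cohorts score to mean relative risk near one", {
  # prevalences used for drawing match the scoring denominator, so the
  # numerator averages to the denominator within each applicability stratum
  m <- ydr_model(prevalence_source = "nhs")
  spec <- cohort_spec(n_subjects = 30000, random_seed = 31,
                      prevalence_source = "nhs",
                      baseline_10yr_risk = 0.003)
  scored <- score_cohort(suppressWarnings(simulate_cohort(spec, m)), m)
  mc_se <- sd(scored$ydr_rr) / sqrt(nrow(scored))
  expect_lt(abs(mean(scored$ydr_rr) - 1), 3 * mc_se)
})

test_that("age confounding makes top-score subjects younger", {
  m <- ydr_model()
  spec <- cohort_spec(n_subjects = 30000, random_seed = 41,
                      prevalence_source = "nhs",
                      baseline_10yr_risk = 0.01, age_confounding = TRUE)
  scored <- score_cohort(suppressWarnings(simulate_cohort(spec, m)), m)
  top <- as.integer(scored$ydr_category) >= 6
  expect_lt(mean(scored$age[top]), mean(scored$age[!top]))
})
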