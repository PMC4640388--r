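test_that("single-factor scoring matches the closed form", {
  m <- ydr_model(binary_params(0.5, 2.0))
  ref <- score_profile(50, list(f1 = "no"), m)
  expect_equal(ref$numerator, 1.0)
  expect_equal(ref$denominator, 1.5)
  expect_equal(ref$relative_risk, 1 / 1.5, tolerance = 1e-12)
  expect_equal(ref$category, "below_average")

  exp_ <- score_profile(50, list(f1 = "yes"), m)
  expect_equal(exp_$relative_risk, 2 / 1.5, tolerance = 1e-12)
  expect_equal(exp_$category, "above_average")

  # two independent factors: denominators multiply
  m2 <- ydr_model(two_factor_params())
  s2 <- score_profile(50, list(f1 = "no", f2 = "no"), m2)
  expect_equal(s2$denominator, 2.25, tolerance = 1e-12)
})

test_that("category boundaries have inclusive upper bounds", {
  expect_equal(as.character(ydr_category(c(0.2, 0.5, 0.9, 1.1, 2.1, 5.1))),
               c("very_much_below_average", "much_below_average",
                 "below_average", "about_average", "above_average",
                 "much_above_average"))
  expect_equal(as.character(ydr_category(5.1 + 1e-9)),
               "very_much_above_average")
  expect_equal(as.character(ydr_category(1e-6)), "very_much_below_average")
  expect_error(ydr_category(-1), "positive")
  # total, monotone step function
  rr <- sort(exp(runif(200, log(0.01), log(50))))
  cats <- ydr_category(rr)
  expect_false(anyNA(cats))
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("age gates the adiposity pair to exactly one term", {
  expect_equal(select_adiposity_factor(c(59, 60, 74)),
               c("bmi", "waist", "waist"))
  m <- ydr_model()
  base_levels <- list(
    smoking = "never", secondhand_smoke = "rare", multivitamin = "lt5wk",
    physical_activity = "lt3hwk", high_blood_pressure = "no",
    diabetes = "no", cholesterol = "le159", family_history = "no",
    fish = "lt2wk", fruits_vegetables = "lt5day", whole_grains = "lt3day",
    nuts = "lt3wk", saturated_fat = "lt2day", trans_fat = "lt5wk",
    unsaturated_fat = "lt5wk", alcohol = "none")
  s59 <- score_profile(59, c(base_levels, list(bmi = "lt25")), m)
  s60 <- score_profile(60, c(base_levels, list(waist = "le35in")), m)
  davg <- population_average_rr(m, c("bmi", "waist"))
  # swapping the adiposity factor rescales the denominator by the ratio of
  # the two population-average terms
  expect_equal(s59$denominator / s60$denominator,
               davg[["bmi"]] / davg[["waist"]], tolerance = 1e-12)
})

test_that("secondhand smoke contributes nothing for current smokers", {
  m <- ydr_model()
  levels_smoker <- list(
    bmi = "lt25", smoking = "current_le14", secondhand_smoke = "regular",
    multivitamin = "lt5wk", physical_activity = "lt3hwk",
    high_blood_pressure = "no", diabetes = "no", cholesterol = "le159",
    family_history = "no", fish = "lt2wk", fruits_vegetables = "lt5day",
    whole_grains = "lt3day", nuts = "lt3wk", saturated_fat = "lt2day",
    trans_fat = "lt5wk", unsaturated_fat = "lt5wk", alcohol = "none")
  with_sh <- score_profile(50, levels_smoker, m)
  levels_no_sh <- levels_smoker
  levels_no_sh$secondhand_smoke <- NULL
  without_sh <- score_profile(50, levels_no_sh, m)
  expect_identical(with_sh$numerator, without_sh$numerator)
  expect_identical(with_sh$denominator, without_sh$denominator)
  # a never smoker, by contrast, does carry the term
  levels_never <- levels_smoker
  levels_never$smoking <- "never"
  never <- score_profile(50, levels_never, m)
  davg <- population_average_rr(m, c("secondhand_smoke", "smoking"))
  expect_equal(never$denominator / without_sh$denominator,
               davg[["secondhand_smoke"]] / 1, tolerance = 1e-12)
})

test_that("missing applicable levels error unless imputation is requested", {
  m <- ydr_model(binary_params())
  coh <- data.frame(age = 50, f1 = NA_character_)
  expect_error(score_cohort(coh, m), "missing a level")
  imputed <- score_cohort(coh, m, impute_reference = TRUE)
  expect_equal(imputed$ydr_numerator, 1.0)
  expect_error(score_cohort(data.frame(age = 50, f1 = "typo"), m),
               "unknown level")
  expect_error(score_cohort(data.frame(age = 50), m), "factor column")
})

test_that("scoring is deterministic and monotone in the assigned level", {
  m <- ydr_model()
  raw <- oracle_read_params()
  set.seed(401)
  for (i in 1:25) {
    prof <- oracle_random_profile(raw)
    s1 <- score_profile(prof$age, as.list(prof$levels), m)
    s2 <- score_profile(prof$age, as.list(prof$levels), m)
    expect_identical(s1, s2)
    # raise the RR assigned to one of the subject's own (non-reference)
    # levels, all else fixed: the score must not decrease
    p <- m$params
    at_exposed <- vapply(unique(p$factor_id), function(fid) {
      rows <- p[p$factor_id == fid, ]
      !rows$is_reference[rows$level_id == prof$levels[[fid]]]
    }, logical(1))
    candidates <- names(at_exposed)[at_exposed]
    if (!length(candidates)) next
    fid <- sample(candidates, 1)
    p2 <- p
    hit <- p2$factor_id == fid & p2$level_id == prof$levels[[fid]]
    p2$consensus_rr[hit] <- p2$consensus_rr[hit] * runif(1, 1, 2)
    s3 <- score_profile(prof$age, as.list(prof$levels), ydr_model(p2))
    expect_gte(s3$relative_risk, s1$relative_risk - 1e-12)
  }
})

test_that("scores agree with the brute-force oracle on random profiles", {
  m <- ydr_model()
  raw <- oracle_read_params()
  set.seed(402)
  n_bad <- 0
  for (i in 1:1000) {
    prof <- oracle_random_profile(raw)
    got <- score_profile(prof$age, as.list(prof$levels), m)
    want <- oracle_score(prof$age, prof$levels, raw)
    rel <- abs(got$relative_risk - want$rr) / want$rr
    if (rel > 1e-12 ||
        abs(got$numerator - want$numerator) > 1e-12 * want$numerator ||
        abs(got$denominator - want$denominator) > 1e-12 * want$denominator) {
      n_bad <- n_bad + 1
    }
  }
  expect_equal(n_bad, 0)
})

test_that("vectorised denominators match per-profile scoring", {
  m <- ydr_model()
  spec <- cohort_spec(n_subjects = 200, random_seed = 5,
                      baseline_10yr_risk = 0.02)
  coh <- suppressWarnings(simulate_cohort(spec, m))
  scored <- score_cohort(coh, m)
  expect_equal(score_denominator(coh, m), scored$ydr_denominator,
               tolerance = 1e-12)
  expect_equal(scored$ydr_rr, scored$ydr_numerator / scored$ydr_denominator)
  expect_identical(as.character(scored$ydr_category),
                   as.character(ydr_category(scored$ydr_rr)))
})
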