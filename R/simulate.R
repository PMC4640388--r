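# Deterministic child seeds so that ages, factor levels, outcomes and
# auxiliary columns come from independent reproducible streams.
child_seed <- function(seed, stage) {
  as.integer(((as.double(seed) %% 2147483647) * 7919 + stage * 104729) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic cohort
#'
#' Defines the conditions for [simulate_cohort()]. The defaults emulate
#' the structure of the validation cohort: 55,802 women aged 47 to 74,
#' factor prevalences as observed in that cohort, multiplicative
#' consensus relative risks on the 10-year risk, and an overall 10-year
#' coronary-heart-disease incidence near 2.1%.
#'
#' @param n_subjects Number of subjects.
#' @param random_seed Master seed; all stages derive child streams from it.
#' @param prevalence_source `"nhs"`, `"us"` — prevalence column used to
#'   draw factor levels.
#' @param effect_source Relative-risk column driving the outcome
#'   (`"consensus"`, `"observed"`, `"observed_multivariate"`).
#' @param effect_scale `"risk"` multiplies the factor effects on the risk
#'   scale (the scoring equation's semantics; risks are clamped below 1
#'   with a warning count); `"odds"` multiplies them on the odds scale, so
#'   the logistic-model odds ratio is exactly the simulated effect.
#' @param baseline_10yr_risk 10-year risk of an all-reference subject of
#'   median age. `NULL` calibrates it so the expected marginal incidence
#'   equals `target_incidence` (see [calibrate_baseline()]).
#' @param target_incidence Marginal incidence target used when
#'   `baseline_10yr_risk` is `NULL`.
#' @param age_range Inclusive integer age range, uniform by default.
#' @param age_effect_or_per_year Per-year odds multiplier for the outcome;
#'   the default 1.08 reproduces an incidence gradient from roughly 0.8%
#'   below age 55 to 4% above 70, as in the validation cohort.
#' @param age_confounding If `TRUE`, current-smoking and obesity
#'   prevalences decline with age (exposure weight
#'   `exp(-confounding_strength * (age - 60))`, reference level absorbing
#'   the shift), making the top score categories younger on average and
#'   inducing age confounding of the category odds ratios.
#' @param confounding_strength Per-year log-weight of the confounding rule.
#' @param auxiliary Also draw screening columns `ffq_missing_items`,
#'   `kcal_per_day` and `prior_heart_disease` so the exclusion filters of
#'   [apply_exclusion_filters()] can be exercised.
#' @return A `ydr_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 55802L,
                        random_seed = 1L,
                        prevalence_source = c("nhs", "us"),
                        effect_source = c("consensus", "observed",
                                          "observed_multivariate"),
                        effect_scale = c("risk", "odds"),
                        baseline_10yr_risk = NULL,
                        target_incidence = 0.021,
                        age_range = c(47L, 74L),
                        age_effect_or_per_year = 1.08,
                        age_confounding = FALSE,
                        confounding_strength = 0.04,
                        auxiliary = FALSE) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[1] <= age_range[2], age_effect_or_per_year > 0,
            target_incidence > 0, target_incidence < 1)
  if (!is.null(baseline_10yr_risk)) {
    stopifnot(baseline_10yr_risk > 0, baseline_10yr_risk < 1)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      random_seed = as.integer(random_seed),
      prevalence_source = match.arg(prevalence_source),
      effect_source = match.arg(effect_source),
      effect_scale = match.arg(effect_scale),
      baseline_10yr_risk = baseline_10yr_risk,
      target_incidence = target_incidence,
      age_range = as.integer(age_range),
      age_effect_or_per_year = age_effect_or_per_year,
      age_confounding = isTRUE(age_confounding),
      confounding_strength = confounding_strength,
      auxiliary = isTRUE(auxiliary)
    ),
    class = "ydr_cohort_spec"
  )
}

# Levels whose prevalence the age-confounding rule shifts: current smoking
# and obesity, the exposures reported to make the top categories younger.
.confounded_levels <- data.frame(
  factor_id = c("smoking", "smoking", "smoking", "bmi"),
  level_id = c("current_ge25", "current_15to24", "current_le14", "ge29"),
  stringsAsFactors = FALSE
)

# Per-subject level probabilities for one factor (n x K), age-modulated
# when the confounding hook is on.
level_prob_matrix <- function(spec, fid, levels, prev, is_ref, age) {
  n <- length(age)
  pm <- matrix(prev, nrow = n, ncol = length(prev), byrow = TRUE)
  if (spec$age_confounding) {
    shift <- levels %in%
      .confounded_levels$level_id[.confounded_levels$factor_id == fid]
    if (any(shift)) {
      w <- exp(-spec$confounding_strength * (age - 60))
      pm[, shift] <- pm[, shift] * w
      pm[, is_ref] <- pmax(1 - rowSums(pm[, !is_ref, drop = FALSE]), 0)
    }
  }
  pm
}

# Draw one level per row from an n x K probability matrix.
sample_levels <- function(pm, levels) {
  cum <- pm
  for (k in seq_len(ncol(pm))[-1]) cum[, k] <- cum[, k - 1] + cum[, k]
  u <- stats::runif(nrow(pm)) * cum[, ncol(pm)]
  idx <- rowSums(u > cum) + 1L
  levels[idx]
}

# Product of the subject's effect RRs over applicable factors, and the
# per-subject odds multiplier for age.
true_effect_product <- function(spec, model, cohort) {
  effect_col <- switch(spec$effect_source,
    consensus = "consensus_rr",
    observed = "observed_rr",
    observed_multivariate = "observed_rr_mv"
  )
  sim_model <- ydr_model(model$params,
                         prevalence_source = spec$prevalence_source,
                         effect_source = spec$effect_source)
  stopifnot(effect_col %in% names(model$params))
  scored <- score_cohort(cohort, sim_model)
  scored$ydr_numerator
}

outcome_probability <- function(spec, baseline, effect_product, age) {
  age_mult <- spec$age_effect_or_per_year^(age - 60)
  if (spec$effect_scale == "risk") {
    r <- baseline * effect_product
    clamped <- sum(r >= 1)
    r <- pmin(r, 1 - 1e-12)
    odds <- r / (1 - r) * age_mult
    p <- odds / (1 + odds)
    attr(p, "clamped_n") <- clamped
  } else {
    odds <- baseline / (1 - baseline) * effect_product * age_mult
    p <- odds / (1 + odds)
    attr(p, "clamped_n") <- 0L
  }
  p
}

#' Simulate a synthetic cohort
#'
#' Draws ages uniformly on the spec's range, factor levels independently
#' per factor at the spec's prevalences (age-modulated when the
#' confounding hook is on), and a binary 10-year outcome whose probability
#' multiplies the subject's effect relative risks and a per-year age odds
#' multiplier onto the baseline risk. Inapplicable factor cells (BMI at 60
#' and over, waist below 60, secondhand smoke for current smokers) are
#' `NA`. Fully reproducible given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param model A [ydr_model()] supplying the factor definitions.
#' @return A cohort `data.frame` with columns `subject_id`, `age`, one
#'   column per factor, `chd_10yr`, and (if requested) the auxiliary
#'   screening columns. Attributes: `spec`, `baseline_10yr_risk`,
#'   `clamped_n` (subjects whose risk-scale product was clamped below 1).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 500, random_seed = 7,
#'                     baseline_10yr_risk = 0.01)
#' coh <- simulate_cohort(spec, ydr_model())
#' mean(coh$chd_10yr)
simulate_cohort <- function(spec, model = ydr_model()) {
  stopifnot(inherits(spec, "ydr_cohort_spec"), inherits(model, "ydr_model"))
  n <- spec$n_subjects
  p <- model$params
  prev_col <- paste0(spec$prevalence_source, "_prevalence")

  age <- with_seed(child_seed(spec$random_seed, 1L), {
    sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  })

  fids <- unique(p$factor_id)
  cohort <- data.frame(subject_id = seq_len(n), age = age)
  with_seed(child_seed(spec$random_seed, 2L), {
    for (fid in fids) {
      rows <- p$factor_id == fid
      pm <- level_prob_matrix(spec, fid, p$level_id[rows], p[[prev_col]][rows],
                              p$is_reference[rows], age)
      cohort[[fid]] <- sample_levels(pm, p$level_id[rows])
    }
  })
  # blank out inapplicable cells
  app <- applicability_matrix(model, age, smoking_level = cohort$smoking)
  for (fid in fids) cohort[[fid]][!app[, fid]] <- NA_character_

  baseline <- spec$baseline_10yr_risk
  if (is.null(baseline)) {
    baseline <- calibrate_baseline(spec, model, spec$target_incidence)
  }
  eff <- true_effect_product(spec, model, cohort)
  prob <- outcome_probability(spec, baseline, eff, age)
  clamped <- attr(prob, "clamped_n")
  if (clamped > 0) {
    warning(clamped, " subject(s) had risk-scale product >= 1; clamped",
            call. = FALSE)
  }
  cohort$chd_10yr <- with_seed(child_seed(spec$random_seed, 3L), {
    stats::rbinom(n, 1L, as.numeric(prob))
  })

  if (spec$auxiliary) {
    aux <- with_seed(child_seed(spec$random_seed, 4L), {
      data.frame(
        ffq_missing_items = ifelse(stats::runif(n) < 0.03,
                                   sample(10:20, n, replace = TRUE),
                                   stats::rpois(n, 0.5)),
        kcal_per_day = round(stats::rnorm(n, 1800, 430)),
        prior_heart_disease = stats::rbinom(n, 1L, 0.05)
      )
    })
    cohort <- cbind(cohort, aux)
  }

  attr(cohort, "spec") <- spec
  attr(cohort, "baseline_10yr_risk") <- baseline
  attr(cohort, "clamped_n") <- clamped
  cohort
}

#' Calibrate the baseline risk to a target marginal incidence
#'
#' Root-finds the all-reference baseline 10-year risk such that the
#' expected marginal incidence over the spec's factor and age
#' distributions equals `target`. The expectation is evaluated over a
#' large deterministic Monte-Carlo draw of profiles (the risk is not
#' separable once clamping and the odds-scale age effect enter), then
#' inverted with [stats::uniroot()].
#'
#' @inheritParams simulate_cohort
#' @param target Target marginal incidence in (0, 1).
#' @param n_mc Monte-Carlo profile draw used for the expectation.
#' @param tol Tolerance on the achieved expected incidence.
#' @return The calibrated baseline risk (scalar).
#' @export
calibrate_baseline <- function(spec, model = ydr_model(),
                               target = spec$target_incidence,
                               n_mc = 200000L, tol = 1e-4) {
  stopifnot(target > 0, target < 1)
  mc_spec <- spec
  mc_spec$n_subjects <- as.integer(n_mc)
  mc_spec$random_seed <- child_seed(spec$random_seed, 9L)
  mc_spec$auxiliary <- FALSE

  n <- mc_spec$n_subjects
  p <- model$params
  prev_col <- paste0(mc_spec$prevalence_source, "_prevalence")
  age <- with_seed(child_seed(mc_spec$random_seed, 1L), {
    sample(seq(mc_spec$age_range[1], mc_spec$age_range[2]), n, replace = TRUE)
  })
  cohort <- data.frame(subject_id = seq_len(n), age = age)
  with_seed(child_seed(mc_spec$random_seed, 2L), {
    for (fid in unique(p$factor_id)) {
      rows <- p$factor_id == fid
      pm <- level_prob_matrix(mc_spec, fid, p$level_id[rows],
                              p[[prev_col]][rows], p$is_reference[rows], age)
      cohort[[fid]] <- sample_levels(pm, p$level_id[rows])
    }
  })
  app <- applicability_matrix(model, age, smoking_level = cohort$smoking)
  for (fid in unique(p$factor_id)) cohort[[fid]][!app[, fid]] <- NA_character_
  eff <- true_effect_product(mc_spec, model, cohort)

  f <- function(b) {
    mean(as.numeric(outcome_probability(mc_spec, b, eff, age))) - target
  }
  upper <- min(0.99, 1 / stats::quantile(eff, 0.5))
  if (f(upper) < 0) {
    stop("target incidence ", target, " unattainable for this model",
         call. = FALSE)
  }
  root <- stats::uniroot(f, lower = 1e-10, upper = upper, tol = 1e-10)
  achieved <- f(root$root) + target
  if (abs(achieved - target) > tol) {
    stop("calibration failed: achieved ", signif(achieved, 6),
         " vs target ", target, call. = FALSE)
  }
  root$root
}

#' Apply the study's exclusion filters
#'
#' Drops subjects with prior heart disease, 10 or more missing
#' food-frequency items, daily energy intake below 500 or above 3500
#' kilocalories (exactly 500 and 3500 are retained; the thresholds are
#' strict), or a missing level for any applicable risk factor. Auxiliary
#' columns that are absent simply cannot trigger their filter. Each
#' subject is counted once, under the first filter (in the order above)
#' that removes it.
#'
#' @param cohort A cohort `data.frame`, optionally carrying
#'   `prior_heart_disease`, `ffq_missing_items`, `kcal_per_day`.
#' @param model A [ydr_model()] used to decide factor applicability;
#'   `NULL` skips the missing-factor filter.
#' @return The filtered cohort, with attribute `exclusion_log`: a
#'   `data.frame` of per-reason exclusion counts.
#' @export
apply_exclusion_filters <- function(cohort, model = ydr_model()) {
  n <- nrow(cohort)
  excluded <- rep(NA_character_, n)
  mark <- function(cond, reason) {
    hit <- is.na(excluded) & !is.na(cond) & cond
    excluded[hit] <<- reason
  }
  if ("prior_heart_disease" %in% names(cohort)) {
    mark(cohort$prior_heart_disease == 1, "prior_heart_disease")
  }
  if ("ffq_missing_items" %in% names(cohort)) {
    mark(cohort$ffq_missing_items >= 10, "ffq_missing_items_ge10")
  }
  if ("kcal_per_day" %in% names(cohort)) {
    mark(cohort$kcal_per_day < 500 | cohort$kcal_per_day > 3500,
         "kcal_outside_500_3500")
  }
  if (!is.null(model)) {
    app <- applicability_matrix(model, cohort$age,
                                smoking_level = cohort[["smoking"]])
    fids <- colnames(app)
    present <- intersect(fids, names(cohort))
    miss <- rep(FALSE, n)
    for (fid in fids) {
      lev <- if (fid %in% present) cohort[[fid]] else NA
      miss <- miss | (app[, fid] & is.na(lev))
    }
    mark(miss, "missing_risk_factor")
  }
  reasons <- c("prior_heart_disease", "ffq_missing_items_ge10",
               "kcal_outside_500_3500", "missing_risk_factor")
  log <- data.frame(
    reason = c(reasons, "retained"),
    n = c(vapply(reasons, function(r) sum(excluded == r, na.rm = TRUE),
                 integer(1)),
          sum(is.na(excluded))),
    stringsAsFactors = FALSE
  )
  out <- cohort[is.na(excluded), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  out
}
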