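#' Score a cohort with the relative-risk equation
#'
#' For each subject, the 10-year relative risk of coronary heart disease
#' compared with an average person of the same age and sex is
#' \deqn{RR = \frac{\prod_f RR_{l(f)}}{\prod_f \left[\sum_k P_{f,k} RR_{f,k}\right]}}
#' where the products run over the factors applicable to that subject
#' (BMI below age 60 / waist at 60 and over; secondhand smoke only for
#' never and past smokers), \eqn{RR_{l(f)}} is the relative risk assigned
#' to the subject's level of factor \eqn{f}, and the denominator terms are
#' the population-average relative risks of [population_average_rr()].
#' The score is then binned into the seven categories of
#' [ydr_categories()].
#'
#' A subject missing a level for an applicable factor is an error by
#' default, mirroring the validation study's exclusion of such subjects;
#' `impute_reference = TRUE` instead assigns the factor's reference level.
#'
#' @param cohort A cohort `data.frame` with columns `age` and one column
#'   per factor id holding level ids (see [read_cohort()]).
#' @param model A [ydr_model()].
#' @param impute_reference Replace missing levels of applicable factors
#'   with the reference level instead of erroring.
#' @return The cohort with columns `ydr_numerator`, `ydr_denominator`,
#'   `ydr_rr` and `ydr_category` (ordered factor) appended.
#' @export
#' @examples
#' m <- ydr_model()
#' coh <- read_cohort(ydr_extdata("cohort_synthetic_example.csv"), model = m)
#' head(score_cohort(coh, m)[, c("age", "ydr_rr", "ydr_category")])
score_cohort <- function(cohort, model = ydr_model(),
                         impute_reference = FALSE) {
  stopifnot(inherits(model, "ydr_model"), is.data.frame(cohort))
  if (!"age" %in% names(cohort)) {
    stop("cohort lacks mandatory column: age", call. = FALSE)
  }
  p <- model$params
  fids <- unique(p$factor_id)
  missing_cols <- setdiff(fids, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks factor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  app <- applicability_matrix(model, cohort$age,
                              smoking_level = cohort[["smoking"]])
  num <- rep(1, n)
  denom <- rep(1, n)
  davg <- population_average_rr(model, fids)
  for (fid in fids) {
    rows <- p$factor_id == fid
    lev <- as.character(cohort[[fid]])
    idx <- match(lev, p$level_id[rows])
    unknown <- !is.na(lev) & is.na(idx)
    if (any(unknown)) {
      stop("unknown level '", lev[which(unknown)[1]], "' for factor '",
           fid, "' (row ", which(unknown)[1], ")", call. = FALSE)
    }
    applicable <- app[, fid]
    miss <- applicable & is.na(idx)
    if (any(miss)) {
      if (!impute_reference) {
        stop(sum(miss), " subject(s) missing a level for applicable ",
             "factor '", fid, "' (first at row ", which(miss)[1],
             "); exclude them or use impute_reference = TRUE",
             call. = FALSE)
      }
      idx[miss] <- which(p$is_reference[rows])
    }
    rr_lev <- p[[model$effect_col]][rows][idx]
    num <- num * ifelse(applicable, rr_lev, 1)
    denom <- denom * ifelse(applicable, davg[[fid]], 1)
  }
  cohort$ydr_numerator <- num
  cohort$ydr_denominator <- denom
  cohort$ydr_rr <- num / denom
  cohort$ydr_category <- ydr_category(cohort$ydr_rr)
  cohort
}

#' Score denominator for one or more profiles
#'
#' The product of population-average relative risks over the factors
#' applicable to each profile.
#'
#' @inheritParams score_cohort
#' @return Numeric vector of denominators, one per cohort row.
#' @export
score_denominator <- function(cohort, model = ydr_model()) {
  stopifnot(inherits(model, "ydr_model"))
  app <- applicability_matrix(model, cohort$age,
                              smoking_level = cohort[["smoking"]])
  davg <- population_average_rr(model)[colnames(app)]
  as.numeric(exp(app %*% log(davg)))
}

#' Score a single subject
#'
#' Convenience wrapper around [score_cohort()] for one profile.
#'
#' @param age Age in years.
#' @param levels Named list or vector mapping factor ids to level ids;
#'   inapplicable factors may be omitted.
#' @inheritParams score_cohort
#' @return A list with `numerator`, `denominator`, `relative_risk` and
#'   `category`.
#' @export
score_profile <- function(age, levels, model = ydr_model(),
                          impute_reference = FALSE) {
  fids <- unique(model$params$factor_id)
  row <- as.list(rep(NA_character_, length(fids)))
  names(row) <- fids
  for (fid in names(levels)) row[[fid]] <- as.character(levels[[fid]])
  cohort <- cbind(data.frame(age = age), as.data.frame(row,
                  stringsAsFactors = FALSE))
  scored <- score_cohort(cohort, model, impute_reference = impute_reference)
  list(
    numerator = scored$ydr_numerator,
    denominator = scored$ydr_denominator,
    relative_risk = scored$ydr_rr,
    category = as.character(scored$ydr_category)
  )
}
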