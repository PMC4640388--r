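#' Construct a relative-risk scoring model
#'
#' Bundles a validated risk-factor parameter table with the choices that
#' fix the score: which prevalence column anchors the denominator (the
#' deployed tool uses estimated U.S. prevalences; the cohort-observed
#' column can be swapped in for sensitivity analyses) and which relative
#' risks feed the numerator (consensus by default; the cohort-estimated
#' unadjusted or multivariate columns are alternatives when present).
#'
#' The seven ordered risk categories, from "very much below average"
#' (RR <= 0.2) to "very much above average" (RR > 5.1), are part of the
#' model; their cutpoints are contiguous half-open intervals with
#' inclusive upper bounds covering (0, Inf).
#'
#' @param params Parameter table as returned by [read_params()].
#' @param prevalence_source `"us"` or `"nhs"`: prevalence column used for
#'   the population-average denominator.
#' @param effect_source `"consensus"`, `"observed"` or
#'   `"observed_multivariate"`: relative-risk column used for scoring.
#' @return An object of class `ydr_model`.
#' @export
#' @examples
#' m <- ydr_model()
#' population_average_rr(m, "diabetes")
ydr_model <- function(params = read_params(),
                      prevalence_source = c("us", "nhs"),
                      effect_source = c("consensus", "observed",
                                        "observed_multivariate")) {
  prevalence_source <- match.arg(prevalence_source)
  effect_source <- match.arg(effect_source)
  params <- validate_params(params)
  effect_col <- switch(effect_source,
    consensus = "consensus_rr",
    observed = "observed_rr",
    observed_multivariate = "observed_rr_mv"
  )
  if (!effect_col %in% names(params)) {
    stop("parameter table has no '", effect_col, "' column required for ",
         "effect_source = '", effect_source, "'", call. = FALSE)
  }
  structure(
    list(
      params = params,
      prevalence_source = prevalence_source,
      effect_source = effect_source,
      prevalence_col = paste0(prevalence_source, "_prevalence"),
      effect_col = effect_col,
      categories = ydr_categories()
    ),
    class = "ydr_model"
  )
}

#' @export
print.ydr_model <- function(x, ...) {
  cat("Relative-risk scoring model (ydr_model)\n")
  cat("  factors:           ", length(unique(x$params$factor_id)),
      " (", nrow(x$params), " levels)\n", sep = "")
  cat("  prevalence source: ", x$prevalence_source, "\n", sep = "")
  cat("  effect source:     ", x$effect_source, "\n", sep = "")
  invisible(x)
}

#' The seven risk-score categories
#'
#' @return A `data.frame` with columns `category` (machine label),
#'   `label` (display label), `lower` (exclusive) and `upper` (inclusive)
#'   relative-risk bounds.
#' @export
ydr_categories <- function() {
  data.frame(
    category = c("very_much_below_average", "much_below_average",
                 "below_average", "about_average", "above_average",
                 "much_above_average", "very_much_above_average"),
    label = c("Very much below average", "Much below average",
              "Below average", "About average", "Above average",
              "Much above average", "Very much above average"),
    lower = c(0, 0.2, 0.5, 0.9, 1.1, 2.1, 5.1),
    upper = c(0.2, 0.5, 0.9, 1.1, 2.1, 5.1, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign relative risks to risk categories
#'
#' Upper bounds are inclusive: a score of exactly 1.1 is "about average"
#' and exactly 5.1 is "much above average".
#'
#' @param rr Numeric vector of positive relative risks.
#' @return An ordered factor over the seven category labels.
#' @export
ydr_category <- function(rr) {
  if (any(is.finite(rr) & rr <= 0)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  cats <- ydr_categories()
  cut(rr, breaks = c(0, cats$upper), labels = cats$category,
      right = TRUE, ordered_result = TRUE)
}

#' Which adiposity factor applies at a given age
#'
#' Body mass index is assessed below age 60 and waist circumference at
#' age 60 and above; each subject contributes exactly one of the pair.
#'
#' @param age Integer vector of ages in years.
#' @return Character vector, `"bmi"` or `"waist"`.
#' @export
select_adiposity_factor <- function(age) {
  stopifnot(all(age >= 0))
  ifelse(age < 60, "bmi", "waist")
}

# factor_id -> applicability rule, one entry per factor
factor_applicability <- function(model) {
  p <- model$params
  idx <- !duplicated(p$factor_id)
  stats::setNames(p$applicability[idx], p$factor_id[idx])
}

# Evaluate applicability rules for each subject x factor.
# `smoking_level` feeds the not_current_smoker rule: a subject is a current
# smoker when that factor's level id starts with "current".
applicability_matrix <- function(model, age, smoking_level = NULL) {
  rules <- factor_applicability(model)
  n <- length(age)
  if ("not_current_smoker" %in% rules && is.null(smoking_level)) {
    stop("applicability rule 'not_current_smoker' needs the smoking level",
         call. = FALSE)
  }
  out <- matrix(TRUE, nrow = n, ncol = length(rules),
                dimnames = list(NULL, names(rules)))
  for (fid in names(rules)) {
    out[, fid] <- switch(rules[[fid]],
      "always" = rep(TRUE, n),
      "age<60" = age < 60,
      "age>=60" = age >= 60,
      # a missing smoking level counts as non-current; such a subject is
      # already flagged through the smoking factor itself
      "not_current_smoker" = {
        sl <- as.character(smoking_level)
        is.na(sl) | !startsWith(sl, "current")
      }
    )
  }
  out
}

#' Population-average relative risk of a factor
#'
#' The prevalence-weighted mean relative risk across a factor's levels,
#' \eqn{\sum_k P_k RR_k}, with the reference contributing
#' \eqn{(1 - \sum P_{exposed}) \times 1}. For a binary factor this is the
#' familiar \eqn{P \cdot RR + (1 - P)}. Dividing an individual's risk-factor
#' product by the product of these terms anchors the population-average
#' person at a relative risk of 1.
#'
#' @param model A [ydr_model()].
#' @param factor_id One or more factor ids; default all factors.
#' @return Named numeric vector of population-average relative risks.
#' @export
population_average_rr <- function(model, factor_id = NULL) {
  stopifnot(inherits(model, "ydr_model"))
  p <- model$params
  if (is.null(factor_id)) factor_id <- unique(p$factor_id)
  bad <- setdiff(factor_id, p$factor_id)
  if (length(bad)) {
    stop("unknown factor id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prev <- p[[model$prevalence_col]]
  rr <- p[[model$effect_col]]
  avg <- tapply(prev * rr, p$factor_id, sum)
  out <- as.numeric(avg[factor_id])
  names(out) <- factor_id
  out
}
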