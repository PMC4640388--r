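#' Tabulate subjects and cases by risk category
#'
#' @param scored A scored cohort (see [score_cohort()]) with columns
#'   `ydr_category` and `chd_10yr`.
#' @return A `data.frame` with one row per category (all seven, in order;
#'   empty categories count 0): `category`, `n`, `cases`, `pct`.
#' @export
category_counts <- function(scored) {
  stopifnot(all(c("ydr_category", "chd_10yr") %in% names(scored)))
  cats <- ydr_categories()$category
  cat_f <- factor(as.character(scored$ydr_category), levels = cats)
  n <- as.integer(table(cat_f))
  cases <- as.integer(tapply(scored$chd_10yr, cat_f, sum, default = 0L))
  out <- data.frame(category = cats, n = n, cases = cases,
                    pct = 100 * n / sum(n), stringsAsFactors = FALSE)
  validate_counts(out)
}

validate_counts <- function(counts) {
  stopifnot(all(c("category", "n", "cases") %in% names(counts)),
            all(counts$cases >= 0), all(counts$cases <= counts$n))
  if (sum(counts$cases) < 1 || sum(counts$n - counts$cases) < 1) {
    stop("count table needs at least one case and one non-case",
         call. = FALSE)
  }
  counts
}

#' Closed-form category odds ratios
#'
#' For a logistic model whose only predictors are indicators of a single
#' categorical variable, the maximum-likelihood odds ratios equal the
#' empirical odds ratios of the 2x2 margins, so they can be read directly
#' off the count table:
#' \deqn{OR_k = \frac{cases_k / (n_k - cases_k)}{cases_{ref} / (n_{ref} - cases_{ref})}}
#' with Wald confidence limits on the log scale using the variance
#' \eqn{1/a + 1/b + 1/c + 1/d} over the four cells. This is the exact
#' oracle for [logistic_category_model()] without age adjustment.
#'
#' Zero cells yield 0 or infinite estimates/bounds and are flagged via the
#' `zero_cell` column rather than corrected; no continuity correction is
#' applied.
#'
#' @param counts A count table from [category_counts()] (or the packaged
#'   published counts, see [read_category_counts()]).
#' @param reference Reference category label.
#' @return A `data.frame` with columns `category`, `n`, `cases`, `or`,
#'   `ci_low`, `ci_high`, `se_log`, `zero_cell`; the reference row has
#'   `or = 1` and `NA` limits.
#' @export
closed_form_category_or <- function(counts, reference = "about_average") {
  counts <- validate_counts(counts)
  if (!reference %in% counts$category) {
    stop("reference category '", reference, "' not in count table",
         call. = FALSE)
  }
  ref <- counts[counts$category == reference, ]
  a_ref <- ref$cases
  b_ref <- ref$n - ref$cases
  if (a_ref < 1 || b_ref < 1) {
    stop("reference category needs at least one case and one non-case",
         call. = FALSE)
  }
  a <- counts$cases
  b <- counts$n - counts$cases
  or <- (a / b) / (a_ref / b_ref)
  zero <- (a == 0) | (b == 0)
  se <- sqrt(1 / a + 1 / b + 1 / a_ref + 1 / b_ref)
  z <- stats::qnorm(0.975)
  out <- data.frame(
    category = counts$category, n = counts$n, cases = counts$cases,
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    se_log = se,
    zero_cell = zero,
    stringsAsFactors = FALSE
  )
  is_ref <- out$category == reference
  out$or[is_ref] <- 1
  out$ci_low[is_ref] <- NA_real_
  out$ci_high[is_ref] <- NA_real_
  out$se_log[is_ref] <- NA_real_
  attr(out, "reference") <- reference
  out
}

#' Logistic model of outcome on risk category
#'
#' Fits `chd_10yr ~ category` (optionally `+ age` as a continuous
#' covariate) by maximum likelihood and returns per-category odds ratios
#' against the reference, with Wald confidence limits. Without age
#' adjustment the estimates agree with [closed_form_category_or()] to
#' numerical precision.
#'
#' @param scored A scored cohort with `ydr_category`, `chd_10yr` and (for
#'   `adjust_age = TRUE`) `age`.
#' @param adjust_age Adjust for age as a continuous variable.
#' @param reference Reference category.
#' @return A `data.frame` as in [closed_form_category_or()] plus a
#'   `separation` flag; attribute `fit` carries the `glm` object.
#' @export
logistic_category_model <- function(scored, adjust_age = FALSE,
                                    reference = "about_average") {
  stopifnot(all(c("ydr_category", "chd_10yr") %in% names(scored)))
  cat_chr <- as.character(scored$ydr_category)
  present <- intersect(ydr_categories()$category, unique(cat_chr))
  if (length(present) < 2) {
    stop("need at least two occupied categories to fit a contrast",
         call. = FALSE)
  }
  if (!reference %in% present) {
    stop("reference category '", reference, "' is empty", call. = FALSE)
  }
  dat <- data.frame(
    y = scored$chd_10yr,
    category = stats::relevel(factor(cat_chr, levels = present), reference)
  )
  form <- y ~ category
  if (adjust_age) {
    dat$age <- scored$age
    form <- y ~ category + age
  }
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  if (!fit$converged) {
    stop("logistic category model did not converge (deviance ",
         signif(fit$deviance, 6), ")", call. = FALSE)
  }
  est <- summary(fit)$coefficients
  idx <- grep("^category", rownames(est))
  lev <- sub("^category", "", rownames(est)[idx])
  z <- stats::qnorm(0.975)
  counts <- category_counts(scored)
  out <- data.frame(
    category = c(reference, lev),
    or = c(1, exp(est[idx, "Estimate"])),
    ci_low = c(NA, exp(est[idx, "Estimate"] - z * est[idx, "Std. Error"])),
    ci_high = c(NA, exp(est[idx, "Estimate"] + z * est[idx, "Std. Error"])),
    se_log = c(NA, est[idx, "Std. Error"]),
    separation = c(FALSE, abs(est[idx, "Estimate"]) > 10),
    stringsAsFactors = FALSE
  )
  out <- merge(counts[, c("category", "n", "cases")], out, by = "category")
  out <- out[match(intersect(ydr_categories()$category, out$category),
                   out$category), ]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "adjust_age") <- adjust_age
  attr(out, "fit") <- fit
  out
}

#' Per-factor and multivariate outcome associations
#'
#' Reproduces the per-factor validation: one logistic model per risk
#' factor (subjects for whom the factor applies, levels against the
#' factor's reference), and one joint model containing all factors. In the
#' joint model a subject's inapplicable factors sit at the reference level
#' so they contribute nothing to the linear predictor; factors observed at
#' a single level are flagged and dropped.
#'
#' @param cohort A cohort with `chd_10yr` and one column per factor.
#' @param model A [ydr_model()].
#' @return A list with `unadjusted` and `multivariate` `data.frame`s
#'   (columns `factor_id`, `level_id`, `or`, `ci_low`, `ci_high`,
#'   `se_log`) and `dropped`, the ids of constant factors.
#' @export
factor_association_models <- function(cohort, model = ydr_model()) {
  stopifnot("chd_10yr" %in% names(cohort))
  p <- model$params
  fids <- unique(p$factor_id)
  app <- applicability_matrix(model, cohort$age,
                              smoking_level = cohort[["smoking"]])
  z <- stats::qnorm(0.975)

  # per-factor models
  unadj <- list()
  for (fid in fids) {
    rows <- p$factor_id == fid
    ref <- p$level_id[rows & p$is_reference]
    use <- app[, fid] & !is.na(cohort[[fid]])
    lev <- factor(cohort[[fid]][use], levels = p$level_id[rows])
    if (length(unique(as.character(lev))) < 2) next
    dat <- data.frame(y = cohort$chd_10yr[use],
                      lev = stats::relevel(droplevels(lev), ref))
    fit <- stats::glm(y ~ lev, family = stats::binomial(), data = dat)
    est <- summary(fit)$coefficients
    keep <- grep("^lev", rownames(est))
    unadj[[fid]] <- data.frame(
      factor_id = fid,
      level_id = sub("^lev", "", rownames(est)[keep]),
      or = exp(est[keep, "Estimate"]),
      ci_low = exp(est[keep, "Estimate"] - z * est[keep, "Std. Error"]),
      ci_high = exp(est[keep, "Estimate"] + z * est[keep, "Std. Error"]),
      se_log = est[keep, "Std. Error"],
      stringsAsFactors = FALSE
    )
  }
  unadjusted <- do.call(rbind, unadj)
  rownames(unadjusted) <- NULL

  # joint model: inapplicable/missing -> reference (contributes nothing)
  dat <- data.frame(y = cohort$chd_10yr)
  dropped <- character(0)
  for (fid in fids) {
    rows <- p$factor_id == fid
    ref <- p$level_id[rows & p$is_reference]
    lev <- as.character(cohort[[fid]])
    lev[!app[, fid] | is.na(lev)] <- ref
    if (length(unique(lev)) < 2) {
      dropped <- c(dropped, fid)
      next
    }
    dat[[paste0("f_", fid)]] <-
      stats::relevel(factor(lev, levels = p$level_id[rows]), ref)
  }
  preds <- setdiff(names(dat), "y")
  if (!length(preds)) {
    stop("no non-constant factors for the multivariate model", call. = FALSE)
  }
  form <- stats::as.formula(paste("y ~", paste(preds, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  if (!fit$converged) {
    stop("multivariate factor model did not converge", call. = FALSE)
  }
  est <- summary(fit)$coefficients
  keep <- grep("^f_", rownames(est))
  nm <- rownames(est)[keep]
  fid_part <- vapply(nm, function(x) {
    hit <- preds[startsWith(x, preds)]
    hit[which.max(nchar(hit))]
  }, character(1))
  multivariate <- data.frame(
    factor_id = sub("^f_", "", fid_part),
    level_id = substring(nm, nchar(fid_part) + 1),
    or = exp(est[keep, "Estimate"]),
    ci_low = exp(est[keep, "Estimate"] - z * est[keep, "Std. Error"]),
    ci_high = exp(est[keep, "Estimate"] + z * est[keep, "Std. Error"]),
    se_log = est[keep, "Std. Error"],
    stringsAsFactors = FALSE
  )
  rownames(multivariate) <- NULL
  list(unadjusted = unadjusted, multivariate = multivariate,
       dropped = dropped, fit = fit)
}
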