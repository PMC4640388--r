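new_cstat <- function(c, var, n_cases, n_noncases, method,
                      degenerate = FALSE) {
  se <- sqrt(var)
  structure(
    list(
      c = c,
      ci_low = if (degenerate) NA_real_ else max(0, c - stats::qnorm(0.975) * se),
      ci_high = if (degenerate) NA_real_ else min(1, c + stats::qnorm(0.975) * se),
      var = var,
      n_cases = n_cases,
      n_noncases = n_noncases,
      method = method,
      degenerate = degenerate
    ),
    class = "ydr_cstat"
  )
}

#' @export
print.ydr_cstat <- function(x, ...) {
  cat(sprintf("c-statistic %.4f (95%% CI %.4f-%.4f), %d cases / %d non-cases [%s]%s\n",
              x$c, x$ci_low, x$ci_high, x$n_cases, x$n_noncases, x$method,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Hanley-McNeil variance of the concordance statistic.
hanley_mcneil_var <- function(c, n_cases, n_noncases) {
  q1 <- c / (2 - c)
  q2 <- 2 * c^2 / (1 + c)
  (c * (1 - c) + (n_cases - 1) * (q1 - c^2) +
      (n_noncases - 1) * (q2 - c^2)) / (n_cases * n_noncases)
}

#' Concordance statistic from a category count table
#'
#' For a logistic model whose predictors are indicators of a single
#' categorical variable, the fitted risks order the subjects exactly as
#' the categories' event rates do, so the model's c-statistic is the
#' tie-corrected rank concordance over the count table:
#' \deqn{c = \frac{\sum_{rate_i < rate_j} cases_j \cdot noncases_i
#'        + \tfrac12 \sum_k cases_k \cdot noncases_k}
#'       {cases_{tot} \cdot noncases_{tot}}}
#' Confidence limits use the Hanley-McNeil variance.
#'
#' @param counts A count table (`category`, `n`, `cases`).
#' @return A `ydr_cstat` object: `c`, `ci_low`, `ci_high`, `var`,
#'   `n_cases`, `n_noncases`. If all subjects fall in one category the
#'   result is a flagged degenerate c of 0.5.
#' @export
c_statistic_from_counts <- function(counts) {
  counts <- validate_counts(counts)
  counts <- counts[counts$n > 0, , drop = FALSE]
  cases <- counts$cases
  noncases <- counts$n - counts$cases
  n1 <- sum(cases)
  n0 <- sum(noncases)
  if (nrow(counts) == 1) {
    return(new_cstat(0.5, 0, n1, n0, "hanley-mcneil", degenerate = TRUE))
  }
  rate <- cases / counts$n
  conc <- 0
  for (j in seq_along(rate)) {
    conc <- conc + cases[j] * sum(noncases[rate < rate[j]])
  }
  # ties: case-noncase pairs whose categories share an event rate
  # (including the case's own category) count half
  ties <- sum(vapply(seq_along(rate), function(j) {
    cases[j] * sum(noncases[rate == rate[j]])
  }, numeric(1)))
  cval <- (conc + 0.5 * ties) / (n1 * n0)
  new_cstat(cval, hanley_mcneil_var(cval, n1, n0), n1, n0, "hanley-mcneil")
}

# DeLong variance via placement values (O(n log n) with midranks).
delong_var <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n          # P(Y < x_i) + 0.5 ties
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m  # P(X > y_j) + 0.5 ties
  stats::var(v10) / m + stats::var(v01) / n
}

#' Pairwise (Mann-Whitney) concordance statistic
#'
#' Tie-corrected probability that a randomly chosen case has a higher
#' predicted score than a randomly chosen non-case, ties counted half;
#' computed via midranks in O(n log n). Invariant under strictly monotone
#' transformations of the scores, and identical to
#' [c_statistic_from_counts()] when the scores are constant within
#' categories.
#'
#' @param scores Numeric predicted risks or any monotone score.
#' @param outcomes Binary outcome vector (0/1), same length.
#' @param ci_method `"hanley-mcneil"` (default, matches the count-based
#'   estimator) or `"delong"`.
#' @return A `ydr_cstat` object.
#' @export
c_statistic_pairwise <- function(scores, outcomes,
                                 ci_method = c("hanley-mcneil", "delong")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 < 1 || n0 < 1) {
    stop("need at least one case and one non-case", call. = FALSE)
  }
  r <- rank(scores)
  cval <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  v <- switch(ci_method,
    "hanley-mcneil" = hanley_mcneil_var(cval, n1, n0),
    "delong" = delong_var(scores, outcomes)
  )
  new_cstat(cval, v, n1, n0, ci_method)
}

#' Compare two concordance statistics from independent strata
#'
#' Two-sided z-test of equal discrimination for disjoint subject sets
#' (e.g. women under versus over 60), using the same variance estimates
#' that back the individual confidence intervals:
#' \eqn{z = (c_A - c_B) / \sqrt{var_A + var_B}}.
#'
#' @param a,b `ydr_cstat` objects for the two strata.
#' @return A list with `z`, `p_value`, and the c difference `delta`.
#' @export
compare_c_statistics <- function(a, b) {
  stopifnot(inherits(a, "ydr_cstat"), inherits(b, "ydr_cstat"))
  if (isTRUE(a$degenerate) || isTRUE(b$degenerate)) {
    stop("cannot compare a degenerate c-statistic", call. = FALSE)
  }
  v <- a$var + b$var
  if (v <= 0) {
    stop("zero variance: c-statistics carry no sampling uncertainty",
         call. = FALSE)
  }
  z <- (a$c - b$c) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), delta = a$c - b$c)
}
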