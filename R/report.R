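#' Full validation report for a scored cohort
#'
#' Runs the whole statistical battery on a scored cohort with a binary
#' 10-year outcome and age: per-category counts; crude (closed-form and
#' logistic) and age-adjusted category odds ratios against "about
#' average"; the same refit within age strata at the 60-year cutpoint;
#' the count-based c-statistic of the category model, the age-adjusted
#' c-statistic (concordance of fitted probabilities from the
#' age-plus-categories logistic model), age-band c-statistics (bands
#' <=55, 56-60, 61-65, 66-70, >70), and the z-test comparing
#' discrimination below versus at-or-above 60.
#'
#' @param scored A scored cohort with `ydr_category`, `chd_10yr`, `age`.
#' @param age_cutpoint Stratification cutpoint in years.
#' @return A `ydr_report` list; every element is the output of one of the
#'   documented operations.
#' @export
build_report <- function(scored, age_cutpoint = 60) {
  stopifnot(all(c("ydr_category", "chd_10yr", "age") %in% names(scored)))
  counts <- category_counts(scored)
  n <- sum(counts$n)
  cases <- sum(counts$cases)

  safe <- function(expr) tryCatch(expr, error = function(e) {
    structure(list(message = conditionMessage(e)), class = "ydr_skipped")
  })

  crude_closed <- safe(closed_form_category_or(counts))
  crude_logistic <- safe(logistic_category_model(scored, adjust_age = FALSE))
  age_adjusted <- safe(logistic_category_model(scored, adjust_age = TRUE))

  strata <- list(
    lower = scored[scored$age < age_cutpoint, , drop = FALSE],
    upper = scored[scored$age >= age_cutpoint, , drop = FALSE]
  )
  names(strata) <- c(paste0("age_lt", age_cutpoint),
                     paste0("age_ge", age_cutpoint))
  stratified <- lapply(strata, function(s) {
    list(
      counts = safe(category_counts(s)),
      crude_or = safe(closed_form_category_or(category_counts(s))),
      c_stat = safe(c_statistic_from_counts(category_counts(s)))
    )
  })

  c_overall <- safe(c_statistic_from_counts(counts))
  c_age_adjusted <- safe({
    fit <- attr(age_adjusted, "fit")
    c_statistic_pairwise(stats::fitted(fit), scored$chd_10yr)
  })
  bands <- list(age_le55 = scored$age <= 55,
                age_56_60 = scored$age > 55 & scored$age <= 60,
                age_61_65 = scored$age > 60 & scored$age <= 65,
                age_66_70 = scored$age > 65 & scored$age <= 70,
                age_gt70 = scored$age > 70)
  c_age_bands <- lapply(bands, function(i) {
    safe(c_statistic_from_counts(category_counts(scored[i, , drop = FALSE])))
  })
  c_compare <- safe(compare_c_statistics(stratified[[1]]$c_stat,
                                         stratified[[2]]$c_stat))

  structure(
    list(
      n = n, cases = cases, incidence_pct = 100 * cases / n,
      counts = counts,
      crude_or_closed_form = crude_closed,
      crude_or_logistic = crude_logistic,
      age_adjusted_or = age_adjusted,
      stratified = stratified,
      c_statistic = c_overall,
      c_statistic_age_adjusted = c_age_adjusted,
      c_statistic_age_bands = c_age_bands,
      c_statistic_age_comparison = c_compare,
      age_cutpoint = age_cutpoint
    ),
    class = "ydr_report"
  )
}

#' @export
print.ydr_report <- function(x, ...) {
  cat("Validation report\n")
  cat(sprintf("  subjects: %d, cases: %d (%.1f%%)\n",
              x$n, x$cases, x$incidence_pct))
  ok <- function(o) !inherits(o, "ydr_skipped")
  if (ok(x$crude_or_closed_form)) {
    cat("  category odds ratios (crude, vs about average):\n")
    or <- x$crude_or_closed_form
    for (i in seq_len(nrow(or))) {
      cat(sprintf("    %-24s n=%6d cases=%4d OR=%s\n", or$category[i],
                  or$n[i], or$cases[i],
                  ifelse(is.na(or$ci_low[i]), "1.00 (REF)",
                         sprintf("%.2f (%.2f-%.2f)", or$or[i],
                                 or$ci_low[i], or$ci_high[i]))))
    }
  }
  if (ok(x$c_statistic)) {
    cat(sprintf("  c-statistic (category model): %.2f (%.2f-%.2f)\n",
                x$c_statistic$c, x$c_statistic$ci_low, x$c_statistic$ci_high))
  }
  if (ok(x$c_statistic_age_adjusted)) {
    cat(sprintf("  c-statistic (age-adjusted):   %.2f (%.2f-%.2f)\n",
                x$c_statistic_age_adjusted$c,
                x$c_statistic_age_adjusted$ci_low,
                x$c_statistic_age_adjusted$ci_high))
  }
  if (ok(x$c_statistic_age_comparison)) {
    cat(sprintf("  discrimination <%d vs >=%d: z=%.2f, p=%.3g\n",
                x$age_cutpoint, x$age_cutpoint,
                x$c_statistic_age_comparison$z,
                x$c_statistic_age_comparison$p_value))
  }
  skipped <- sum(!vapply(x[c("crude_or_closed_form", "crude_or_logistic",
                             "age_adjusted_or", "c_statistic",
                             "c_statistic_age_adjusted")], ok, logical(1)))
  if (skipped) cat("  (", skipped, " component(s) skipped with flags)\n")
  invisible(x)
}

#' Write a validation report to delimited files
#'
#' Emits `category_or.csv` (crude, logistic and age-adjusted odds
#' ratios), `c_statistics.csv`, per-stratum OR tables, and a plain-text
#' `summary.txt`.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- function(o) !inherits(o, "ydr_skipped")
  if (ok(report$crude_or_closed_form)) {
    utils::write.csv(report$crude_or_closed_form,
                     file.path(dir, "category_or_crude.csv"),
                     row.names = FALSE)
  }
  if (ok(report$age_adjusted_or)) {
    utils::write.csv(report$age_adjusted_or,
                     file.path(dir, "category_or_age_adjusted.csv"),
                     row.names = FALSE)
  }
  for (s in names(report$stratified)) {
    if (ok(report$stratified[[s]]$crude_or)) {
      utils::write.csv(report$stratified[[s]]$crude_or,
                       file.path(dir, paste0("category_or_", s, ".csv")),
                       row.names = FALSE)
    }
  }
  cs <- list(overall = report$c_statistic,
             age_adjusted = report$c_statistic_age_adjusted)
  cs <- c(cs, report$c_statistic_age_bands)
  rows <- lapply(names(cs), function(nm) {
    o <- cs[[nm]]
    if (!ok(o)) return(NULL)
    data.frame(stratum = nm, c = o$c, ci_low = o$ci_low,
               ci_high = o$ci_high, n_cases = o$n_cases,
               n_noncases = o$n_noncases, method = o$method)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "c_statistics.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(dir)
}

#' Recompute the published tables from the packaged count fixtures
#'
#' Runs the packaged per-category count tables through the closed-form
#' odds-ratio and count-based c-statistic operations and tabulates the
#' recomputed values against the published ones, per stratum.
#'
#' @param counts_path Counts CSV (default: packaged published counts).
#' @param cstat_path Published c-statistic CSV for the overall comparison.
#' @return A list with `or` (a `data.frame` with recomputed and printed
#'   odds ratios and their difference), `c_statistic` (same for the
#'   overall count-based c), and `incidence_pct`.
#' @export
reproduce_tables <- function(counts_path = ydr_extdata("table2_counts.csv"),
                             cstat_path = ydr_extdata("table3_cstat.csv")) {
  all_counts <- read_category_counts(counts_path)
  strata <- unique(all_counts$stratum %||% "overall")
  or_rows <- lapply(strata, function(s) {
    counts <- if ("stratum" %in% names(all_counts)) {
      all_counts[all_counts$stratum == s, , drop = FALSE]
    } else all_counts
    or <- closed_form_category_or(counts)
    out <- data.frame(stratum = s, category = or$category, n = or$n,
                      cases = or$cases, or = or$or, ci_low = or$ci_low,
                      ci_high = or$ci_high)
    if ("or_printed" %in% names(counts)) {
      out$or_printed <- counts$or_printed[match(out$category,
                                                counts$category)]
      out$diff <- round(out$or, 2) - out$or_printed
    }
    out
  })
  or <- do.call(rbind, or_rows)

  overall <- if ("stratum" %in% names(all_counts)) {
    all_counts[all_counts$stratum == "overall", , drop = FALSE]
  } else all_counts
  cs <- c_statistic_from_counts(overall)
  c_row <- data.frame(stratum = "overall", c = cs$c, ci_low = cs$ci_low,
                      ci_high = cs$ci_high)
  if (file.exists(cstat_path)) {
    printed <- utils::read.csv(cstat_path, stringsAsFactors = FALSE)
    hit <- printed[printed$stratum == "overall", , drop = FALSE]
    if (nrow(hit)) {
      c_row$c_printed <- hit$c_printed[1]
      c_row$diff <- round(c_row$c, 2) - c_row$c_printed
    }
  }
  list(
    or = or,
    c_statistic = c_row,
    incidence_pct = 100 * sum(overall$cases) / sum(overall$n)
  )
}
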