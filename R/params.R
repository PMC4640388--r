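#' Path to a packaged data file
#'
#' Convenience accessor for the plain-text data files shipped with the
#' package: the default risk-factor parameter table (`params_table1.csv`),
#' the published per-category count tables (`table2_counts.csv`), the
#' published concordance statistics (`table3_cstat.csv`) and a small
#' synthetic example cohort (`cohort_synthetic_example.csv`).
#'
#' @param file File name within the package's `extdata` directory. With no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' ydr_extdata()
#' read_params(ydr_extdata("params_table1.csv"))
ydr_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "ydrisk")))
  }
  path <- system.file("extdata", file, package = "ydrisk")
  if (!nzchar(path)) {
    stop("no packaged data file named '", file, "'", call. = FALSE)
  }
  path
}

.mandatory_param_cols <- c(
  "factor_id", "level_id", "is_reference", "consensus_rr",
  "us_prevalence", "nhs_prevalence", "applicability"
)

.applicability_rules <- c("always", "age<60", "age>=60", "not_current_smoker")

#' Read and validate a risk-factor parameter table
#'
#' The parameter file is delimited text with one row per factor level and
#' header columns `factor_id, level_id, is_reference, consensus_rr,
#' us_prevalence, nhs_prevalence, applicability`. Additional columns (the
#' packaged default carries `observed_rr` and `observed_rr_mv`, the
#' cohort-estimated unadjusted and multivariate relative risks) are
#' preserved. `applicability` is one of `always`, `age<60`, `age>=60`,
#' `not_current_smoker` and must be constant within a factor.
#'
#' Validation enforces: exactly one reference level per factor, with
#' relative risk 1.0; all relative risks strictly positive; prevalences in
#' \[0, 1\] and summing to 1 across a factor's levels (within printing
#' tolerance; the reference prevalence is then re-derived exactly as one
#' minus the exposed total); no duplicated levels. The packaged default
#' encodes the published consensus table verbatim: 18 factors (the
#' adiposity pair is two age-gated factors) and 46 levels.
#'
#' @param path Path to a parameter CSV; defaults to the packaged table.
#' @return A validated `data.frame` of factor levels.
#' @seealso [ydr_model()], [population_average_rr()]
#' @export
read_params <- function(path = ydr_extdata("params_table1.csv")) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  params <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_params(params)
}

#' @rdname read_params
#' @param params A parameter `data.frame` to validate in place.
#' @export
validate_params <- function(params) {
  missing <- setdiff(.mandatory_param_cols, names(params))
  if (length(missing)) {
    stop("parameter table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params$is_reference <- as.logical(as.integer(params$is_reference))
  if (anyNA(params$is_reference)) {
    stop("is_reference must be 0/1", call. = FALSE)
  }
  key <- paste(params$factor_id, params$level_id)
  if (anyDuplicated(key)) {
    stop("duplicated factor level(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  rr_cols <- intersect(c("consensus_rr", "observed_rr", "observed_rr_mv"),
                       names(params))
  for (col in rr_cols) {
    if (any(!is.finite(params[[col]]) | params[[col]] <= 0)) {
      stop("column '", col, "' must be strictly positive", call. = FALSE)
    }
  }
  if (!all(.applicability_rules %in% .applicability_rules) ||
      !all(params$applicability %in% .applicability_rules)) {
    bad <- setdiff(unique(params$applicability), .applicability_rules)
    stop("unknown applicability rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (fid in unique(params$factor_id)) {
    rows <- params$factor_id == fid
    if (sum(params$is_reference[rows]) != 1L) {
      stop("factor '", fid, "' must have exactly one reference level",
           call. = FALSE)
    }
    ref <- rows & params$is_reference
    if (abs(params$consensus_rr[ref] - 1.0) > 1e-9) {
      stop("reference level of factor '", fid,
           "' must have consensus_rr = 1.0", call. = FALSE)
    }
    if (length(unique(params$applicability[rows])) != 1L) {
      stop("applicability must be constant within factor '", fid, "'",
           call. = FALSE)
    }
    for (pcol in c("us_prevalence", "nhs_prevalence")) {
      p <- params[[pcol]][rows]
      if (any(!is.finite(p) | p < 0 | p > 1)) {
        stop("factor '", fid, "': ", pcol, " outside [0, 1]", call. = FALSE)
      }
      exposed <- sum(p[!params$is_reference[rows]])
      if (exposed > 1 + 1e-9) {
        stop("factor '", fid, "': exposed ", pcol, " levels sum to ",
             signif(exposed, 6), " > 1", call. = FALSE)
      }
      if (abs(sum(p) - 1) > 2e-3) {
        stop("factor '", fid, "': ", pcol, " levels sum to ",
             signif(sum(p), 6), ", not 1", call. = FALSE)
      }
      # re-derive the reference prevalence exactly (printed values round)
      params[[pcol]][ref] <- 1 - exposed
    }
  }
  rownames(params) <- NULL
  params
}
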