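#' Read a person-level cohort table
#'
#' Delimited text (comma, header row), one row per subject. `age` is
#' mandatory; `subject_id` is added if absent; when a `model` is supplied
#' every factor column it defines must be present (values may still be
#' missing row-wise, which scoring handles). Unknown columns are carried
#' through untouched. Empty strings and `NA` are read as missing.
#'
#' @param path Path to a cohort CSV.
#' @param model Optional [ydr_model()] used to check factor columns.
#' @param require_outcome Also require the binary `chd_10yr` column.
#' @return A cohort `data.frame`.
#' @export
read_cohort <- function(path, model = NULL, require_outcome = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  mandatory <- "age"
  if (require_outcome) mandatory <- c(mandatory, "chd_10yr")
  missing <- setdiff(mandatory, names(cohort))
  if (length(missing)) {
    stop("cohort file missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cohort$age)) {
    bad <- which(is.na(suppressWarnings(as.numeric(cohort$age))))[1]
    stop("unparseable age at row ", bad, call. = FALSE)
  }
  if (require_outcome && !all(cohort$chd_10yr %in% c(0L, 1L))) {
    bad <- which(!cohort$chd_10yr %in% c(0L, 1L))[1]
    stop("chd_10yr must be 0/1 (row ", bad, ")", call. = FALSE)
  }
  if (!"subject_id" %in% names(cohort)) {
    cohort$subject_id <- seq_len(nrow(cohort))
  }
  if (!is.null(model)) {
    fids <- unique(model$params$factor_id)
    missing <- setdiff(fids, names(cohort))
    if (length(missing)) {
      stop("cohort file missing factor column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  message("read ", nrow(cohort), " subjects from ", path,
          " (", sum(is.na(cohort)), " missing cells)")
  cohort
}

#' Write a cohort (or scored cohort) table
#'
#' Plain CSV, exact round-trip with [read_cohort()].
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  if ("ydr_category" %in% names(out)) {
    out$ydr_category <- as.character(out$ydr_category)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-category count table
#'
#' Expects columns `category`, `n`, `cases`, and optionally `stratum`
#' (the packaged `table2_counts.csv` carries the published counts for the
#' whole cohort and both age strata, plus the published odds ratios for
#' comparison).
#'
#' @param path Path to a counts CSV; defaults to the packaged table.
#' @param stratum If the file has a `stratum` column, which stratum to
#'   return; `NULL` returns everything.
#' @return A count `data.frame` ordered by the seven categories.
#' @export
read_category_counts <- function(path = ydr_extdata("table2_counts.csv"),
                                 stratum = NULL) {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(stratum)) {
    if (!"stratum" %in% names(counts)) {
      stop("count file has no 'stratum' column", call. = FALSE)
    }
    counts <- counts[counts$stratum == stratum, , drop = FALSE]
    if (!nrow(counts)) {
      stop("no rows for stratum '", stratum, "'", call. = FALSE)
    }
  }
  counts$category <- factor(counts$category,
                            levels = ydr_categories()$category)
  ord <- if ("stratum" %in% names(counts)) {
    order(match(counts$stratum, unique(counts$stratum)), counts$category)
  } else {
    order(counts$category)
  }
  counts <- counts[ord, ]
  counts$category <- as.character(counts$category)
  rownames(counts) <- NULL
  validate_counts(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the parameter file, recorded in run logs
params_checksum <- function(path = ydr_extdata("params_table1.csv")) {
  unname(tools::md5sum(path))
}
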