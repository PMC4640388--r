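# Independent spreadsheet-style oracle for the scoring equation: reads the
# raw parameter CSV itself, re-derives reference prevalences, and evaluates
# the printed equation by explicit loops. Shares no code with the package.
oracle_read_params <- function(path = ydr_extdata("params_table1.csv")) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (fid in unique(raw$factor_id)) {
    rows <- raw$factor_id == fid
    for (pcol in c("us_prevalence", "nhs_prevalence")) {
      exposed <- sum(raw[[pcol]][rows & raw$is_reference == 0])
      raw[[pcol]][rows & raw$is_reference == 1] <- 1 - exposed
    }
  }
  raw
}

oracle_applicable <- function(rule, age, smoking_level) {
  if (rule == "always") return(TRUE)
  if (rule == "age<60") return(age < 60)
  if (rule == "age>=60") return(age >= 60)
  if (rule == "not_current_smoker") {
    return(!grepl("^current", smoking_level))
  }
  stop("oracle: unknown rule ", rule)
}

# levels: named character vector factor_id -> level_id
oracle_score <- function(age, levels, raw,
                         prev_col = "us_prevalence",
                         eff_col = "consensus_rr") {
  num <- 1
  den <- 1
  for (fid in unique(raw$factor_id)) {
    rows <- raw[raw$factor_id == fid, ]
    if (!oracle_applicable(rows$applicability[1], age,
                           levels[["smoking"]])) next
    den_term <- 0
    for (k in seq_len(nrow(rows))) {
      den_term <- den_term + rows[[prev_col]][k] * rows[[eff_col]][k]
    }
    num <- num * rows[[eff_col]][rows$level_id == levels[[fid]]]
    den <- den * den_term
  }
  list(numerator = num, denominator = den, rr = num / den)
}

# Random profile drawn uniformly over levels (distribution irrelevant for
# oracle-equivalence checks).
oracle_random_profile <- function(raw) {
  age <- sample(47:74, 1)
  levels <- vapply(unique(raw$factor_id), function(fid) {
    sample(raw$level_id[raw$factor_id == fid], 1)
  }, character(1))
  list(age = age, levels = levels)
}

# Brute-force O(n^2) tie-corrected concordance.
oracle_concordance <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  total / (length(x) * length(y))
}
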