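# Small parameter tables built in code for unit tests.

binary_params <- function(p_exposed = 0.5, rr = 2.0,
                          factor_id = "f1", applicability = "always",
                          p_nhs = p_exposed) {
  data.frame(
    factor_id = factor_id,
    level_id = c("no", "yes"),
    is_reference = c(1L, 0L),
    consensus_rr = c(1.0, rr),
    us_prevalence = c(1 - p_exposed, p_exposed),
    nhs_prevalence = c(1 - p_nhs, p_nhs),
    applicability = applicability,
    stringsAsFactors = FALSE
  )
}

two_factor_params <- function() {
  rbind(binary_params(0.5, 2.0, "f1"), binary_params(0.5, 2.0, "f2"))
}

# A one-row cohort for a given binary-factor model.
binary_cohort <- function(levels, age = 50) {
  out <- data.frame(age = rep(age, length.out = max(lengths(levels))))
  for (nm in names(levels)) out[[nm]] <- levels[[nm]]
  out
}
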