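# ydrisk

Scoring and validation machinery for the **Your Disease Risk (YDR)**
coronary-heart-disease (CHD) relative-risk score, aimed at epidemiologists
and biostatisticians who study health risk appraisal tools: people who need
to score cohorts with the published consensus parameters, check a tool's
calibration and discrimination against a cohort with a binary 10-year
outcome, or run simulation studies with known ground truth.

## The score

YDR estimates a person's 10-year relative risk of CHD compared with an
average person of the same age and sex, from self-reportable factors only
(smoking history, diet, physical activity, blood pressure, diabetes,
cholesterol, adiposity, family history, ...). Each factor level carries a
consensus relative risk $RR_{f,k}$ and a population prevalence $P_{f,k}$;
an individual at levels $l(f)$ scores

$$RR = \frac{\prod_f RR_{f,l(f)}}{\prod_f \left[\sum_k P_{f,k}\,RR_{f,k}\right]}$$

where both products run over the factors applicable to that person
(body-mass index below age 60, waist circumference at 60 and above;
secondhand smoke only for non-smokers). The denominator is the
prevalence-weighted average numerator of the reference population, so an
average person scores 1. Scores are binned into seven ordered categories
from "very much below average" (RR ≤ 0.2) to "very much above average"
(RR > 5.1), upper bounds inclusive.

The validation side fits logistic models of the outcome on category
indicators (crude, age-adjusted, age-stratified), computes their odds
ratios both by maximum likelihood and in closed form from count tables,
and measures discrimination with tie-corrected concordance statistics
(count-based and pairwise Mann-Whitney estimators, Hanley-McNeil or DeLong
intervals, and a z-test comparing strata). A synthetic-cohort generator
emulates the structure of the cohort the tool was validated on (55,802
women aged 47–74, observed factor prevalences, multiplicative effects,
2.1% ten-year incidence, optional age confounding) so every stage runs and
is testable without any restricted data.

## Worked example

Score one 55-year-old heavy-exposure profile with the packaged consensus
parameters:

```r
library(ydrisk)
model <- ydr_model()   # U.S. prevalences in the denominator, consensus RRs
profile <- list(bmi = "ge29", smoking = "current_15to24",
  multivitamin = "lt5wk", physical_activity = "lt3hwk",
  high_blood_pressure = "yes", diabetes = "no", cholesterol = "240to299",
  family_history = "yes", fish = "lt2wk", fruits_vegetables = "lt5day",
  whole_grains = "lt3day", nuts = "lt3wk", saturated_fat = "ge2day",
  trans_fat = "ge5wk", unsaturated_fat = "lt5wk", alcohol = "none")
str(score_profile(55, profile, model))
#> List of 4
#>  $ numerator    : num 481
#>  $ denominator  : num 13.5
#>  $ relative_risk: num 35.8
#>  $ category     : chr "very_much_above_average"
```

The numerator multiplies the profile's level relative risks (obesity 5.0 ×
smoking 2.25 × hypertension 2.25 × ...); the denominator 13.5 is the
population-average product for an under-60 non-smoker; their ratio says
this person's 10-year CHD risk is ~36 times that of an average woman of
the same age — deep in the top category.

Recompute the published validation tables from the packaged count data:

```r
rep <- reproduce_tables()
round(rep$or[rep$or$stratum == "overall", c("or", "or_printed")], 2)
#>     or or_printed
#> 1 0.42       0.42
#> 2 0.70       0.70
#> 3 0.81       0.81
#> 4 1.00       1.00
#> 5 1.31       1.31
#> 6 1.40       1.40
#> 7 1.71       1.71
sprintf("c = %.4f", rep$c_statistic$c)
#> [1] "c = 0.6190"
```

The crude odds ratios rise monotonically across the seven categories —
the tool ranks risk correctly — but are much flatter than the nominal
category ranges (0.42 observed where the category promises ≤ 0.2; 1.71
where it promises > 5.1): correct discrimination, imperfect calibration.
The count-based c-statistic of 0.62 quantifies that moderate
discrimination.

Simulate a ground-truth cohort, score it, and run the full battery:

```r
spec <- cohort_spec(n_subjects = 55802, random_seed = 11,
                    prevalence_source = "nhs")
scored <- score_cohort(simulate_cohort(spec, model), model)
build_report(scored)
```

A command-line front end over the same functions is installed at
`system.file("cli", "ydr.R", package = "ydrisk")` with subcommands
`score`, `simulate`, `validate` and `reproduce-tables`; every output gets
a JSON run log with the seed and parameter-file checksum.

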