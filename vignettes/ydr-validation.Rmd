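---
title: "A prevalence-normalised relative-risk score for coronary heart disease, and how it is validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A prevalence-normalised relative-risk score for coronary heart disease, and how it is validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ydrisk)
```

## The score

Health risk appraisal tools such as Your Disease Risk (YDR) estimate how an
individual's 10-year risk of coronary heart disease (CHD) compares with that
of an average person of the same age and sex, using only self-reportable
lifestyle and clinical factors. `ydrisk` implements the scoring engine, a
synthetic-cohort generator with known ground truth, and the statistical
battery used to validate such a tool against a cohort with a binary 10-year
outcome.

The score is multiplicative. Each risk factor $f$ has a set of levels with
consensus-assigned relative risks $RR_{f,k}$ (reference level fixed at 1)
and population prevalences $P_{f,k}$. An individual at levels $l(f)$ gets

$$
RR \;=\; \frac{\prod_f RR_{f,l(f)}}
             {\prod_f \Bigl[\sum_k P_{f,k}\, RR_{f,k}\Bigr]} .
$$

The numerator is the individual's joint relative risk under independent
multiplicative factor effects; each denominator term is the
prevalence-weighted average relative risk of that factor in the reference
population, so the denominator is the expected numerator of a randomly drawn
person. Dividing by it anchors the population average at $RR = 1$: someone
with typical exposures scores near 1, someone uniformly at reference levels
scores well below 1. For a binary factor the denominator term reduces to
$P\,RR + (1-P)$; the multi-level sum is the natural generalisation and the
package uses it throughout (smoking has eight levels, cholesterol five,
body-mass index three).

Three structural rules, encoded as per-factor applicability in the parameter
table, matter in both the numerator and the denominator:

* adiposity is assessed as body-mass index below age 60 and as waist
  circumference at 60 and above — each subject carries exactly one of the
  pair;
* secondhand-smoke exposure applies only to never and past smokers; for a
  current smoker the factor contributes no term at all (it is a model rule,
  not missing data);
* all other factors apply always.

The score is then binned into seven ordered categories, from "very much
below average" ($RR \le 0.2$) to "very much above average" ($RR > 5.1$),
with inclusive upper bounds read literally from the category definitions
(a score of exactly 1.1 is "about average", exactly 5.1 is "much above
average").

Protective factors (relative risks below 1, e.g. physical activity at 0.55)
need no special handling; the score moves symmetrically below and above 1.
With at most 18 factors and level relative risks between 0.55 and 7 the
products stay far from floating-point limits, so everything is computed in
plain double precision without log-space accumulation. Missing levels for an
applicable factor are an error by default — the validation study excluded
such subjects — with an explicit `impute_reference = TRUE` opt-in that
substitutes the reference level.

The parameter table ships as data (`ydr_extdata("params_table1.csv")`), not
code, with both the estimated U.S. prevalences used by the deployed tool and
the prevalences observed in the validation cohort, plus the
cohort-estimated unadjusted and multivariate relative risks, so either side
of the scoring can be swapped for sensitivity analyses
(`ydr_model(prevalence_source =, effect_source =)`).

## What the validation battery computes

The published evaluation of the tool scored roughly 56,000 middle-aged
women, tabulated subjects and CHD events by score category, and asked two
questions.

**Calibration.** Do the observed relative risks per category match the
categories' nominal ranges? The package fits the logistic model of outcome
on category indicators ("about average" as reference), crude and with age
as a continuous covariate, and also within age strata (`build_report()`
refits below/at-or-above 60 rather than using interaction terms, matching
the published layout). For the crude model a closed form exists: with a
single categorical predictor the maximum-likelihood odds ratios equal the
empirical odds ratios of the count table, with Wald limits from the four
reciprocal cell counts. `closed_form_category_or()` is therefore both a
fast route from published count tables and an exact oracle for the `glm`
route — the two agree to numerical precision, and the test suite asserts
it. The tables report odds ratios; at ~2% incidence these approximate
relative risks closely, and the package names them honestly as odds ratios.

**Discrimination.** The concordance (c-) statistic of the category model:
the probability that a random case outranks a random non-case, ties counted
half. Because the fitted risks of a categorical model order subjects exactly
as the category event rates do, the c-statistic is computable from the count
table alone (`c_statistic_from_counts()`); the generic tie-corrected
Mann-Whitney estimator over per-subject scores
(`c_statistic_pairwise()`, midranks, $O(n\log n)$) agrees with it exactly
on categorical scores and with an $O(n^2)$ brute-force pair count on small
data — both equivalences are tested. Confidence intervals use the
Hanley-McNeil variance by default (the published analysis cites a CI method
without formulas); DeLong's covariance-based variance is available as an
option and is cross-checked against an independent implementation in the
tests. Reports state which method was used.

Discrimination in younger versus older women is compared with an
independent-samples z-test, $z = (c_A - c_B)/\sqrt{v_A + v_B}$, using the
same variance estimator as the intervals. The published comparison cites a
specific paired-strata approach whose exact variance is not reproduced in
the source; we label our version an approximation and do not treat the
published p-value as a reproduction target.

Counts from the published category tables (overall and both age strata) are
packaged verbatim, and `reproduce_tables()` re-derives the crude odds
ratios and the overall count-based c-statistic from them. Sixteen of the
eighteen non-reference odds ratios match the printed values to ±0.005; two
stratified entries differ by exactly one unit in the final printed digit
(e.g. 1.7749 recomputed from the integer counts against a printed 1.78),
which is what one expects when the published fit ran on unrounded microdata.
The overall c-statistic recomputes to 0.619 against a printed 0.62, and the
overall incidence to 2.09% against a printed 2.1%.

## The synthetic cohort: what it emulates, and what it does not

The original cohort microdata are not public, so the package ships a
generator whose defaults emulate the study's structure: 55,802 women, ages
uniform on 47–74, factor levels drawn independently at the cohort-observed
prevalences, outcomes Bernoulli with probability
$\text{clamp}(b \cdot \prod_f RR_{f,l(f)}) \times$ an age effect, and the
baseline $b$ calibrated so the marginal 10-year incidence is 2.1%.
Design choices worth knowing:

* **Risk-scale effects with clamping.** Factor effects multiply the risk
  (the score equation's semantics), and products that would exceed 1 are
  clamped with a warning count. At a 2% baseline the risk/odds distinction
  is immaterial for almost all subjects; the handful of clamped extreme
  profiles are counted, not hidden. An `effect_scale = "odds"` switch
  instead multiplies effects on the odds scale, making the logistic-model
  odds ratio exactly the simulated effect — that is the configuration the
  parameter-recovery tests use, since there the estimand must equal the
  generator's truth.
* **Age.** Age enters the outcome as a per-year odds multiplier, default
  1.08, chosen so the simulated incidence gradient across age bands
  (roughly 0.8% below 55 up to ~4% above 70) resembles the published one;
  uniform ages are an assumption, as the source reports only mean ages.
  The score itself never uses age except through applicability — the tool
  estimates risk *relative to one's own age group*.
* **Independence.** Factors are drawn independently because no joint
  distribution is published. Real exposures co-occur (smoking with low
  physical activity, etc.), so the synthetic cohorts will understate the
  variance of the score relative to a real population. Passing calibration
  tests on synthetic data therefore demonstrates the correctness of the
  machinery, not field calibration of the tool.
* **Age confounding hook.** With `age_confounding = TRUE`, current-smoking
  and obesity prevalences decline with age (exposure weight
  $e^{-0.04(\text{age}-60)}$, reference absorbing the shift). That makes
  the top score categories younger on average — the phenomenon the study
  reported — and lets tests check the direction of the crude-versus-
  age-adjusted difference: adjustment moves the top-category odds ratio
  away from 1.
* **Seeding.** One master seed; ages, factor levels, outcomes, auxiliary
  columns and the calibration draw use deterministically derived child
  streams, so any stage can be re-run in isolation and runs are exactly
  reproducible. The generator saves and restores the caller's RNG state.
* **Calibration.** `calibrate_baseline()` root-finds $b$ against the
  expected incidence computed over a large (default 200,000) deterministic
  Monte-Carlo draw of profiles; clamping and the odds-scale age effect make
  the expectation non-separable, so no closed form is attempted beyond the
  test oracles. Achieved-versus-target agreement is enforced to $10^{-4}$.
* **Exclusion screens.** `apply_exclusion_filters()` reproduces the
  study's intake filters — prior heart disease, ten or more missed
  food-frequency items, daily energy intake below 500 or above 3500 kcal
  (strict inequalities; exactly 500/3500 are retained), and any missing
  applicable factor — with per-reason counts. The auxiliary screening
  columns the generator can draw are plumbing for exercising these filters,
  with rates chosen only to produce a realistic mix; they model no
  published quantity.

## Numerical and statistical conventions

* Category cutpoints are half-open intervals with inclusive upper bounds;
  the category function is total and monotone, and the tests exercise the
  exact boundary points.
* Prevalences in the parameter file are printed to three decimals; at load
  the reference prevalence is re-derived exactly as one minus the exposed
  total (after checking the printed sum to within printing tolerance), so
  denominators never inherit rounding residue.
* No continuity correction for zero cells: odds ratios of 0 or infinity
  are returned flagged (`zero_cell`), and degenerate concordance inputs
  (a single occupied category) yield a flagged $c = 0.5$ rather than an
  error, so whole-report generation never crashes on sparse strata.
* Logistic fits are ordinary `stats::glm` maximum likelihood;
  non-convergence is an error carrying the deviance, and coefficient
  magnitudes above 10 on the log scale are flagged as probable separation.
  In the joint per-factor model, a subject's inapplicable factors sit at
  the reference level (contributing nothing), and factors observed at a
  single level are dropped with a flag.
* Published tables print two decimals; tests compare unrounded recomputed
  values against printed ones at ±0.005 (±one final-digit unit for the two
  boundary rows discussed above).

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks: oracle equivalence of
the scoring engine against an independently coded evaluator on 1,000 random
profiles (to $10^{-12}$ relative); mean score $\approx 1$ on a 100,000-
subject cohort drawn at the scoring model's own prevalences (within three
Monte-Carlo standard errors — the normalisation property of the
denominator); multivariate recovery of all 28 non-reference effects at
$n = 50{,}000$ (each within three standard errors); a monotone observed
odds-ratio gradient across all seven categories on a consensus-effect
cohort of 55,802; and interval coverage of the null over 200 replicates.
These sizes make the whole suite run in well under a minute while keeping
every Monte-Carlo tolerance honest.

## Limitations

The consensus relative risks describe lifetime risk while the score is
presented on a 10-year horizon; the implementation takes the equation at
face value, as the deployed tool does, and applies no horizon adjustment.
No cap is applied to extreme scores (whether the deployed tool caps them is
unstated). The score is a *relative* measure by construction — converting
it to absolute risk would require an external baseline and is out of scope.
And synthetic validation, however complete, cannot speak to questionnaire
measurement error, correlated exposures, or secular changes in treatment —
the things that made the observed category risks flatter than the nominal
ranges in the real cohort. The package's attenuation machinery (simulate
with weaker effects than you score with, via `effect_source`) exists
precisely to study that phenomenon qualitatively.
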