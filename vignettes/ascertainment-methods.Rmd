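---
title: "Methods: two-part ascertainment of preschool developmental disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-part ascertainment of preschool developmental disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddascertain)
```

## The problem and the model

Definitive developmental-disability diagnoses (ASD, cerebral palsy,
chromosomal syndromes, moderate–profound learning disability) are often
deferred until school age; preschool children instead accumulate
indicator diagnoses such as developmental delay. Case ascertainment from
coded primary-care records therefore proceeds in two parts: a narrow
condition-code part with low false-positive risk, and a broader
indicator part that accepts more false positives in exchange for far
fewer false negatives. The package classifies every included child as
**probable** (any condition code in the age window), **potential-only**
(indicator codes only) or **neither**, and derives prevalence and
between-group comparisons from that classification. No inference about
disability severity is attempted: the coding system records diagnoses,
not function.

## The code lists

The packaged lists (`inst/extdata/read_codelists.csv`) transcribe the
published two-part Read CTV3 lists verbatim, one row per printed token,
so the file is editable without code changes and the transcription
remains auditable. Codes are canonicalised to exactly five characters
(right-padded with `.`); matching everywhere is case-sensitive
exact-string. No terminology-hierarchy expansion is performed, because
the lists enumerate final codes, not parent concepts. Drug, treatment
and referral codes are out of scope by design.

The transcription has genuine anomalies, which `validate_codelists()`
reports rather than hides:

* the condition part holds 148 raw entries that deduplicate to **129**
  unique codes (e.g. `F23y0` is printed twice under cerebral palsy);
  both numbers are carried, and the stated total for this part matches
  the raw, duplicate-containing enumeration;
* the narrative count of "four" condition lists conflicts with the five
  printed blocks; the five blocks win (Fragile X is modelled as its own
  category);
* three codes (`Xa3HI`, `Eu7y1`, `Eu7z1`) appear in **both** parts
  (moderate–severe learning disability and generalised disabilities).
  Their handling is configurable (`cross_part_precedence`): the default
  `probable_wins` treats a code printed on a condition list as evidence
  of the condition even if it also appears on an indicator list. The
  choice is empirically moot in the reference cohort (no
  moderate–severe LD children) but must be deterministic.

The indicator part has 103 unique codes split 22/37/33/11 across its
four categories; this is an exact invariant of the packaged file.

## Age arithmetic and the window

For anonymity only the year and month of birth are carried. Ages are
anchored to the **first day of the birth month** and counted in
completed (floored) calendar months, so the fifth birthday is exactly 60
months and printed ranges such as 0–60 are integer month counts. The
ascertainment window is inclusive `[0, 60]`: published per-condition age
ranges extend to 60, although one published range prints 0–59, so the
60th month cannot be resolved with certainty from the source tables; the
window is configurable for sensitivity analysis. Events dated before the
birth-month anchor are retained and flagged (`pre_birth`) rather than
dropped — prenatal screening codes can legitimately predate the
anonymised anchor — but they never enter windowed ascertainment. How
events falling in the birth month but before the true (unknown) birth
day were originally handled is unknowable; the floor convention is this
package's choice.

## Exclusions and suppression

Exclusions are applied in a fixed order, each child counted under the
first rule that removes it: withdrawn or died; no linked primary-care
record; no maternal baseline questionnaire; all but one child per
mother. The original one-child rule is unstated; the default here keeps
the earliest birth month with a lexicographic child-id tie-break so
twins resolve deterministically.

Small-cell disclosure control operates twice. A condition category with
more than zero but fewer than five children is suppressed: its children
are removed from the study numerators entirely (in the reference
conditions this removes the three Fragile X children, leaving 83
probable), while the denominator stays at the included-cohort size —
the source reports its full included count as denominator even after the
exclusion, and whether its denominator preceded or followed suppression
is not stated. `suppress_denominator` flips that choice. Separately,
any published rate below 5 per 10,000 is rounded down to 0
(`prevalence_per_10000()`), so suppressed cells cannot be recovered from
the report.

## Deferral

A probable child "received an indicator before the condition" only when
some indicator event date is **strictly** earlier than every condition
event date; a same-day indicator does not count as before. This follows
the ordinary reading of receiving one diagnosis before another and makes
the flag well-defined on coarse EHR timestamps.

## Statistics

Categorical comparisons use the Pearson χ² statistic with **no**
continuity correction — the published education and sex statistics (4.1
and 1.2 at one decimal) reproduce from the published contingency counts
only without Yates' correction — with missing covariate levels excluded
from the table. Continuous comparisons use the two-sample t test,
pooled-variance by default (matching the default of the original
analysis software), Welch with Satterthwaite degrees of freedom by flag;
both variants are always computed in the report. The published t
statistics are *not* reproducible from the published rounded means and
SDs under either formula (pooled from summaries gives −2.78 where −2.1
is printed); they presumably reflect unrounded raw data. The report
therefore carries both computed variants at full precision and a note,
rather than forcing agreement. Display rounding is half-away-from-zero:
statistics to 1 dp, p-values to 2 dp, percentages to 1 dp, prevalences
to integers; R's default half-to-even rounding would not reproduce the
printed integers. No confidence intervals or multiplicity adjustment are
produced, mirroring the reporting conventions of the original tables.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, with every rate and distribution fixed at the reference study
conditions by default: 12,196 child records; mutually exclusive
per-condition prevalences equal to the observed counts over 9,727;
truncated-normal ages at diagnosis with the observed per-condition
means/SDs and supports (months, within [0, 60]); per-condition deferral
probabilities equal to the observed deferral proportions; an
indicator-only prevalence of 394/9,727 with the observed record-level
category mix; a geometric multi-indicator continuation of 0.241;
group-specific sociodemographic mixtures with the observed margins; and
exclusion-rule strata (withdrawal/death, linkage, baseline, sibling
rates) chosen once as plausible values totalling roughly the observed
exclusion fraction. Where the source gives no per-child distribution
(e.g. how many indicator records a child accumulates), the mechanism is
an explicit modelling choice, stated here rather than tuned.

Two design points matter for correctness:

* **Indicator codes are drawn only from codes exclusive to the
  indicator part.** A cross-part code would silently reclassify a
  configured indicator-only child as probable under the default
  precedence, biasing parameter recovery.
* **Noise codes come from a reserved alphabet** (prefix `Q`, checked
  disjoint from the lists at generation time), so background coding can
  never classify anyone.

Under this construction the pipeline's deferral proportion for a
condition converges to `deferral_prob × P(condition age ≥ 1 month)`,
and realized condition counts are exactly binomial, which is what the
property tests check against direct-sampling oracles. The generator does
**not** model comorbidity, code co-occurrence, secular or seasonal
trends, regional coding practice, or miscoding; passing tests on
synthetic cohorts shows the pipeline is correct under its stated
assumptions, not that those assumptions hold in any real EHR extract.

## The fixture

`make_bib_fixture()` is **constructed, not sampled**: exact headline
counts require deterministic assignment, and the stochastic generator
exists separately. Ages and maternal ages are placed at normal quantiles
of the published mean/SD, clamped to the published ranges — a
deterministic stand-in for a truncated-normal sample — so group means
land close to (not exactly on) the published values, while every count
margin is exact: 2,469 excludable records by rule; 12/24/47 children per
retained condition plus 3 Fragile X to be suppressed; 394
potential-only; deferral 6/0/17; 44 probable children with indicators
(62 indicator records over 16 codes); 521 indicator records over 33
codes in the potential-only group following the published record-level
frequency table; education, sex, ethnicity, parity, cohabitation,
finance and deprivation margins per group as published, so the report's
χ² statistics reproduce from the fixture itself. One published
record-level triple (97 condition records, 83 children, 24 children with
repeat codes) is arithmetically unsatisfiable — 24 children with two or
more records forces at least 107 records — so the fixture realises 97
records with 14 repeat-coded children (3 same-date, 11 different-date)
and leaves the impossible triple unforced. Inert extras (reserved-alphabet
noise codes, an event past the window, a pre-birth event, an event on an
excluded child) exercise the filtering paths without moving any count.

## Numerical and testing choices

* χ² is delegated to `stats::chisq.test(correct = FALSE)` and checked
  against the explicit Σ(O−E)²/E double loop to 1e-9 on random tables;
  the closed-form pooled/Welch t formulas are likewise mirrored by
  independent oracles in the tests.
* Classification is checked against a brute-force per-child
  set-intersection oracle on random cohorts of ≤ 50 children under all
  three precedence rules.
* Generator recovery runs 200 seeds at n = 10,000 children and requires
  the mean prevalence error per condition to sit within 3 Monte-Carlo
  standard errors of zero; the seed sweep is fixed so the check is
  deterministic. These problem sizes keep the whole suite around a
  minute while leaving the Monte-Carlo bounds meaningful.
* Degenerate inputs are defined behaviour: empty cohorts yield all-zero
  summaries and reports; an empty code-list file yields empty sets; a
  zero table margin or zero denominator is a domain error, not a NaN.

## Limitations

Exact-string matching cannot find children coded only with parent or
sibling concepts outside the printed lists; free text, assessment
outcomes and severity are out of scope; the one-child rule and the
60th-month boundary are documented choices where the source is silent or
inconsistent; and agreement on the fixture demonstrates arithmetic
fidelity to the published tables, not validity of the code lists in any
other health system.
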