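Package: ddascertain
Title: Two-Part Case Ascertainment of Preschool Developmental Disability
    from Coded Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies preschool children (ages 0-5) with probable and
    potential developmental disabilities from Read CTV3 coded primary-care
    records, using a two-part code-list strategy: five condition categories
    (cerebral palsy, Down syndrome, Fragile X syndrome, autism spectrum
    disorders, moderate-severe learning disability) and four indicator
    categories (developmental delay, generalised developmental disorders,
    generalised disabilities, generic disability). Provides anonymised
    birth-month age arithmetic, cohort exclusion rules, small-cell
    disclosure suppression, prevalence per 10,000 with display rounding,
    Pearson chi-square and two-sample t comparisons, report assembly, and
    a seeded synthetic linked mother-child cohort generator together with
    a deterministic fixture cohort for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
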