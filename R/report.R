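# Report assembly: machine-readable analogues of the published comparison
# tables (prevalence vs literature, per-condition characteristics,
# indicator code frequencies, tested and untested between-group
# sociodemographic comparisons).

#' Literature prevalence reference constants (per 10,000)
#'
#' Published UK and Bradford prevalence estimates carried into the
#' prevalence-comparison table as reference columns. These are constants
#' quoted from the literature, never computed by the pipeline.
#'
#' @return Nested list of per-10,000 reference rates.
#' @export
reference_prevalence <- function() {
  list(
    uk = list(
      disability_conditions = 419, mod_severe_ld = 350, asd = 38,
      cerebral_palsy = 20, down_syndrome = 9, fragile_x = 2,
      indicators = 320, developmental_disability_under5 = 468
    ),
    bradford = list(
      disability_conditions = 505, asd = 103, cerebral_palsy = 41
    )
  )
}

fmt_pct <- function(n, denom) {
  if (denom == 0) return(sprintf("%d (-)", n))
  sprintf("%d (%.1f)", n, round_half_up(100 * n / denom, 1))
}

fmt_mean_sd_range <- function(s) {
  if (s$n == 0) return("-")
  sprintf("%.1f (%.1f), %g-%g", round_half_up(s$mean, 1),
          round_half_up(s$sd, 1), s$min, s$max)
}

count_levels <- function(x, levels) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "missing"
  vapply(levels, function(l) sum(x == l), 0L)
}

dist_rows <- function(variable, x, levels, labels = levels) {
  n <- count_levels(x, levels)
  denom <- length(x)
  data.frame(
    variable = variable, level = labels, n = as.integer(n),
    pct = round_half_up(ifelse(denom > 0, 100 * n / denom, NA_real_), 1),
    stringsAsFactors = FALSE
  )
}

ETHNICITY_LEVELS <- c("white_british", "other", "pakistani", "missing")
EDUCATION_LEVELS <- c("higher", "compulsory", "missing")
FINANCE_LEVELS <- c("living_comfortably", "doing_alright",
                    "just_about_getting_by", "quite_difficult",
                    "very_difficult", "missing")
IMD_LEVELS <- c("1", "2", "3", "4", "5", "missing")

#' Assemble the analysis report
#'
#' Builds machine-readable analogues of the published tables from a
#' completed pipeline run: prevalence comparison against literature
#' reference constants (table3), per-condition diagnostic timing and
#' sociodemographics (table4), indicator code frequencies in the
#' potential-only group (table5), tested between-group comparisons --
#' Pearson chi-square for sex and maternal education, two-sample t for
#' maternal age and age at first diagnosis, both pooled and Welch
#' variants (table6) -- and untested covariate distributions (table7).
#' Display rounding: statistics to 1 dp, p-values to 2 dp, percentages to
#' 1 dp, prevalences half-up to integers; full-precision values are kept
#' alongside in `tests`.
#'
#' If the maternal covariate table is absent the covariate sections are
#' marked unavailable rather than failing.
#'
#' @param run A `dd_run` from [run_ascertainment()], or a list with the
#'   same fields.
#' @return A `dd_report`: `tables` (data frames `table3` .. `table7`),
#'   `tests` (full-precision test objects), `prevalence`, `notes`.
#' @export
build_report <- function(run) {
  summary <- run$summary
  cl <- run$classifications
  children <- run$included
  maternal <- run$maternal
  cls <- run$cls
  ref <- reference_prevalence()
  n_total <- summary$n_total
  have_cov <- !is.null(maternal) && nrow(maternal) > 0
  notes <- character(0)

  prev_of <- function(num) {
    if (n_total == 0) {
      return(data.frame(numerator = num, denominator = 0, rate = NA_real_,
                        per_10000 = 0L, suppressed = FALSE))
    }
    prevalence_per_10000(num, n_total)
  }

  # ---- table 3: prevalence comparison -------------------------------------
  cond_counts <- summary$per_condition
  suppressed_cats <- summary$suppressed_categories
  row3 <- function(label, uk, bradford, numerator, suppressed = FALSE) {
    if (suppressed || is.na(numerator)) {
      p <- 0L; r <- NA_real_; numerator <- NA_integer_; suppressed <- TRUE
    } else {
      pe <- prev_of(numerator)
      p <- pe$per_10000; r <- pe$rate; suppressed <- pe$suppressed
    }
    data.frame(condition = label, uk = uk, bradford = bradford,
               bib_n = numerator, bib_per_10000 = p, bib_rate = r,
               suppressed = suppressed, stringsAsFactors = FALSE)
  }
  table3 <- rbind(
    row3("disability_conditions", ref$uk$disability_conditions,
         ref$bradford$disability_conditions, summary$n_probable),
    row3("mod_severe_ld", ref$uk$mod_severe_ld, NA,
         cond_counts[["mod_severe_ld"]],
         "mod_severe_ld" %in% suppressed_cats),
    row3("asd", ref$uk$asd, ref$bradford$asd, cond_counts[["asd"]],
         "asd" %in% suppressed_cats),
    row3("cerebral_palsy", ref$uk$cerebral_palsy, ref$bradford$cerebral_palsy,
         cond_counts[["cerebral_palsy"]],
         "cerebral_palsy" %in% suppressed_cats),
    row3("down_syndrome", ref$uk$down_syndrome, NA,
         cond_counts[["down_syndrome"]],
         "down_syndrome" %in% suppressed_cats),
    row3("fragile_x", ref$uk$fragile_x, NA, cond_counts[["fragile_x"]],
         "fragile_x" %in% suppressed_cats),
    row3("potential_disability_indicators", ref$uk$indicators, NA,
         summary$n_any_indicator)
  )
  combined <- prev_of(summary$n_ascertained)

  # ---- joins for covariates ----------------------------------------------
  cl$sex <- children$sex[match(cl$child_id, children$child_id)]
  if (have_cov) {
    mid <- children$mother_id[match(cl$child_id, children$child_id)]
    midx <- match(mid, maternal$mother_id)
    cl$ethnicity <- maternal$ethnicity[midx]
    cl$education <- maternal$education[midx]
    cl$maternal_age <- maternal$age_at_birth[midx]
    cl$parity <- maternal$parity[midx]
    cl$cohabiting <- maternal$cohabiting[midx]
    cl$finance <- maternal$subjective_finance[midx]
    cl$imd <- maternal$imd_quintile[midx]
  }
  is_prob <- cl$group == "probable"
  is_pot <- cl$group == "potential_only"

  # ---- table 4: per-condition characteristics -----------------------------
  retained <- names(cond_counts)[!is.na(cond_counts) & cond_counts > 0]
  col4 <- function(sel, label) {
    n <- sum(sel)
    def <- sum(cl$indicator_before_condition[sel] %in% TRUE)
    cond_age <- age_summary(cl$first_condition_age[sel])
    any_age <- age_summary(cl$first_any_age[sel])
    male <- sum(cl$sex[sel] == "male", na.rm = TRUE)
    rows <- c(
      n = as.character(n),
      indicator_before_condition = fmt_pct(def, n),
      age_condition_diagnosed_months = fmt_mean_sd_range(cond_age),
      age_first_diagnosis_months = fmt_mean_sd_range(any_age),
      sex_male = fmt_pct(male, n)
    )
    if (have_cov) {
      eth <- count_levels(cl$ethnicity[sel], ETHNICITY_LEVELS)
      edu <- count_levels(cl$education[sel], EDUCATION_LEVELS)
      mat <- age_summary(cl$maternal_age[sel])
      rows <- c(rows,
        ethnicity_white_british = fmt_pct(eth[["white_british"]], n),
        ethnicity_pakistani = fmt_pct(eth[["pakistani"]], n),
        education_higher = fmt_pct(edu[["higher"]], n),
        education_compulsory = fmt_pct(edu[["compulsory"]], n),
        education_missing = fmt_pct(edu[["missing"]], n),
        maternal_age_years = fmt_mean_sd_range(mat)
      )
    } else {
      rows <- c(rows, covariates = "unavailable")
    }
    stats::setNames(data.frame(rows, stringsAsFactors = FALSE), label)
  }
  cols4 <- lapply(retained, function(cat) {
    col4(is_prob & has_category(cl, "probable_categories", cat), cat)
  })
  cols4 <- c(cols4, list(col4(is_prob, "total")))
  table4 <- do.call(cbind, cols4)
  table4 <- cbind(variable = rownames(table4), table4)
  rownames(table4) <- NULL

  # ---- table 5: indicator code frequencies (potential-only) ---------------
  freq <- summary$code_usage$indicator_code_frequencies
  if (!is.null(freq) && nrow(freq) > 0) {
    desc <- cls$raw$description[match(freq$code, cls$raw$code)]
    desc[is.na(desc)] <- ""
    table5 <- data.frame(category = freq$category, code = freq$code,
                         description = desc, n_records = freq$n_records,
                         stringsAsFactors = FALSE)
  } else {
    table5 <- data.frame(category = character(), code = character(),
                         description = character(), n_records = integer())
  }

  # ---- table 6: tested between-group comparisons --------------------------
  tests <- list()
  rows6 <- list()
  add_row6 <- function(variable, pot, prob, test) {
    rows6[[length(rows6) + 1]] <<- data.frame(
      variable = variable, potential_only = pot, probable = prob,
      statistic = round_half_up(test$statistic, 1),
      p_value = round_half_up(test$p_value, 2),
      variant = test$variant, stringsAsFactors = FALSE)
  }
  can_test <- sum(is_prob) > 0 && sum(is_pot) > 0
  if (can_test) {
    sex_tab <- rbind(potential_only = count_levels(cl$sex[is_pot],
                                                   c("female", "male")),
                     probable = count_levels(cl$sex[is_prob],
                                             c("female", "male")))
    if (all(rowSums(sex_tab) > 0) && all(colSums(sex_tab) > 0)) {
      tests$sex <- pearson_chi2(sex_tab)
      add_row6("sex",
               paste(sprintf("%s %d", colnames(sex_tab), sex_tab[1, ]),
                     collapse = ", "),
               paste(sprintf("%s %d", colnames(sex_tab), sex_tab[2, ]),
                     collapse = ", "),
               tests$sex)
    }
    if (have_cov) {
      # missing excluded from the test
      edu_tab <- rbind(
        potential_only = count_levels(cl$education[is_pot],
                                      EDUCATION_LEVELS)[1:2],
        probable = count_levels(cl$education[is_prob], EDUCATION_LEVELS)[1:2])
      if (all(rowSums(edu_tab) > 0) && all(colSums(edu_tab) > 0)) {
        tests$education <- pearson_chi2(edu_tab)
        add_row6("education",
                 paste(sprintf("%s %d", colnames(edu_tab), edu_tab[1, ]),
                       collapse = ", "),
                 paste(sprintf("%s %d", colnames(edu_tab), edu_tab[2, ]),
                       collapse = ", "),
                 tests$education)
      }
      ma_pot <- cl$maternal_age[is_pot & !is.na(cl$maternal_age)]
      ma_prob <- cl$maternal_age[is_prob & !is.na(cl$maternal_age)]
      if (length(ma_pot) >= 2 && length(ma_prob) >= 2) {
        tests$maternal_age_pooled <- two_sample_t(ma_pot, ma_prob, "pooled")
        tests$maternal_age_welch <- two_sample_t(ma_pot, ma_prob, "welch")
        add_row6("maternal_age_years",
                 fmt_mean_sd_range(age_summary(ma_pot)),
                 fmt_mean_sd_range(age_summary(ma_prob)),
                 tests$maternal_age_pooled)
      }
    }
    fa_pot <- cl$first_any_age[is_pot & !is.na(cl$first_any_age)]
    fa_prob <- cl$first_any_age[is_prob & !is.na(cl$first_any_age)]
    if (length(fa_pot) >= 2 && length(fa_prob) >= 2) {
      tests$first_diagnosis_age_pooled <- two_sample_t(fa_pot, fa_prob,
                                                       "pooled")
      tests$first_diagnosis_age_welch <- two_sample_t(fa_pot, fa_prob,
                                                      "welch")
      add_row6("first_diagnosis_age_months",
               fmt_mean_sd_range(age_summary(fa_pot)),
               fmt_mean_sd_range(age_summary(fa_prob)),
               tests$first_diagnosis_age_pooled)
    }
    notes <- c(notes, paste(
      "Continuous comparisons report both pooled and Welch t variants",
      "computed from the underlying values; t statistics computed from",
      "rounded published summary statistics are not expected to reproduce",
      "statistics computed from raw data."))
  }
  table6 <- if (length(rows6) > 0) do.call(rbind, rows6) else
    data.frame(variable = character(), potential_only = character(),
               probable = character(), statistic = numeric(),
               p_value = numeric(), variant = character())
  if (have_cov && can_test) {
    notes <- c(notes,
               "Missing covariate values were excluded from the tests.")
  }
  if (!have_cov) {
    notes <- c(notes, "Maternal covariate table unavailable; covariate sections omitted.")
  }

  # ---- table 7: untested covariate distributions --------------------------
  if (have_cov) {
    sect <- function(sel, group) {
      out <- rbind(
        dist_rows("parity", cl$parity[sel],
                  c("first_child", "two_or_more", "missing")),
        dist_rows("cohabiting", cl$cohabiting[sel],
                  c("yes", "no", "missing")),
        dist_rows("ethnicity", cl$ethnicity[sel], ETHNICITY_LEVELS),
        dist_rows("subjective_finance", cl$finance[sel], FINANCE_LEVELS),
        dist_rows("imd_quintile", cl$imd[sel], IMD_LEVELS)
      )
      cbind(group = group, out)
    }
    table7 <- rbind(sect(is_pot, "potential_only"),
                    sect(is_prob, "probable"))
  } else {
    table7 <- data.frame(group = character(), variable = character(),
                         level = character(), n = integer(), pct = numeric())
  }

  structure(
    list(
      tables = list(table3 = table3, table4 = table4, table5 = table5,
                    table6 = table6, table7 = table7),
      tests = tests,
      prevalence = list(
        combined = combined,
        probable = prev_of(summary$n_probable),
        potential_only = prev_of(summary$n_potential_only)
      ),
      summary = summary,
      notes = notes
    ),
    class = "dd_report"
  )
}

#' @export
print.dd_report <- function(x, ...) {
  s <- x$summary
  cat("=== Developmental-disability ascertainment report ===\n")
  cat(sprintf("Included cohort N = %d; ascertained %d (%.1f%%)\n",
              s$n_total, s$n_ascertained,
              round_half_up(s$pct_ascertained, 1)))
  cat(sprintf("Combined prevalence %d per 10,000 (probable %d, potential-only %d)\n",
              x$prevalence$combined$per_10000,
              x$prevalence$probable$per_10000,
              x$prevalence$potential_only$per_10000))
  cat("\n-- Prevalence comparison (per 10,000) --\n")
  print(x$tables$table3, row.names = FALSE)
  cat("\n-- Probable-disability group --\n")
  print(x$tables$table4, row.names = FALSE)
  cat("\n-- Between-group comparisons --\n")
  print(x$tables$table6, row.names = FALSE)
  if (length(x$notes) > 0) {
    cat("\nNotes:\n")
    for (n in x$notes) cat("  -", n, "\n")
  }
  invisible(x)
}

#' Write report tables and JSON bundle
#'
#' @param report A `dd_report`.
#' @param dir Output directory.
#' @return Vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  s <- report$summary
  json <- list(
    summary = list(
      n_total = s$n_total, n_probable = s$n_probable,
      n_potential_only = s$n_potential_only, n_neither = s$n_neither,
      n_suppressed = s$n_suppressed, n_ascertained = s$n_ascertained,
      pct_ascertained = s$pct_ascertained, n_both = s$n_both,
      pct_both_of_probable = s$pct_both_of_probable,
      n_any_indicator = s$n_any_indicator,
      n_multi_indicator = s$n_multi_indicator,
      pct_multi_indicator = s$pct_multi_indicator,
      per_condition = as.list(s$per_condition),
      suppressed_categories = s$suppressed_categories
    ),
    prevalence = lapply(report$prevalence, function(p) as.list(p[1, ])),
    tests = lapply(report$tests, function(t) {
      t[c("statistic", "df", "p_value", "variant")]
    }),
    notes = report$notes
  )
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, p))
}
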