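# Seeded synthetic linked mother-child cohort generator. Emulates the
# statistical structure the ascertainment pipeline assumes: coded events
# with deferred-diagnosis behaviour, group-specific sociodemographics,
# exclusion-rule strata and out-of-list background noise codes. It makes
# no attempt to model true clinical incidence or comorbidity beyond that.

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study cohort: per-condition prevalences equal to
#' the observed counts over 9,727 included children, deferral (an
#' indicator recorded strictly before the first condition code)
#' probabilities matching the observed per-condition deferral
#' proportions, age-at-diagnosis distributions truncated-normal with the
#' observed means/SDs, and sociodemographic mixtures with the observed
#' group margins.
#'
#' @param n_children Number of child records to generate (default 12,196,
#'   the pre-exclusion cohort size).
#' @param seed Integer seed; the same configuration and seed reproduce
#'   byte-identical output files.
#' @param condition_prevalence Named per-child probability of each of the
#'   five condition categories (mutually exclusive draws).
#' @param deferral_prob Named probability, per condition, that a child
#'   with that condition receives an indicator code strictly before the
#'   first condition code (possible only when the condition age is >= 1
#'   month).
#' @param later_indicator_prob Probability a condition child additionally
#'   receives an indicator on/after the condition date.
#' @param indicator_only_prevalence Probability a non-condition child
#'   receives indicator codes only.
#' @param indicator_category_mix Named probabilities over the four
#'   indicator categories.
#' @param condition_age Named list of `c(mean, sd, lo, hi)` truncated
#'   normal parameters (months) per condition.
#' @param indicator_age `c(mean, sd, lo, hi)` for indicator ages (months).
#' @param multi_indicator_prob Probability an indicator-only child gains
#'   each further indicator record (geometric continuation, max 3).
#' @param repeat_code_prob Probability a condition child has the condition
#'   coded again (same or later date).
#' @param noise_rate Probability a child carries one background code from
#'   the reserved out-of-list alphabet (codes beginning `"Q"`).
#' @param demographics Per-group sociodemographic mixtures: named lists
#'   with `sex_male`, `edu_higher`, `mat_age_mean`, `mat_age_sd`,
#'   `eth_wb`, `eth_pak` for each condition, `indicator_only`, `neither`.
#' @param exclusion_rates Probabilities for `withdrawn_died`, `no_link`,
#'   `no_baseline` flags and the `sibling` rate (share of children who are
#'   a later sibling of the previous mother).
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_children = 12196L,
    seed = 1L,
    condition_prevalence = c(cerebral_palsy = 12 / 9727,
                             down_syndrome = 24 / 9727,
                             fragile_x = 3 / 9727,
                             asd = 47 / 9727,
                             mod_severe_ld = 0),
    deferral_prob = c(cerebral_palsy = 0.5, down_syndrome = 0,
                      fragile_x = 1 / 3, asd = 17 / 47,
                      mod_severe_ld = 0),
    later_indicator_prob = 0.25,
    indicator_only_prevalence = 394 / 9727,
    indicator_category_mix = c(dev_delay = 480 / 521,
                               gen_dev_disorders = 31 / 521,
                               gen_disabilities = 3 / 521,
                               generic_disability = 7 / 521),
    condition_age = list(
      cerebral_palsy = c(mean = 29.6, sd = 19.5, lo = 0, hi = 58),
      down_syndrome = c(mean = 0.3, sd = 0.7, lo = 0, hi = 3),
      fragile_x = c(mean = 32, sd = 23.2, lo = 0, hi = 60),
      asd = c(mean = 48.7, sd = 7.6, lo = 32, hi = 60),
      mod_severe_ld = c(mean = 32, sd = 23.2, lo = 0, hi = 60)),
    indicator_age = c(mean = 34.8, sd = 14.3, lo = 0, hi = 59),
    multi_indicator_prob = 0.241,
    repeat_code_prob = 24 / 83,
    noise_rate = 0.05,
    demographics = list(
      cerebral_palsy = list(sex_male = 5 / 12, edu_higher = 0.5,
                            mat_age_mean = 24.8, mat_age_sd = 6.6,
                            eth_wb = 5 / 12, eth_pak = 7 / 12),
      down_syndrome = list(sex_male = 0.5, edu_higher = 11 / 24,
                           mat_age_mean = 34.1, mat_age_sd = 8.1,
                           eth_wb = 16 / 24, eth_pak = 8 / 24),
      fragile_x = list(sex_male = 0.8, edu_higher = 0.5,
                       mat_age_mean = 30, mat_age_sd = 6,
                       eth_wb = 0.5, eth_pak = 0.5),
      asd = list(sex_male = 37 / 47, edu_higher = 31 / 47,
                 mat_age_mean = 28.2, mat_age_sd = 5.3,
                 eth_wb = 27 / 47, eth_pak = 20 / 47),
      mod_severe_ld = list(sex_male = 0.6, edu_higher = 0.4,
                           mat_age_mean = 28, mat_age_sd = 6,
                           eth_wb = 0.4, eth_pak = 0.5),
      indicator_only = list(sex_male = 280 / 394, edu_higher = 182 / 394,
                            mat_age_mean = 27.4, mat_age_sd = 5.7,
                            eth_wb = 0.404, eth_pak = 0.437),
      neither = list(sex_male = 0.51, edu_higher = 0.40,
                     mat_age_mean = 27.3, mat_age_sd = 5.6,
                     eth_wb = 0.39, eth_pak = 0.45)),
    exclusion_rates = c(withdrawn_died = 0.025, no_link = 0.10,
                        no_baseline = 0.065, sibling = 0.02)) {
  rates <- c(condition_prevalence, deferral_prob, later_indicator_prob,
             indicator_only_prevalence, indicator_category_mix,
             multi_indicator_prob, repeat_code_prob, noise_rate,
             exclusion_rates)
  if (any(rates < 0 | rates > 1)) {
    stop("all generator rates must lie in [0, 1]")
  }
  for (p in condition_age) {
    if (p[["lo"]] < 0 || p[["hi"]] > 60) {
      stop("condition age support must lie within [0, 60] months")
    }
  }
  structure(as.list(environment()), class = "generator_config")
}

# truncated-normal sampler on [lo, hi] by inverse-CDF
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

BIRTH_MONTHS <- format(seq(as.Date("2007-03-01"), as.Date("2010-12-01"),
                           by = "month"), "%Y-%m")

sample_codes <- function(cls, category, n) {
  codes <- cls$entries[[category]]
  codes[1L + (stats::runif(n) * length(codes)) %/% 1]
}

# event at a given completed-month age; day_offset 0..27 keeps the date
# inside the month (so the floored age is exactly age_months)
event_df <- function(child_id, code, birth_month, age_months, day_offset) {
  stopifnot(all(day_offset >= 0 & day_offset <= 27))
  ym <- as.integer(substr(birth_month, 1, 4)) * 12L +
    as.integer(substr(birth_month, 6, 7)) - 1L + as.integer(age_months)
  date <- as.Date(sprintf("%04d-%02d-01", ym %/% 12L, ym %% 12L + 1L)) +
    day_offset
  data.frame(child_id = child_id, code = code,
             event_date = date, stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic linked cohort
#'
#' Produces the three cohort tables (children, maternal baseline, coded
#' events) plus a generation manifest. The same configuration and seed
#' give identical output. Background noise codes are drawn from a
#' reserved alphabet (`"Q"`-prefixed) checked disjoint from the supplied
#' code lists, so noise can never classify a child.
#'
#' @param config A [generator_config()].
#' @param cls Code lists used for event codes (default packaged).
#' @param dir Optional output directory; when given the three CSVs and
#'   `manifest.json` are written there.
#' @return List with `children`, `maternal`, `events` data frames and
#'   `manifest`.
#' @export
generate_cohort <- function(config = generator_config(),
                            cls = load_codelists(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_children
  child_id <- sprintf("S%06d", seq_len(n))
  birth_month <- BIRTH_MONTHS[1L + (seq_len(n) - 1L) %% length(BIRTH_MONTHS)]

  # mothers: a `sibling` fraction of children reuse the previous mother
  sibling <- c(FALSE, stats::runif(n - 1) < config$exclusion_rates[["sibling"]])
  mother_index <- cumsum(!sibling)
  mother_id <- sprintf("SM%06d", mother_index)

  withdrawn_died <- stats::runif(n) < config$exclusion_rates[["withdrawn_died"]]
  withdrawn <- withdrawn_died & stats::runif(n) < 0.5
  died <- withdrawn_died & !withdrawn
  has_link <- stats::runif(n) >= config$exclusion_rates[["no_link"]]
  no_baseline_mother <- stats::runif(max(mother_index)) <
    config$exclusion_rates[["no_baseline"]]
  has_baseline <- !no_baseline_mother[mother_index]

  # mutually exclusive condition assignment
  cp <- config$condition_prevalence
  cum <- cumsum(cp)
  u <- stats::runif(n)
  condition <- rep(NA_character_, n)
  lo <- 0
  for (cat in names(cp)) {
    condition[u >= lo & u < cum[[cat]]] <- cat
    lo <- cum[[cat]]
  }
  indicator_only <- is.na(condition) &
    stats::runif(n) < config$indicator_only_prevalence
  group <- ifelse(!is.na(condition), condition,
                  ifelse(indicator_only, "indicator_only", "neither"))

  # ---- events -------------------------------------------------------------
  # indicator codes are sampled only from codes exclusive to the potential
  # part: a code also on a condition list would reclassify an
  # indicator-only child as probable under the default precedence
  probable_union <- unique(unlist(cls$entries[DD_PROBABLE_CATEGORIES],
                                  use.names = FALSE))
  ind_pool <- lapply(cls$entries[DD_POTENTIAL_CATEGORIES], setdiff,
                     y = probable_union)
  mix <- config$indicator_category_mix
  draw_icat <- function(k) {
    names(mix)[pmin(findInterval(stats::runif(k), cumsum(mix)) + 1L,
                    length(mix))]
  }
  draw_icode <- function(icat) {
    vapply(icat, function(cat) {
      codes <- ind_pool[[cat]]
      codes[1L + (stats::runif(1) * length(codes)) %/% 1]
    }, character(1), USE.NAMES = FALSE)
  }
  events <- list()
  day_of <- function(k) as.integer(1L + (stats::runif(k) * 26) %/% 1)  # 1..26

  for (cat in names(cp)) {
    idx <- which(condition == cat)
    if (length(idx) == 0) next
    p <- config$condition_age[[cat]]
    age <- as.integer(round(rtrunc_norm(length(idx), p[["mean"]], p[["sd"]],
                                        p[["lo"]], p[["hi"]])))
    code <- sample_codes(cls, cat, length(idx))
    cond_day <- day_of(length(idx))
    events[[length(events) + 1]] <-
      event_df(child_id[idx], code, birth_month[idx], age, cond_day)

    # deferred indicator strictly before the condition date
    defer <- stats::runif(length(idx)) < config$deferral_prob[[cat]] & age >= 1L
    if (any(defer)) {
      d_idx <- idx[defer]
      d_age <- (stats::runif(sum(defer)) * age[defer]) %/% 1  # 0..age-1
      events[[length(events) + 1]] <-
        event_df(child_id[d_idx], draw_icode(draw_icat(sum(defer))),
                 birth_month[d_idx], as.integer(d_age), 0L)
    }
    # indicator on/after the condition date: day 27 >= any condition day,
    # so an equal age never produces a spuriously earlier date
    later <- stats::runif(length(idx)) < config$later_indicator_prob & !defer
    if (any(later)) {
      l_idx <- idx[later]
      l_age <- pmin(age[later] +
                      as.integer((stats::runif(sum(later)) *
                                    (61L - age[later])) %/% 1), 60L)
      events[[length(events) + 1]] <-
        event_df(child_id[l_idx], draw_icode(draw_icat(sum(later))),
                 birth_month[l_idx], l_age, 27L)
    }
    # repeat condition coding (same or later date); same-date repeats reuse
    # the original day with a different code so the record stays distinct
    rep_ <- stats::runif(length(idx)) < config$repeat_code_prob
    if (any(rep_)) {
      r_idx <- idx[rep_]
      same_date <- stats::runif(sum(rep_)) < 0.2
      r_age <- ifelse(same_date, age[rep_],
                      pmin(age[rep_] + 1L +
                             as.integer((stats::runif(sum(rep_)) * 12) %/% 1),
                           60L))
      r_day <- ifelse(same_date, cond_day[rep_], day_of(sum(rep_)))
      events[[length(events) + 1]] <-
        event_df(child_id[r_idx], sample_codes(cls, cat, sum(rep_)),
                 birth_month[r_idx], as.integer(r_age), as.integer(r_day))
    }
  }

  idx <- which(indicator_only)
  if (length(idx) > 0) {
    ia <- config$indicator_age
    n_extra <- rep(0L, length(idx))
    cont <- stats::runif(length(idx)) < config$multi_indicator_prob
    n_extra[cont] <- 1L
    cont2 <- cont & stats::runif(length(idx)) < config$multi_indicator_prob
    n_extra[cont2] <- 2L
    for (k in 0:2) {
      sel <- which(n_extra >= k)
      if (length(sel) == 0) next
      age <- as.integer(round(rtrunc_norm(length(sel), ia[["mean"]],
                                          ia[["sd"]], ia[["lo"]],
                                          ia[["hi"]])))
      age <- pmin(age + 3L * k, 60L)
      events[[length(events) + 1]] <-
        event_df(child_id[idx[sel]], draw_icode(draw_icat(length(sel))),
                 birth_month[idx[sel]], age, day_of(length(sel)))
    }
  }

  # background noise codes from the reserved "Q" alphabet
  noisy <- which(stats::runif(n) < config$noise_rate)
  if (length(noisy) > 0) {
    ncode <- sprintf("Q%04d", as.integer((stats::runif(length(noisy)) *
                                            10000) %/% 1))
    listed <- unlist(cls$entries, use.names = FALSE)
    if (any(ncode %in% listed)) {
      stop("noise alphabet collides with the code lists")
    }
    age <- as.integer((stats::runif(length(noisy)) * 61) %/% 1)
    events[[length(events) + 1]] <-
      event_df(child_id[noisy], ncode, birth_month[noisy], age,
               day_of(length(noisy)))
  }

  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(child_id = character(), code = character(),
               event_date = as.Date(character()))
  events <- events[order(events$child_id, events$event_date, events$code), ,
                   drop = FALSE]
  rownames(events) <- NULL

  # ---- sociodemographics --------------------------------------------------
  demo_of <- function(field) {
    vapply(group, function(g) config$demographics[[g]][[field]], 0)
  }
  sex <- ifelse(stats::runif(n) < demo_of("sex_male"), "male", "female")
  edu <- ifelse(stats::runif(n) < demo_of("edu_higher"), "higher",
                "compulsory")
  mat_age <- round(pmin(pmax(stats::rnorm(n, demo_of("mat_age_mean"),
                                          demo_of("mat_age_sd")), 15), 49), 1)
  u_eth <- stats::runif(n)
  eth <- ifelse(u_eth < demo_of("eth_wb"), "white_british",
                ifelse(u_eth < demo_of("eth_wb") + demo_of("eth_pak"),
                       "pakistani", "other"))
  parity <- ifelse(stats::runif(n) < 0.9, "first_child", "two_or_more")
  cohab <- ifelse(stats::runif(n) < 0.84, "yes", "no")
  fin_lv <- c("living_comfortably", "doing_alright", "just_about_getting_by",
              "quite_difficult", "very_difficult")
  fin <- fin_lv[findInterval(stats::runif(n),
                             cumsum(c(0.21, 0.45, 0.24, 0.06))) + 1L]
  imd <- as.character(findInterval(stats::runif(n),
                                   cumsum(c(0.02, 0.03, 0.09, 0.17))) + 1L)

  children <- data.frame(
    child_id = child_id, mother_id = mother_id, birth_month = birth_month,
    sex = sex, withdrawn = withdrawn, died = died,
    has_primary_care_link = has_link, has_maternal_baseline = has_baseline,
    stringsAsFactors = FALSE
  )
  first_child <- !duplicated(mother_id)
  maternal <- data.frame(
    mother_id = mother_id[first_child & has_baseline],
    ethnicity = eth[first_child & has_baseline],
    education = edu[first_child & has_baseline],
    age_at_birth = mat_age[first_child & has_baseline],
    parity = parity[first_child & has_baseline],
    cohabiting = cohab[first_child & has_baseline],
    subjective_finance = fin[first_child & has_baseline],
    imd_quintile = imd[first_child & has_baseline],
    stringsAsFactors = FALSE
  )

  manifest <- list(
    seed = config$seed,
    n_children = n,
    n_maternal = nrow(maternal),
    n_events = nrow(events),
    realized_condition_counts = as.list(table(
      factor(condition, levels = names(cp)))),
    n_indicator_only = sum(indicator_only),
    n_neither = sum(group == "neither")
  )

  out <- list(children = children, maternal = maternal, events = events,
              manifest = manifest)
  if (!is.null(dir)) {
    paths <- write_cohort(out, dir)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}
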