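# Deterministic fixture cohort. Constructed (not sampled) so that the
# full pipeline reproduces the headline study counts exactly: 12,196
# child records of which 2,469 are excludable and 9,727 included; after
# small-cell suppression of the 3 Fragile X children, 83 probable
# (12 cerebral palsy / 24 Down / 47 ASD), 394 potential-only, 44 probable
# children with at least one indicator, 95 potential-only children with
# more than one indicator, and deferral counts 6/0/17 (CP/Down/ASD).
# Covariate margins match the published group tables so the between-group
# chi-square statistics reproduce from the fixture itself.

# integer "ages" (or 1-dp values) placed at normal quantiles: a
# deterministic stand-in for a truncated-normal sample with the published
# mean/sd/range
quantile_ages <- function(n, mean, sd, lo, hi, digits = 0) {
  x <- stats::qnorm((seq_len(n) - 0.5) / n, mean, sd)
  round(pmin(pmax(x, lo), hi), digits)
}

seq_levels <- function(counts) {
  rep(names(counts), counts)
}

cycle_levels <- function(n, counts) {
  # deterministic approximate mixture: proportions out of 100 per cycle
  stopifnot(sum(counts) == 100)
  seq_levels(counts)[(seq_len(n) - 1L) %% 100L + 1L]
}

#' Deterministic fixture cohort reproducing the headline study counts
#'
#' Builds, by construction rather than sampling, a linked cohort whose
#' pipeline output matches the published headline numbers (see the
#' package vignette). Intended for end-to-end validation; the stochastic
#' [generate_cohort()] exists separately for property testing.
#'
#' @param dir Optional directory; when given the three CSVs and
#'   `manifest.json` are written there.
#' @param cls Code lists (packaged default); fixture codes are drawn from
#'   these lists.
#' @return List with `children`, `maternal`, `events`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' fx <- make_bib_fixture()
#' run <- run_ascertainment(fx$children, fx$maternal, fx$events)
#' run$summary$n_ascertained  # 477
#' }
make_bib_fixture <- function(dir = NULL, cls = load_codelists()) {
  n_inc <- 9727L
  id <- function(i) sprintf("C%05d", i)
  inc_ids <- id(seq_len(n_inc))
  inc_bm <- BIRTH_MONTHS[(seq_len(n_inc) - 1L) %% length(BIRTH_MONTHS) + 1L]

  # group layout over included ids
  cp_i <- 1:12; ds_i <- 13:36; asd_i <- 37:83; fx_i <- 84:86
  pot_i <- 87:480; nei_i <- 481:9727
  prob_i <- 1:83  # retained probable after Fragile X suppression

  # ---- condition events ---------------------------------------------------
  ev <- list()
  add <- function(i, code, age, day_offset) {
    ev[[length(ev) + 1]] <<- event_df(id(i), code, inc_bm[i],
                                      as.integer(age), day_offset)
  }
  cp_age <- quantile_ages(12, 29.6, 19.5, 0, 58)
  ds_age <- quantile_ages(24, 0.3, 0.7, 0, 3)
  asd_age <- quantile_ages(47, 48.7, 7.6, 32, 60)
  fx_age <- c(1, 2, 24)

  cp_codes <- cls$entries$cerebral_palsy[1:3]
  ds_codes <- cls$entries$down_syndrome[1:2]
  asd_codes <- cls$entries$asd[1:6]
  add(cp_i, cp_codes[(cp_i - 1L) %% 3L + 1L], cp_age, 14L)
  add(ds_i, ds_codes[(ds_i - 1L) %% 2L + 1L], ds_age, 14L)
  add(asd_i, asd_codes[(asd_i - 1L) %% 6L + 1L], asd_age, 14L)
  add(fx_i, cls$entries$fragile_x[1], fx_age, 14L)

  # repeat condition coding for 14 ASD children: 11 on a later date (2
  # months on, one code not in the base palette) and 3 on the same date
  # (a different code, so the record is distinct) -> 97 condition records
  # over 13 distinct codes among the retained 83
  rep_diff <- 70:80
  add(rep_diff, c(cls$entries$asd[7], asd_codes[(rep_diff[-1] - 1L) %% 6L + 1L]),
      pmin(asd_age[rep_diff - 36L] + 2L, 60L), 19L)
  rep_same <- 81:83
  add(rep_same, cls$entries$asd[8], asd_age[rep_same - 36L], 14L)

  # ---- indicators in the probable group -----------------------------------
  # 44 of the 83 carry >=1 indicator: 23 strictly before the first
  # condition code (6 CP + 17 ASD; Down 0), 21 on/after it; 18 second
  # records. 62 indicator records over 16 distinct codes.
  ind_palette <- c(cls$entries$dev_delay[1:12],
                   cls$entries$gen_dev_disorders[1:4])
  pal_k <- 0L
  next_codes <- function(k) {
    out <- ind_palette[(pal_k + seq_len(k) - 1L) %% 16L + 1L]
    pal_k <<- pal_k + k
    out
  }
  defer_cp <- 7:12                     # the six oldest-diagnosed CP children
  add(defer_cp, next_codes(6), pmax(cp_age[defer_cp] - 6L, 0L), 0L)
  defer_asd <- 37:53
  add(defer_asd, next_codes(17), asd_age[defer_asd - 36L] - 12L, 0L)
  later_i <- c(1:3, 13:20, 54:63)      # 3 CP + 8 Down + 10 ASD, on/after
  later_age <- c(cp_age[1:3], ds_age[1:8], asd_age[54:63 - 36L]) + 6L
  add(later_i, next_codes(21), pmin(later_age, 60L), 26L)
  second_i <- 37:54                    # 18 second indicator records
  second_age <- asd_age[second_i - 36L] + 3L
  add(second_i, next_codes(18), pmin(second_age, 60L), 26L)

  # ---- potential-only indicators ------------------------------------------
  # 394 children, 521 records: 299 single-record children, 63 with two,
  # 32 with three; record-level code frequencies follow the published
  # indicator frequency table (18 + 11 + 2 + 2 distinct codes)
  pot_age <- quantile_ages(394, 34.8, 14.3, 0, 59)
  pool <- c(
    rep(cls$entries$dev_delay[1:18],
        c(151, 134, 101, 21, 16, 15, 10, 5, 5, 5, 3, 3, 3, 3, 2, 1, 1, 1)),
    rep(cls$entries$gen_dev_disorders[1:11],
        c(12, 5, 3, 2, 2, 2, 2, 1, 1, 1, 1)),
    rep(cls$entries$gen_disabilities[1:2], c(2, 1)),
    rep(cls$entries$generic_disability[1:2], c(6, 1))
  )
  # interleave by occurrence rank so a child's consecutive records differ
  pool <- pool[order(stats::ave(seq_along(pool), pool, FUN = seq_along),
                     seq_along(pool))]
  n_rec <- rep(c(1L, 2L, 3L), c(299L, 63L, 32L))    # per potential child
  child_of_rec <- rep(pot_i, n_rec)
  rec_rank <- sequence(n_rec)
  rec_age <- pmin(pot_age[child_of_rec - 86L] + 2L * (rec_rank - 1L), 60L)
  add(child_of_rec, pool[seq_along(child_of_rec)], rec_age,
      c(4L, 9L, 19L)[rec_rank])

  # ---- inert extras: noise, out-of-window, pre-birth ----------------------
  noise_i <- 481:530
  add(noise_i, sprintf("Q%04d", seq_along(noise_i)), 30L, 4L)
  add(531:532, cls$entries$asd[1], 61L, 4L)   # beyond the fifth birthday
  pre_birth <- data.frame(
    child_id = id(533L),
    code = cls$entries$down_syndrome[3],
    event_date = first_of_birth_month(inc_bm[533]) - 10,
    stringsAsFactors = FALSE
  )
  ev[[length(ev) + 1]] <- pre_birth

  # ---- excluded child records (2,469) -------------------------------------
  exc_wd <- 9728:10027    # withdrawn (200) or died (100)
  exc_nl <- 10028:11227   # no linked primary-care record
  exc_nb <- 11228:11996   # no maternal baseline questionnaire
  exc_sb <- 11997:12196   # later sibling of an included child
  exc_i <- c(exc_wd, exc_nl, exc_nb, exc_sb)
  exc_ids <- id(exc_i)
  exc_bm <- c(BIRTH_MONTHS[(c(exc_wd, exc_nl, exc_nb) - 1L) %%
                             length(BIRTH_MONTHS) + 1L],
              rep("2010-12", length(exc_sb)))
  exc_mother <- c(sprintf("M%05d", c(exc_wd, exc_nl, exc_nb)),
                  sprintf("M%05d", 481:680))  # siblings reuse included mothers
  # a coded event on an excluded child must not leak into the analysis
  ev[[length(ev) + 1]] <- event_df(id(9728L), cls$entries$asd[1],
                                   BIRTH_MONTHS[(9728L - 1L) %% 46L + 1L],
                                   40L, 4L)

  events <- do.call(rbind, ev)
  events <- events[order(events$child_id, events$event_date, events$code), ,
                   drop = FALSE]
  rownames(events) <- NULL

  # ---- children table -----------------------------------------------------
  sex <- character(n_inc)
  sex[cp_i] <- seq_levels(c(male = 5, female = 7))
  sex[ds_i] <- seq_levels(c(male = 12, female = 12))
  sex[asd_i] <- seq_levels(c(male = 37, female = 10))
  sex[fx_i] <- "male"
  sex[pot_i] <- seq_levels(c(male = 280, female = 114))
  sex[nei_i] <- c("male", "female")[(nei_i %% 2L) + 1L]

  children <- data.frame(
    child_id = c(inc_ids, exc_ids),
    mother_id = c(sprintf("M%05d", seq_len(n_inc)), exc_mother),
    birth_month = c(inc_bm, exc_bm),
    sex = c(sex, c("male", "female")[(exc_i %% 2L) + 1L]),
    withdrawn = c(rep(FALSE, n_inc), exc_i %in% 9728:9927),
    died = c(rep(FALSE, n_inc), exc_i %in% 9928:10027),
    has_primary_care_link = c(rep(TRUE, n_inc), !exc_i %in% exc_nl),
    has_maternal_baseline = c(rep(TRUE, n_inc), !exc_i %in% exc_nb),
    stringsAsFactors = FALSE
  )

  # ---- maternal covariates ------------------------------------------------
  eth <- edu <- par <- coh <- fin <- imd <- character(n_inc)
  mat_age <- numeric(n_inc)

  eth[cp_i] <- seq_levels(c(white_british = 5, pakistani = 7))
  eth[ds_i] <- seq_levels(c(white_british = 16, pakistani = 8))
  eth[asd_i] <- seq_levels(c(white_british = 27, pakistani = 20))
  eth[fx_i] <- c("white_british", "white_british", "pakistani")
  eth[pot_i] <- seq_levels(c(white_british = 159, other = 62,
                             pakistani = 172, missing = 1))
  eth[nei_i] <- cycle_levels(length(nei_i),
                             c(pakistani = 45, white_british = 39, other = 16))

  edu[cp_i] <- seq_levels(c(higher = 6, compulsory = 6))
  edu[ds_i] <- seq_levels(c(higher = 11, compulsory = 12, missing = 1))
  edu[asd_i] <- seq_levels(c(higher = 31, compulsory = 16))
  edu[fx_i] <- c("higher", "higher", "compulsory")
  edu[pot_i] <- seq_levels(c(higher = 182, compulsory = 212))
  edu[nei_i] <- cycle_levels(length(nei_i), c(compulsory = 60, higher = 40))

  mat_age[cp_i] <- quantile_ages(12, 24.8, 6.6, 18, 41, 1)
  mat_age[ds_i] <- quantile_ages(24, 34.1, 8.1, 18, 49, 1)
  mat_age[asd_i] <- quantile_ages(47, 28.2, 5.3, 18, 39, 1)
  mat_age[fx_i] <- c(30, 31, 32)
  mat_age[pot_i] <- quantile_ages(394, 27.4, 5.7, 15, 43, 1)
  mat_age[nei_i] <- quantile_ages(length(nei_i), 27.3, 5.6, 15, 45, 1)

  par[prob_i] <- seq_levels(c(first_child = 11, two_or_more = 1,   # CP
                              first_child = 22, two_or_more = 2,   # Down
                              first_child = 44, two_or_more = 3))  # ASD
  par[fx_i] <- "first_child"
  par[pot_i] <- seq_levels(c(first_child = 358, two_or_more = 36))
  par[nei_i] <- cycle_levels(length(nei_i),
                             c(first_child = 90, two_or_more = 10))

  coh[prob_i] <- seq_levels(c(yes = 10, no = 2, yes = 21, no = 3,
                              yes = 41, no = 6))
  coh[fx_i] <- "yes"
  coh[pot_i] <- seq_levels(c(yes = 328, no = 66))
  coh[nei_i] <- cycle_levels(length(nei_i), c(yes = 84, no = 16))

  fin[prob_i] <- seq_levels(c(living_comfortably = 25, doing_alright = 34,
                              just_about_getting_by = 18,
                              quite_difficult = 4, very_difficult = 2))
  fin[fx_i] <- "doing_alright"
  fin[pot_i] <- seq_levels(c(living_comfortably = 82, doing_alright = 176,
                             just_about_getting_by = 97,
                             quite_difficult = 23, very_difficult = 10,
                             missing = 6))
  fin[nei_i] <- cycle_levels(length(nei_i),
                             c(living_comfortably = 21, doing_alright = 45,
                               just_about_getting_by = 24,
                               quite_difficult = 7, very_difficult = 3))

  imd[prob_i] <- seq_levels(c("1" = 1, "2" = 4, "3" = 11, "4" = 18,
                              "5" = 49))
  imd[fx_i] <- "5"
  imd[pot_i] <- seq_levels(c("1" = 5, "2" = 10, "3" = 33, "4" = 68,
                             "5" = 278))
  imd[nei_i] <- cycle_levels(length(nei_i),
                             c("1" = 2, "2" = 3, "3" = 9, "4" = 17,
                               "5" = 69))

  n_exc_b <- length(exc_wd) + length(exc_nl)  # excluded mothers w/ baseline
  maternal <- data.frame(
    mother_id = c(sprintf("M%05d", seq_len(n_inc)),
                  sprintf("M%05d", c(exc_wd, exc_nl))),
    ethnicity = c(eth, rep(c("pakistani", "white_british"),
                           length.out = n_exc_b)),
    education = c(edu, rep("compulsory", n_exc_b)),
    age_at_birth = c(mat_age, rep(27, n_exc_b)),
    parity = c(par, rep("first_child", n_exc_b)),
    cohabiting = c(coh, rep("yes", n_exc_b)),
    subjective_finance = c(fin, rep("doing_alright", n_exc_b)),
    imd_quintile = c(imd, rep("5", n_exc_b)),
    stringsAsFactors = FALSE
  )

  manifest <- list(
    fixture = "bib",
    n_children = nrow(children),
    n_included_expected = n_inc,
    n_excludable = length(exc_i),
    n_maternal = nrow(maternal),
    n_events = nrow(events),
    group_layout = list(
      cerebral_palsy = length(cp_i), down_syndrome = length(ds_i),
      asd = length(asd_i), fragile_x = length(fx_i),
      potential_only = length(pot_i), neither = length(nei_i)
    ),
    expected = list(
      ascertained = 477L, probable = 83L, potential_only = 394L,
      both = 44L, multi_indicator = 95L,
      deferred = c(cerebral_palsy = 6L, down_syndrome = 0L, asd = 17L)
    )
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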