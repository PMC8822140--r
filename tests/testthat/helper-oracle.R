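# Independent oracles kept deliberately naive: plain loops and explicit
# formulas, sharing no code with the implementation paths they check.

# brute-force classifier: for each child, intersect the set of their
# windowed codes with every category's code set directly
oracle_classify <- function(children, events, cls,
                            config = ascertainment_config()) {
  out <- list()
  for (i in seq_len(nrow(children))) {
    cid <- children$child_id[i]
    anchor <- as.Date(paste0(children$birth_month[i], "-01"))
    probable <- character(0)
    potential <- character(0)
    cond_dates <- as.Date(character(0))
    ind_dates <- as.Date(character(0))
    cond_ages <- integer(0)
    all_ages <- integer(0)
    for (j in which(events$child_id == cid)) {
      d <- as.Date(events$event_date[j])
      if (d < anchor) next
      age <- (as.integer(format(d, "%Y")) - as.integer(format(anchor, "%Y"))) * 12L +
        (as.integer(format(d, "%m")) - as.integer(format(anchor, "%m")))
      if (age < config$window_months[1] || age > config$window_months[2]) next
      code <- events$code[j]
      cats <- character(0)
      for (cat in names(cls$entries)) {
        if (code %in% cls$entries[[cat]]) cats <- c(cats, cat)
      }
      in_prob <- any(cats %in% disability_categories("probable"))
      in_pot <- any(cats %in% disability_categories("potential"))
      if (in_prob && in_pot) {
        if (config$cross_part_precedence == "probable_wins") {
          cats <- cats[cats %in% disability_categories("probable")]
        } else if (config$cross_part_precedence == "potential_wins") {
          cats <- cats[cats %in% disability_categories("potential")]
        }
      }
      p_cats <- cats[cats %in% disability_categories("probable")]
      i_cats <- cats[cats %in% disability_categories("potential")]
      if (length(p_cats) > 0) {
        probable <- union(probable, p_cats)
        cond_dates <- c(cond_dates, d)
        cond_ages <- c(cond_ages, age)
      }
      if (length(i_cats) > 0) {
        potential <- union(potential, i_cats)
        ind_dates <- c(ind_dates, d)
      }
      if (length(p_cats) > 0 || length(i_cats) > 0) {
        all_ages <- c(all_ages, age)
      }
    }
    group <- if (length(probable) > 0) "probable" else
      if (length(potential) > 0) "potential_only" else "neither"
    out[[i]] <- data.frame(
      child_id = cid,
      group = group,
      probable_categories = paste(
        intersect(disability_categories("probable"), probable),
        collapse = ","),
      potential_categories = paste(
        intersect(disability_categories("potential"), potential),
        collapse = ","),
      first_condition_age = if (length(cond_ages) > 0) min(cond_ages)
        else NA_real_,
      first_any_age = if (length(all_ages) > 0) min(all_ages) else NA_real_,
      indicator_before_condition = if (group != "probable") NA else
        length(ind_dates) > 0 && min(ind_dates) < min(cond_dates),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# explicit Pearson statistic: the textbook double loop over cells
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# closed-form two-sample t from summary statistics
oracle_t_pooled <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
oracle_t_welch <- function(m1, s1, n1, m2, s2, n2) {
  (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
}

# small random cohort over a mixed code universe (listed codes, both-part
# codes and unlisted junk), with events scattered around the age window
random_small_cohort <- function(seed, cls, n_children = 30) {
  set.seed(seed)
  universe <- c(
    sample(unlist(cls$entries, use.names = FALSE), 30),
    c("Xa3HI", "Eu7y1", "Eu7z1"),            # cross-part codes
    sprintf("ZZ%03d", 1:10)                  # unlisted
  )
  children <- data.frame(
    child_id = sprintf("K%03d", seq_len(n_children)),
    mother_id = sprintf("KM%03d", seq_len(n_children)),
    birth_month = sample(c("2007-05", "2008-11", "2010-02"), n_children,
                         replace = TRUE),
    sex = sample(c("male", "female"), n_children, replace = TRUE),
    withdrawn = FALSE, died = FALSE, has_primary_care_link = TRUE,
    has_maternal_baseline = TRUE, stringsAsFactors = FALSE
  )
  n_events <- 4 * n_children
  kid <- sample(children$child_id, n_events, replace = TRUE)
  anchor <- as.Date(paste0(
    children$birth_month[match(kid, children$child_id)], "-01"))
  events <- data.frame(
    child_id = kid,
    code = sample(universe, n_events, replace = TRUE),
    event_date = anchor + sample(-30:2000, n_events, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(children = children, events = events)
}
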