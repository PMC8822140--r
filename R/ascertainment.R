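# Cohort exclusions, event windowing, per-child classification against the
# two-part code lists, group summaries and small-cell suppression.

#' Ascertainment configuration
#'
#' @param window_months Inclusive age window in completed months; the
#'   default `c(0, 60)` runs from birth to the fifth birthday, with the
#'   60th month in (the published age ranges extend to 60).
#' @param cross_part_precedence How a code printed in both a condition and
#'   an indicator list contributes: `"probable_wins"` (default; such a code
#'   is evidence of the condition only), `"potential_wins"`, or `"both"`.
#' @param one_child_rule Which child is kept when a mother has several:
#'   `"earliest_birth"` (default; lexicographic `child_id` breaks birth-month
#'   ties, so twins resolve deterministically) or `"lexicographic_id"`.
#' @param suppression_threshold Condition categories with fewer than this
#'   many children are suppressed for disclosure control (default 5).
#' @param suppress_denominator If `TRUE`, suppressed children are also
#'   removed from the denominator; the default `FALSE` keeps the
#'   included-cohort denominator unchanged, matching how the suppressed
#'   cohort is reported against the full included count.
#' @return An `ascertainment_config` list.
#' @export
ascertainment_config <- function(window_months = c(0L, 60L),
                                 cross_part_precedence = c("probable_wins",
                                                           "potential_wins",
                                                           "both"),
                                 one_child_rule = c("earliest_birth",
                                                    "lexicographic_id"),
                                 suppression_threshold = 5L,
                                 suppress_denominator = FALSE) {
  stopifnot(length(window_months) == 2, window_months[1] >= 0,
            window_months[1] <= window_months[2],
            suppression_threshold >= 0)
  structure(
    list(
      window_months = as.integer(window_months),
      cross_part_precedence = match.arg(cross_part_precedence),
      one_child_rule = match.arg(one_child_rule),
      suppression_threshold = as.integer(suppression_threshold),
      suppress_denominator = isTRUE(suppress_denominator)
    ),
    class = "ascertainment_config"
  )
}

#' Apply cohort exclusion rules
#'
#' Removes, in order: children withdrawn from the study or who died;
#' children without linked primary-care data; children without a maternal
#' baseline questionnaire; and all but one child per mother. The exclusion
#' log accounts for every removal exactly once, in that order.
#'
#' @param children Children data frame (see [read_cohort()]).
#' @param config An [ascertainment_config()].
#' @return List with `included` (children data frame) and `log`
#'   (an `exclusion_log`).
#' @export
apply_exclusions <- function(children, config = ascertainment_config()) {
  removed <- list()

  r1 <- children$withdrawn | children$died
  removed$withdrawn_or_died <- children$child_id[r1]
  children <- children[!r1, , drop = FALSE]

  r2 <- !children$has_primary_care_link
  removed$no_primary_care_link <- children$child_id[r2]
  children <- children[!r2, , drop = FALSE]

  r3 <- !children$has_maternal_baseline
  removed$no_maternal_baseline <- children$child_id[r3]
  children <- children[!r3, , drop = FALSE]

  if (nrow(children) > 0) {
    if (config$one_child_rule == "earliest_birth") {
      ord <- order(children$mother_id, children$birth_month,
                   children$child_id)
    } else {
      ord <- order(children$mother_id, children$child_id)
    }
    children <- children[ord, , drop = FALSE]
    r4 <- duplicated(children$mother_id)
  } else {
    r4 <- logical(0)
  }
  removed$sibling_of_included_child <- children$child_id[r4]
  children <- children[!r4, , drop = FALSE]
  children <- children[order(children$child_id), , drop = FALSE]
  rownames(children) <- NULL

  log <- structure(
    list(
      counts = vapply(removed, length, 0L),
      ids = removed,
      n_included = nrow(children),
      suppressed_condition_category = character(0),
      suppressed_children = character(0)
    ),
    class = "exclusion_log"
  )
  list(included = children, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("exclusions applied (in order):\n")
  for (rule in names(x$counts)) {
    cat(sprintf("  %-26s %d\n", rule, x$counts[[rule]]))
  }
  cat(sprintf("  included: %d\n", x$n_included))
  if (length(x$suppressed_condition_category) > 0) {
    cat("  suppressed condition categories:",
        paste(x$suppressed_condition_category, collapse = ", "),
        sprintf("(%d children)\n", length(x$suppressed_children)))
  }
  invisible(x)
}

#' Restrict events to included children and the age window
#'
#' Keeps exactly the events whose completed-month age lies in the
#' inclusive configured window for that child; events of excluded children
#' and events flagged as pre-birth are dropped.
#'
#' @param events Events data frame (with `pre_birth` flag if present).
#' @param children Included children (output of [apply_exclusions()]).
#' @param config An [ascertainment_config()].
#' @return Events data frame with an added integer `age_months` column.
#' @export
window_events <- function(events, children, config = ascertainment_config()) {
  keep <- events$child_id %in% children$child_id
  if (!is.null(events$pre_birth)) keep <- keep & !events$pre_birth
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0) {
    events$age_months <- integer(0)
    rownames(events) <- NULL
    return(events)
  }
  bm <- children$birth_month[match(events$child_id, children$child_id)]
  anchor <- first_of_birth_month(bm)
  pre <- as.Date(events$event_date) < anchor
  events <- events[!pre, , drop = FALSE]
  events$age_months <- age_in_months(
    bm[!pre], events$event_date)
  in_win <- events$age_months >= config$window_months[1] &
    events$age_months <= config$window_months[2]
  events <- events[in_win, , drop = FALSE]
  rownames(events) <- NULL
  events
}

# per-event category memberships under the cross-part precedence rule
resolve_event_categories <- function(events, cls, config) {
  lut <- codelist_lookup(cls)
  if (config$cross_part_precedence != "both") {
    dual <- intersect(lut$code[lut$part == "probable"],
                      lut$code[lut$part == "potential"])
    drop_part <- if (config$cross_part_precedence == "probable_wins")
      "potential" else "probable"
    lut <- lut[!(lut$code %in% dual & lut$part == drop_part), , drop = FALSE]
  }
  hits <- merge(events, lut, by = "code")
  hits[order(hits$child_id, hits$event_date, hits$code), , drop = FALSE]
}

#' Classify each included child from windowed events
#'
#' Every included child receives exactly one row. A child is `probable`
#' if any windowed event carries a condition-list code (under the
#' configured cross-part precedence), `potential_only` if they have
#' indicator-list codes but no condition codes, else `neither`.
#' `first_condition_age` is the minimum completed-month age over condition
#' events; `first_any_age` the minimum over all in-list events;
#' `indicator_before_condition` is `TRUE` only when some indicator event
#' date is strictly earlier than every condition event date (same-day
#' records do not count as "before").
#'
#' @param events Windowed events (output of [window_events()]).
#' @param children Included children.
#' @param cls A `codelist_set`.
#' @param config An [ascertainment_config()].
#' @return Data frame, one row per included child: `child_id`, `group`,
#'   comma-collapsed `probable_categories` / `potential_categories`,
#'   `first_condition_age`, `first_any_age`, `indicator_before_condition`,
#'   `n_condition_code_records`, `n_indicator_code_records`,
#'   `distinct_indicator_count`.
#' @export
classify_children <- function(events, children, cls,
                              config = ascertainment_config()) {
  ids <- children$child_id
  f <- function(x) factor(x, levels = ids)
  hits <- resolve_event_categories(events, cls, config)
  cond <- hits[hits$part == "probable", , drop = FALSE]
  ind <- hits[hits$part == "potential", , drop = FALSE]

  collapse_cats <- function(df, order_ref) {
    out <- tapply(df$category, f(df$child_id), function(x) {
      paste(intersect(order_ref, unique(x)), collapse = ",")
    })
    out <- as.character(out)
    out[is.na(out)] <- ""
    out
  }
  min_by <- function(values, id) {
    out <- tapply(values, f(id), min)
    as.numeric(out)
  }

  # distinct events: several category memberships of one record collapse
  cond_rec <- unique(cond[, c("child_id", "code", "event_date")])
  ind_rec <- unique(ind[, c("child_id", "code", "event_date")])

  probable_categories <- collapse_cats(cond, DD_PROBABLE_CATEGORIES)
  potential_categories <- collapse_cats(ind, DD_POTENTIAL_CATEGORIES)
  first_condition_age <- min_by(cond$age_months, cond$child_id)
  first_any_age <- min_by(hits$age_months, hits$child_id)
  min_cond_date <- min_by(as.numeric(as.Date(cond$event_date)), cond$child_id)
  min_ind_date <- min_by(as.numeric(as.Date(ind$event_date)), ind$child_id)

  n_cond <- as.integer(table(f(cond_rec$child_id)))
  n_ind <- as.integer(table(f(ind_rec$child_id)))
  distinct_ind <- as.integer(tapply(ind_rec$code, f(ind_rec$child_id),
                                    function(x) length(unique(x))))
  distinct_ind[is.na(distinct_ind)] <- 0L

  group <- ifelse(probable_categories != "", "probable",
                  ifelse(potential_categories != "", "potential_only",
                         "neither"))
  indicator_before_condition <- ifelse(
    group != "probable", NA,
    !is.na(min_ind_date) & min_ind_date < min_cond_date)

  data.frame(
    child_id = ids,
    group = group,
    probable_categories = probable_categories,
    potential_categories = potential_categories,
    first_condition_age = first_condition_age,
    first_any_age = first_any_age,
    indicator_before_condition = indicator_before_condition,
    n_condition_code_records = n_cond,
    n_indicator_code_records = n_ind,
    distinct_indicator_count = distinct_ind,
    stringsAsFactors = FALSE
  )
}

has_category <- function(classifications, column, category) {
  vapply(strsplit(classifications[[column]], ",", fixed = TRUE),
         function(x) category %in% x, logical(1))
}

age_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                min = NA_real_, max = NA_real_))
  }
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       min = min(x), max = max(x))
}

#' Summarise classification groups
#'
#' Aggregates per-child classifications into the counts the analysis
#' reports: group sizes, per-category compositions, diagnostic-deferral
#' proportions, age-at-diagnosis summaries, multi-indicator counts and
#' (when windowed events and the code lists are supplied) distinct-code
#' usage and repeat-coding statistics.
#'
#' @param classifications Output of [classify_children()].
#' @param config An [ascertainment_config()].
#' @param events Optional windowed events, for code-usage statistics.
#' @param cls Optional `codelist_set`, required with `events`.
#' @return A `group_summary` list.
#' @export
summarize_groups <- function(classifications,
                             config = ascertainment_config(),
                             events = NULL, cls = NULL) {
  cl <- classifications
  grp <- cl$group
  n_total <- nrow(cl)
  n_probable <- sum(grp == "probable")
  n_potential_only <- sum(grp == "potential_only")
  n_neither <- sum(grp == "neither")
  n_suppressed <- sum(grp == "suppressed")
  n_ascertained <- n_probable + n_potential_only

  per_condition <- vapply(DD_PROBABLE_CATEGORIES, function(cat) {
    sum(grp == "probable" & has_category(cl, "probable_categories", cat))
  }, 0L)
  per_indicator_potential_only <- vapply(DD_POTENTIAL_CATEGORIES, function(cat) {
    sum(grp == "potential_only" &
          has_category(cl, "potential_categories", cat))
  }, 0L)

  is_prob <- grp == "probable"
  n_both <- sum(is_prob & cl$n_indicator_code_records > 0)
  n_any_indicator <- sum(grp %in% c("probable", "potential_only") &
                           cl$n_indicator_code_records > 0)
  n_multi_indicator <- sum(grp == "potential_only" &
                             cl$n_indicator_code_records > 1)

  deferral <- lapply(DD_PROBABLE_CATEGORIES, function(cat) {
    in_cat <- is_prob & has_category(cl, "probable_categories", cat)
    n <- sum(in_cat)
    d <- sum(in_cat & cl$indicator_before_condition %in% TRUE)
    list(n = n, deferred = d,
         pct = if (n > 0) 100 * d / n else NA_real_)
  })
  names(deferral) <- DD_PROBABLE_CATEGORIES
  deferral$total <- list(
    n = n_probable,
    deferred = sum(is_prob & cl$indicator_before_condition %in% TRUE),
    pct = if (n_probable > 0)
      100 * sum(is_prob & cl$indicator_before_condition %in% TRUE) /
        n_probable else NA_real_
  )

  ages <- lapply(DD_PROBABLE_CATEGORIES, function(cat) {
    in_cat <- is_prob & has_category(cl, "probable_categories", cat)
    list(condition = age_summary(cl$first_condition_age[in_cat]),
         first_any = age_summary(cl$first_any_age[in_cat]))
  })
  names(ages) <- DD_PROBABLE_CATEGORIES
  ages$total <- list(
    condition = age_summary(cl$first_condition_age[is_prob]),
    first_any = age_summary(cl$first_any_age[is_prob])
  )
  ages$potential_only <- list(
    first_any = age_summary(cl$first_any_age[grp == "potential_only"])
  )

  code_usage <- NULL
  if (!is.null(events) && !is.null(cls)) {
    hits <- resolve_event_categories(events, cls, config)
    hits$grp <- grp[match(hits$child_id, cl$child_id)]
    crec <- unique(hits[hits$part == "probable" & hits$grp == "probable",
                        c("child_id", "code", "event_date")])
    irec_p <- unique(hits[hits$part == "potential" & hits$grp == "probable",
                          c("child_id", "code", "event_date")])
    irec_o <- unique(hits[hits$part == "potential" &
                            hits$grp == "potential_only",
                          c("child_id", "code", "event_date")])
    rec_per_child <- table(crec$child_id)
    repeaters <- names(rec_per_child)[rec_per_child > 1]
    same_date <- vapply(repeaters, function(id) {
      anyDuplicated(crec$event_date[crec$child_id == id]) > 0
    }, logical(1))
    code_usage <- list(
      condition_codes_used = length(unique(crec$code)),
      condition_records = nrow(crec),
      indicator_codes_in_probable = length(unique(irec_p$code)),
      indicator_records_in_probable = nrow(irec_p),
      indicator_codes_in_potential_only = length(unique(irec_o$code)),
      indicator_records_in_potential_only = nrow(irec_o),
      n_repeat_condition_children = length(repeaters),
      n_repeat_same_date = sum(same_date),
      n_repeat_different_date = sum(!same_date),
      indicator_code_frequencies = if (nrow(irec_o) > 0) {
        freq <- as.data.frame(table(
          category = hits$category[hits$part == "potential" &
                                     hits$grp == "potential_only"],
          code = hits$code[hits$part == "potential" &
                             hits$grp == "potential_only"]),
          stringsAsFactors = FALSE)
        freq <- freq[freq$Freq > 0, , drop = FALSE]
        names(freq)[3] <- "n_records"
        freq[order(freq$category, -freq$n_records, freq$code), ,
             drop = FALSE]
      } else NULL
    )
  }

  structure(
    list(
      n_total = n_total,
      n_probable = n_probable,
      n_potential_only = n_potential_only,
      n_neither = n_neither,
      n_suppressed = n_suppressed,
      n_ascertained = n_ascertained,
      pct_ascertained = if (n_total > 0) 100 * n_ascertained / n_total
        else NA_real_,
      n_both = n_both,
      pct_both_of_probable = if (n_probable > 0) 100 * n_both / n_probable
        else NA_real_,
      n_any_indicator = n_any_indicator,
      n_multi_indicator = n_multi_indicator,
      pct_multi_indicator = if (n_potential_only > 0)
        100 * n_multi_indicator / n_potential_only else NA_real_,
      per_condition = per_condition,
      per_indicator_potential_only = per_indicator_potential_only,
      deferral = deferral,
      ages = ages,
      code_usage = code_usage,
      suppressed_categories = character(0)
    ),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("cohort N = %d; ascertained %d (%.1f%%)\n",
              x$n_total, x$n_ascertained, x$pct_ascertained))
  cat(sprintf("  probable %d | potential-only %d | neither %d",
              x$n_probable, x$n_potential_only, x$n_neither))
  if (x$n_suppressed > 0) cat(sprintf(" | suppressed %d", x$n_suppressed))
  cat("\n  per condition: ",
      paste(sprintf("%s=%d", names(x$per_condition), x$per_condition),
            collapse = ", "), "\n", sep = "")
  if (length(x$suppressed_categories) > 0) {
    cat("  suppressed categories:",
        paste(x$suppressed_categories, collapse = ", "), "\n")
  }
  cat(sprintf("  probable with >=1 indicator: %d (%.1f%% of probable)\n",
              x$n_both, x$pct_both_of_probable))
  cat(sprintf("  potential-only with >1 indicator: %d (%.1f%%)\n",
              x$n_multi_indicator, x$pct_multi_indicator))
  invisible(x)
}

#' Apply small-cell disclosure suppression
#'
#' Any condition category with more than zero but fewer than
#' `config$suppression_threshold` children has those children removed from
#' the study (their classification row becomes group `"suppressed"`), and
#' the category is reported as suppressed. The denominator is left at the
#' included-cohort size unless `config$suppress_denominator` is set. A
#' category with zero children is reported as 0 and nothing is removed.
#'
#' @param summary A `group_summary` (pre-suppression).
#' @param classifications Output of [classify_children()].
#' @param config An [ascertainment_config()].
#' @param events,cls Optional, passed through to re-summarise code usage.
#' @param log Optional `exclusion_log` to record the suppression in.
#' @return List with updated `summary`, `classifications` and `log`.
#' @export
apply_suppression <- function(summary, classifications,
                              config = ascertainment_config(),
                              events = NULL, cls = NULL, log = NULL) {
  thr <- config$suppression_threshold
  small <- names(summary$per_condition)[
    summary$per_condition > 0 & summary$per_condition < thr]
  cl <- classifications
  suppressed_ids <- character(0)
  if (length(small) > 0) {
    for (cat in small) {
      in_cat <- cl$group == "probable" &
        has_category(cl, "probable_categories", cat)
      # drop the category; children left with no retained condition leave
      # the study entirely
      cl$probable_categories[in_cat] <- vapply(
        strsplit(cl$probable_categories[in_cat], ",", fixed = TRUE),
        function(x) paste(setdiff(x, cat), collapse = ","), character(1))
      gone <- in_cat & cl$probable_categories == ""
      suppressed_ids <- c(suppressed_ids, cl$child_id[gone])
      cl$group[gone] <- "suppressed"
    }
  }
  new_summary <- summarize_groups(cl, config, events = events, cls = cls)
  if (config$suppress_denominator) {
    new_summary$n_total <- new_summary$n_total - length(suppressed_ids)
  }
  new_summary$suppressed_categories <- small
  new_summary$per_condition[small] <- NA_integer_
  if (!is.null(log)) {
    log$suppressed_condition_category <- small
    log$suppressed_children <- suppressed_ids
  }
  list(summary = new_summary, classifications = cl, log = log)
}

#' Run the full ascertainment pipeline
#'
#' Chains [apply_exclusions()], [window_events()], [classify_children()],
#' [summarize_groups()] and [apply_suppression()].
#'
#' @param children,maternal,events Cohort tables (see [read_cohort()]).
#' @param cls A `codelist_set` (defaults to the packaged lists).
#' @param config An [ascertainment_config()].
#' @return A `dd_run` list: `included`, `windowed_events`,
#'   `classifications`, `summary`, `presuppression_summary`,
#'   `exclusion_log`, plus the inputs needed downstream (`maternal`,
#'   `config`, `cls`).
#' @export
run_ascertainment <- function(children, maternal, events,
                              cls = load_codelists(),
                              config = ascertainment_config()) {
  excl <- apply_exclusions(children, config)
  win <- window_events(events, excl$included, config)
  cl <- classify_children(win, excl$included, cls, config)
  pre <- summarize_groups(cl, config, events = win, cls = cls)
  sup <- apply_suppression(pre, cl, config, events = win, cls = cls,
                           log = excl$log)
  structure(
    list(
      included = excl$included,
      windowed_events = win,
      classifications = sup$classifications,
      summary = sup$summary,
      presuppression_summary = pre,
      exclusion_log = sup$log,
      maternal = maternal,
      config = config,
      cls = cls
    ),
    class = "dd_run"
  )
}
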