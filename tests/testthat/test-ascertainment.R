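mk_children <- function(ids, mothers = sprintf("M%s", ids),
                        birth = "2008-03") {
  n <- length(ids)
  data.frame(child_id = ids, mother_id = mothers,
             birth_month = rep_len(birth, n),
             sex = rep_len("female", n), withdrawn = rep_len(FALSE, n),
             died = rep_len(FALSE, n),
             has_primary_care_link = rep_len(TRUE, n),
             has_maternal_baseline = rep_len(TRUE, n),
             stringsAsFactors = FALSE)
}
mk_events <- function(ids, codes, dates) {
  data.frame(child_id = ids, code = codes, event_date = as.Date(dates),
             stringsAsFactors = FALSE)
}

test_that("one child per mother keeps the earliest birth", {
  ch <- mk_children(c("A", "B"), mothers = c("M1", "M1"))
  ch$birth_month <- c("2008-01", "2010-02")
  res <- apply_exclusions(ch)
  expect_equal(res$included$child_id, "A")
  expect_equal(unname(res$log$counts["sibling_of_included_child"]), 1L)
  # twins (same birth month) resolve by lexicographic child id
  ch$birth_month <- c("2009-06", "2009-06")
  expect_equal(apply_exclusions(ch)$included$child_id, "A")
})

test_that("exclusion rules are applied in order and account for everyone", {
  ch <- mk_children(c("A", "B", "C", "D", "E"))
  ch$withdrawn[1] <- TRUE
  ch$has_primary_care_link[2] <- FALSE
  ch$has_maternal_baseline[3] <- FALSE
  # a withdrawn child without a care link counts only under withdrawn
  ch$has_primary_care_link[1] <- FALSE
  res <- apply_exclusions(ch)
  expect_equal(unname(res$log$counts),
               c(1L, 1L, 1L, 0L))
  expect_equal(res$included$child_id, c("D", "E"))
  expect_equal(sum(res$log$counts) + nrow(res$included), nrow(ch))

  empty <- apply_exclusions(mk_children(character(0)))
  expect_equal(nrow(empty$included), 0L)
  expect_true(all(empty$log$counts == 0L))
})

test_that("the age window is inclusive of month 60 and drops pre-birth", {
  ch <- mk_children("A")
  ev <- mk_events(rep("A", 4), rep("X00TM", 4),
                  c("2013-03-05",   # 60 months: in
                    "2013-04-01",   # 61 months: out
                    "2008-02-20",   # pre-birth: out
                    "2010-01-01"))  # 22 months: in
  win <- window_events(ev, ch)
  expect_equal(sort(win$age_months), c(22L, 60L))
  # with a [0, 0] window only birth-month events can classify anyone
  win0 <- window_events(ev, ch, ascertainment_config(window_months = c(0, 0)))
  expect_equal(nrow(win0), 0L)
  ev0 <- mk_events("A", "X00TM", "2008-03-20")
  expect_equal(window_events(ev0, ch,
                             ascertainment_config(window_months = c(0, 0)))$age_months,
               0L)
})

test_that("classification matches the published single-child patterns", {
  cls <- load_codelists()
  ch <- mk_children(c("A", "B", "C", "D"))
  ev <- rbind(
    mk_events("A", "E140.", "2012-05-10"),               # ASD at 50 months
    mk_events(c("B", "B"), c("XaX18", "X00TM"),
              c("2009-11-02", "2012-04-15")),            # indicator then ASD
    mk_events("D", "Xa40J", "2010-09-07")                # dev delay at 30
  )
  win <- window_events(ev, ch)
  cl <- classify_children(win, ch, cls)
  a <- cl[cl$child_id == "A", ]
  expect_equal(a$group, "probable")
  expect_equal(a$probable_categories, "asd")
  expect_false(a$indicator_before_condition)
  expect_equal(a$first_condition_age, 50)

  b <- cl[cl$child_id == "B", ]
  expect_equal(b$group, "probable")
  expect_true(b$indicator_before_condition)
  expect_equal(b$first_any_age, 20)
  expect_equal(b$first_condition_age, 49)

  expect_equal(cl$group[cl$child_id == "C"], "neither")
  d <- cl[cl$child_id == "D", ]
  expect_equal(d$group, "potential_only")
  expect_equal(d$potential_categories, "dev_delay")
})

test_that("a same-date indicator does not count as before the condition", {
  cls <- load_codelists()
  ch <- mk_children("A")
  ev <- mk_events(c("A", "A"), c("Xa40J", "X00TM"),
                  c("2011-01-10", "2011-01-10"))
  cl <- classify_children(window_events(ev, ch), ch, cls)
  expect_equal(cl$group, "probable")
  expect_false(cl$indicator_before_condition)
})

test_that("cross-part codes follow the configured precedence", {
  cls <- load_codelists()
  ch <- mk_children("A")
  ev <- mk_events("A", "Xa3HI", "2010-06-15")
  win <- window_events(ev, ch)

  cl <- classify_children(win, ch, cls,
                          ascertainment_config(cross_part_precedence = "probable_wins"))
  expect_equal(cl$group, "probable")
  expect_equal(cl$probable_categories, "mod_severe_ld")
  expect_equal(cl$potential_categories, "")

  cl <- classify_children(win, ch, cls,
                          ascertainment_config(cross_part_precedence = "potential_wins"))
  expect_equal(cl$group, "potential_only")
  expect_equal(cl$potential_categories, "gen_disabilities")

  cl <- classify_children(win, ch, cls,
                          ascertainment_config(cross_part_precedence = "both"))
  expect_equal(cl$group, "probable")
  expect_equal(cl$probable_categories, "mod_severe_ld")
  expect_equal(cl$potential_categories, "gen_disabilities")
})

test_that("classification equals the brute-force set-intersection oracle", {
  cls <- load_codelists()
  for (seed in c(101, 202, 303, 404)) {
    for (prec in c("probable_wins", "potential_wins", "both")) {
      cfg <- ascertainment_config(cross_part_precedence = prec)
      rc <- random_small_cohort(seed, cls, n_children = 30)
      win <- window_events(rc$events, rc$children, cfg)
      got <- classify_children(win, rc$children, cls, cfg)
      want <- oracle_classify(rc$children, rc$events, cls, cfg)
      ord <- order(got$child_id)
      for (col in names(want)) {
        expect_equal(got[[col]][ord], want[[col]][order(want$child_id)],
                     info = paste("seed", seed, prec, col))
      }
    }
  }
})

test_that("group counts are conserved and re-classification is stable", {
  cls <- load_codelists()
  for (seed in c(5, 6)) {
    g <- generate_cohort(generator_config(seed = seed, n_children = 1500),
                         cls)
    run <- run_ascertainment(g$children, g$maternal, g$events, cls)
    s <- run$summary
    expect_equal(s$n_probable + s$n_potential_only + s$n_neither +
                   s$n_suppressed, s$n_total)
    expect_true(s$n_both <= s$n_probable)
    expect_true(all(run$classifications$distinct_indicator_count <=
                      run$classifications$n_indicator_code_records))
    both <- !is.na(run$classifications$first_condition_age) &
      !is.na(run$classifications$first_any_age)
    expect_true(all(run$classifications$first_any_age[both] <=
                      run$classifications$first_condition_age[both]))
    # re-running classification on the already-windowed events changes
    # nothing
    again <- classify_children(run$windowed_events, run$included, cls,
                               run$config)
    pre <- classify_children(run$windowed_events, run$included, cls,
                             run$config)
    expect_identical(again, pre)
  }
})

test_that("small condition cells are suppressed but the denominator is kept", {
  cls <- load_codelists()
  ch <- mk_children(sprintf("A%02d", 1:20))
  # 3 fragile X, 5 Down, 12 clean
  ev <- rbind(
    mk_events(sprintf("A%02d", 1:3), "X78FB", "2010-01-15"),
    mk_events(sprintf("A%02d", 4:8), "PJ00.", "2010-01-15")
  )
  run <- run_ascertainment(ch, NULL, ev, cls)
  expect_equal(run$summary$suppressed_categories, "fragile_x")
  expect_true(is.na(run$summary$per_condition[["fragile_x"]]))
  expect_equal(run$summary$n_suppressed, 3L)
  expect_equal(run$summary$n_probable, 5L)       # the Down five survive
  expect_equal(run$summary$per_condition[["down_syndrome"]], 5L)
  expect_equal(run$summary$n_total, 20L)         # denominator unchanged
  expect_equal(run$summary$per_condition[["asd"]], 0L)  # zero reported as 0
  expect_false("asd" %in% run$summary$suppressed_categories)
  # removed children really leave the probable listings
  expect_equal(sum(run$classifications$group == "probable"), 5L)
})
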