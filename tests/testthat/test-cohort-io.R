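test_that("anonymised age arithmetic floors completed calendar months", {
  expect_equal(age_in_months("2008-03", as.Date("2008-03-15")), 0L)
  expect_equal(age_in_months("2008-03", as.Date("2013-03-01")), 60L)
  expect_equal(age_in_months("2008-03", as.Date("2008-06-20")), 3L)
  # end-of-month day never rounds up: the anchor is the 1st
  expect_equal(age_in_months("2008-03", as.Date("2008-04-30")), 1L)
  expect_error(age_in_months("2008-03", as.Date("2008-02-28")), "precedes")
  expect_error(age_in_months("2008-3", as.Date("2008-04-01")), "birth_month")
})

test_that("age is monotone non-decreasing in event date", {
  dates <- sort(as.Date("2007-06-01") + sample.int(2200, 200))
  ages <- age_in_months("2007-06", dates)
  expect_true(all(diff(ages) >= 0))
  expect_true(all(ages == as.integer(ages)))
})

test_that("cohort write/read round-trips field-for-field", {
  cls <- load_codelists()
  g <- generate_cohort(generator_config(seed = 11, n_children = 400), cls)
  dir <- withr::local_tempdir()
  write_cohort(g, dir)
  back <- read_cohort(file.path(dir, "children.csv"),
                      file.path(dir, "maternal.csv"),
                      file.path(dir, "events.csv"))
  expect_equal(back$children, g$children)
  expect_equal(back$maternal, g$maternal)
  expect_equal(back$events[, c("child_id", "code", "event_date")], g$events)
  # and a second write of the reread cohort is byte-identical
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  for (f in c("children.csv", "maternal.csv", "events.csv")) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
  }
})

test_that("row counts after reading equal the generator manifest", {
  g <- generate_cohort(generator_config(seed = 3, n_children = 300))
  dir <- withr::local_tempdir()
  write_cohort(g, dir)
  back <- read_cohort(file.path(dir, "children.csv"),
                      file.path(dir, "maternal.csv"),
                      file.path(dir, "events.csv"))
  expect_equal(back$report$n_children, g$manifest$n_children)
  expect_equal(back$report$n_maternal, g$manifest$n_maternal)
  expect_equal(back$report$n_events, g$manifest$n_events)
})

write_mini_cohort <- function(dir, events_lines) {
  writeLines(c(
    "child_id,mother_id,birth_month,sex,withdrawn,died,has_primary_care_link,has_maternal_baseline",
    "A1,MA1,2008-03,female,0,0,1,1"), file.path(dir, "children.csv"))
  writeLines(c(
    "mother_id,ethnicity,education,age_at_birth,parity,cohabiting,subjective_finance,imd_quintile",
    "MA1,pakistani,higher,28,first_child,yes,doing_alright,4"),
    file.path(dir, "maternal.csv"))
  writeLines(c("child_id,code,event_date", events_lines),
             file.path(dir, "events.csv"))
  read_cohort(file.path(dir, "children.csv"), file.path(dir, "maternal.csv"),
              file.path(dir, "events.csv"))
}

test_that("header-only files load as empty tables", {
  dir <- withr::local_tempdir()
  writeLines("child_id,mother_id,birth_month,sex,withdrawn,died,has_primary_care_link,has_maternal_baseline",
             file.path(dir, "children.csv"))
  writeLines("mother_id,ethnicity,education,age_at_birth,parity,cohabiting,subjective_finance,imd_quintile",
             file.path(dir, "maternal.csv"))
  writeLines("child_id,code,event_date", file.path(dir, "events.csv"))
  cohort <- read_cohort(file.path(dir, "children.csv"),
                        file.path(dir, "maternal.csv"),
                        file.path(dir, "events.csv"))
  expect_equal(nrow(cohort$children), 0L)
  expect_equal(nrow(cohort$maternal), 0L)
  expect_equal(nrow(cohort$events), 0L)
})

test_that("orphan and pre-birth events are reported, not dropped", {
  dir <- withr::local_tempdir()
  cohort <- write_mini_cohort(dir, c("A1,X00TM,2012-05-02",
                                     "GHOST,X00TM,2012-05-02",
                                     "A1,PJ00.,2008-01-15"))
  expect_equal(nrow(cohort$events), 3L)
  expect_equal(cohort$report$orphan_events, "GHOST")
  expect_equal(cohort$report$n_pre_birth_events, 1L)
  expect_true(cohort$events$pre_birth[cohort$events$event_date ==
                                        as.Date("2008-01-15")])
})

test_that("schema and parse errors name the file, column or row", {
  dir <- withr::local_tempdir()
  expect_error(write_mini_cohort(dir, "A1,X00TM,not-a-date"),
               "row 1")
  writeLines(c("child_id,code", "A1,X00TM"), file.path(dir, "events.csv"))
  expect_error(
    read_cohort(file.path(dir, "children.csv"),
                file.path(dir, "maternal.csv"),
                file.path(dir, "events.csv")),
    "event_date")
})
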