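test_that("the generator is deterministic given config and seed", {
  cfg <- generator_config(seed = 17, n_children = 600)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$children, g2$children)
  expect_identical(g1$maternal, g2$maternal)
  expect_identical(g1$events, g2$events)
  g3 <- generate_cohort(generator_config(seed = 18, n_children = 600))
  expect_false(identical(g1$events, g3$events))

  # written outputs are byte-identical too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in c("children.csv", "maternal.csv", "events.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(generator_config(seed = 5, n_children = 50)))
  expect_identical(.Random.seed, before)
})

test_that("zero prevalence yields an all-neither cohort", {
  cfg <- generator_config(
    seed = 2, n_children = 500,
    condition_prevalence = c(cerebral_palsy = 0, down_syndrome = 0,
                             fragile_x = 0, asd = 0, mod_severe_ld = 0),
    indicator_only_prevalence = 0)
  g <- generate_cohort(cfg)
  run <- run_ascertainment(g$children, g$maternal, g$events)
  expect_equal(run$summary$n_ascertained, 0L)
  expect_equal(run$summary$n_neither, run$summary$n_total)
})

test_that("generator output always passes cohort validation", {
  for (seed in c(4, 9)) {
    g <- generate_cohort(generator_config(seed = seed, n_children = 800))
    dir <- withr::local_tempdir()
    write_cohort(g, dir)
    back <- read_cohort(file.path(dir, "children.csv"),
                        file.path(dir, "maternal.csv"),
                        file.path(dir, "events.csv"))
    expect_equal(back$report$n_orphan_events, 0L)
    expect_equal(back$report$n_pre_birth_events, 0L)
    expect_length(back$report$baseline_flag_without_row, 0L)
    expect_true(all(back$events$event_date >= as.Date("2007-03-01")))
  }
})

test_that("noise codes come from a reserved alphabet and never classify", {
  cls <- load_codelists()
  cfg <- generator_config(
    seed = 8, n_children = 400,
    condition_prevalence = c(cerebral_palsy = 0, down_syndrome = 0,
                             fragile_x = 0, asd = 0, mod_severe_ld = 0),
    indicator_only_prevalence = 0, noise_rate = 0.5)
  g <- generate_cohort(cfg, cls)
  expect_gt(nrow(g$events), 0)
  expect_true(all(startsWith(g$events$code, "Q")))
  expect_false(any(g$events$code %in% unlist(cls$entries)))
  run <- run_ascertainment(g$children, g$maternal, g$events, cls)
  expect_equal(run$summary$n_ascertained, 0L)
})

test_that("realized condition counts are binomial around the configured rate", {
  # mean realized ASD count over seeds within 3 Monte-Carlo standard
  # errors of n * rate (sampling oracle: the binomial mean)
  cls <- load_codelists()
  rate <- 0.005
  n <- 10000
  counts <- vapply(1:40, function(s) {
    cfg <- generator_config(
      seed = 1000 + s, n_children = n,
      condition_prevalence = c(cerebral_palsy = 0, down_syndrome = 0,
                               fragile_x = 0, asd = rate,
                               mod_severe_ld = 0))
    g <- generate_cohort(cfg, cls)
    g$manifest$realized_condition_counts$asd
  }, 0L)
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - n * rate), 3 * mc_se)
})

test_that("pipeline deferral converges to the configured probability", {
  # all cerebral-palsy ages here are >= 1 month, so the deferral
  # proportion should approach the configured probability; the oracle is
  # a direct draw from the same truncated-normal age distribution
  cls <- load_codelists()
  p_def <- 0.4
  cfg <- generator_config(
    seed = 77, n_children = 12000,
    condition_prevalence = c(cerebral_palsy = 0.03, down_syndrome = 0,
                             fragile_x = 0, asd = 0, mod_severe_ld = 0),
    deferral_prob = c(cerebral_palsy = p_def, down_syndrome = 0,
                      fragile_x = 0, asd = 0, mod_severe_ld = 0),
    condition_age = list(
      cerebral_palsy = c(mean = 30, sd = 10, lo = 2, hi = 58),
      down_syndrome = c(mean = 0.3, sd = 0.7, lo = 0, hi = 3),
      fragile_x = c(mean = 32, sd = 23.2, lo = 0, hi = 60),
      asd = c(mean = 48.7, sd = 7.6, lo = 32, hi = 60),
      mod_severe_ld = c(mean = 32, sd = 23.2, lo = 0, hi = 60)),
    later_indicator_prob = 0, indicator_only_prevalence = 0)
  g <- generate_cohort(cfg, cls)
  run <- run_ascertainment(g$children, g$maternal, g$events, cls,
                           ascertainment_config(suppression_threshold = 0))
  d <- run$summary$deferral$cerebral_palsy
  expect_gt(d$n, 150)
  se <- sqrt(p_def * (1 - p_def) / d$n)
  expect_lt(abs(d$deferred / d$n - p_def), 3 * se)
})
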