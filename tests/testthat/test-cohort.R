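test_that("cohort sampling is deterministic and honours n = 0", {
  spec <- cohort_spec(n = 40, seed = 42)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 40)
  expect_equal(a$id, 1:40)

  empty <- sample_cohort(cohort_spec(n = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("malabsorber draws match their Bernoulli rate", {
  spec <- cohort_spec(n = 10000, seed = 5, malabsorber_fraction = 0.3)
  draws <- sample_cohort(spec)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(draws$malabsorber) - 0.3), 3 * se)
  expect_true(all(draws$fructose_completion_h[draws$malabsorber] ==
                    spec$malabsorber_completion_h))
})

test_that("degenerate distributions collapse the cohort to one individual", {
  spec <- cohort_spec(n = 3, seed = 9, fructose_completion_sigma = 0,
                      malabsorber_fraction = 0,
                      drinks_per_day_probs = c(0, 0, 1, 0, 0, 0, 0),
                      duration_days = 5)
  res <- run_cohort(spec)
  expect_equal(nrow(res), 3)
  expect_equal(length(unique(res$mean_map_mmHg)), 1L)

  single <- steady_state_summary(
    simulate_schedule(
      regular_schedule(2, spec$beverage, 5, volume_L = spec$drink_volume_L),
      physiology_params()),
    spec$summary_window_days)
  expect_equal(res$mean_map_mmHg[1], single$mean_map_mmHg)
  expect_equal(res$aldo_exposure_per_day[1], single$aldo_exposure_per_day)
})

test_that("abstainer cohorts are never flagged hypertensive", {
  spec <- cohort_spec(n = 4, seed = 2,
                      drinks_per_day_probs = c(1, 0, 0, 0, 0, 0, 0),
                      duration_days = 4)
  res <- run_cohort(spec)
  expect_false(any(res$hypertensive))
  expect_equal(res$fructose_g_day, rep(0, 4))
  expect_equal(res$mean_map_mmHg, rep(physiology_params()$map0, 4))
})

test_that("dose-response tables bin every individual exactly once", {
  spec <- cohort_spec(n = 12, seed = 17, duration_days = 4)
  res <- run_cohort(spec)
  tab <- dose_response_table(res)
  expect_equal(sum(tab$n), nrow(res))
  expect_true(all(tab$hypertensive_fraction >= 0 &
                    tab$hypertensive_fraction <= 1, na.rm = TRUE))
  one <- dose_response_table(res, breaks = c(0, Inf))
  expect_equal(one$n, nrow(res))
  expect_error(dose_response_table(res, breaks = c(50, 10)), "ascending")
})

test_that("fructose intake derives from the beverage composition", {
  spec <- cohort_spec(n = 6, seed = 3, duration_days = 4)
  res <- run_cohort(spec)
  # 79.2704 g/L fructose in the 800 mosm/L preset, 0.5 L per drink
  expect_equal(res$fructose_g_day, res$drinks_per_day * 0.5 * 79.2704)
  # habitual 2.5 drinks/day exposure of that preset
  expect_equal(2.5 * 0.5 * 79.2704, 99.088)
})

test_that("empty cohorts give empty, well-formed tables", {
  res <- run_cohort(cohort_spec(n = 0, seed = 1))
  expect_equal(nrow(res), 0)
  tab <- dose_response_table(res)
  expect_equal(nrow(tab), 0)
})

test_that("cohort spec validation catches bad distributions", {
  expect_error(cohort_spec(n = -1), "non-negative")
  expect_error(cohort_spec(n = 5, drinks_per_day_probs = rep(-1, 7)),
               "drinks_per_day_probs")
  expect_error(cohort_spec(n = 5, malabsorber_fraction = 1.5),
               "malabsorber_fraction")
  expect_error(cohort_spec(n = 5, fructose_completion_median_h = 1),
               "exceed")
  expect_error(cohort_spec(n = 5, fructose_completion_sigma = -0.1),
               "sigma")
})
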