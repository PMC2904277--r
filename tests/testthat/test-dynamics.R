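params_default <- physiology_params()

test_that("hormone drive is zero without a deficit, monotone with it, and gated by luminal sodium", {
  expect_equal(hormone_drive(0, params_default), list(aldo = 0, adh = 0))
  expect_equal(hormone_drive(-0.3, params_default), list(aldo = 0, adh = 0))

  grid <- seq(0, 2, by = 0.05)
  hd <- hormone_drive(grid, params_default)
  expect_true(all(diff(hd$aldo) >= 0))
  expect_true(all(diff(hd$adh) >= 0))
  # HFCS-sized deficit outranks the sucrose-drink deficit
  expect_gt(hormone_drive(5 / 6, params_default)$aldo,
            hormone_drive(1 / 6, params_default)$aldo)
  # saturation caps the indices
  expect_equal(hormone_drive(100, params_default)$aldo,
               params_default$aldo_saturation)
  # unabsorbed luminal sodium blunts aldosterone, not ADH
  gated <- hormone_drive(5 / 6, params_default, luminal_sodium = 50)
  expect_identical(gated$aldo, 0)
  expect_gt(gated$adh, 0)
})

test_that("colon capacity relaxes first-order toward its hormone-set target", {
  p <- params_default
  # fixed point: no average aldosterone, capacity stays at baseline
  expect_equal(colon_adaptation_step(p$c0, 0, 1, p), p$c0)
  # convergence to c0 + c_gain * a under constant drive
  a <- 0.04
  C <- p$c0
  for (i in 1:200) C <- colon_adaptation_step(C, a, 0.5, p)
  expect_equal(C, p$c0 + p$c_gain * a, tolerance = 1e-9)
  # 63% of the increment is reached after one time constant
  C <- p$c0
  n <- 1000
  for (i in 1:n) C <- colon_adaptation_step(C, a, p$tau_colon / n, p)
  expect_equal((C - p$c0) / (p$c_gain * a), 1 - exp(-1), tolerance = 1e-9)
})

test_that("colon relaxation matches an independent adaptive-step ODE solve", {
  skip_if_not_installed("deSolve")
  p <- params_default
  a <- 0.06
  sol <- deSolve::ode(
    y = c(C = p$c0), times = seq(0, 5, by = 0.25),
    func = function(t, y, parms) list((p$c0 + p$c_gain * a - y) / p$tau_colon),
    parms = NULL)
  C <- p$c0
  mine <- p$c0
  for (t in seq(0.25, 5, by = 0.25)) {
    C <- colon_adaptation_step(C, a, 0.25, p)
    mine <- c(mine, C)
  }
  expect_equal(mine, unname(sol[, "C"]), tolerance = 1e-6)
})

test_that("an empty schedule is a fixed point of the whole loop", {
  traj <- simulate_schedule(ingestion_schedule(list(), 5), params_default)
  d <- traj$data
  expect_lt(max(abs(d$na_mmol - d$na_mmol[1])), 1e-9)
  expect_lt(max(abs(d$colon_capacity_mmol_day - params_default$c0)), 1e-12)
  expect_lt(max(abs(d$map_mmHg - params_default$map0)), 1e-9)
  expect_lt(max(abs(d$ecf_L - params_default$v_ecf0)), 1e-9)
  expect_true(all(d$aldo_index == 0))
})

test_that("water balance closes at every step of an eventful simulation", {
  sched <- regular_schedule(2, hfcs_drink(), 5)
  d <- simulate_schedule(sched, params_default)$data
  lhs <- (d$ecf_L + d$luminal_L) - (d$ecf_L[1] + d$luminal_L[1])
  rhs <- d$intake_cum_L - d$urine_cum_L - d$stool_cum_L
  expect_lt(max(abs(lhs - rhs) / pmax(1, abs(rhs))), 1e-8)
})

test_that("salty-soup schedules raise ADH but leave aldosterone blunted", {
  sched <- regular_schedule(2, preset_beverage("salty_soup"), 2)
  d <- simulate_schedule(sched, params_default)$data
  expect_true(all(d$aldo_index == 0))
  expect_gt(max(d$adh_index), 0)
  expect_equal(max(d$colon_capacity_mmol_day), params_default$c0)
})

test_that("hyperosmolar schedules expand ECF and raise the MAP surrogate", {
  sched <- regular_schedule(3, hfcs_drink(), 10)
  ss <- steady_state_summary(simulate_schedule(sched, params_default))
  expect_gt(ss$mean_map_mmHg, params_default$map0)
  expect_gt(ss$ecf_expansion_pct, 0)
  expect_gt(ss$mean_colon_capacity_mmol_day, params_default$c0)
})

test_that("impaired fructose absorption prolongs aldosterone exposure", {
  sched <- regular_schedule(3, hfcs_drink(), 7)
  normal <- steady_state_summary(
    simulate_schedule(sched, physiology_params(fructose_completion_h = 4)))
  impaired <- steady_state_summary(
    simulate_schedule(sched, physiology_params(fructose_completion_h = 8)))
  expect_gte(impaired$aldo_exposure_per_day, normal$aldo_exposure_per_day)
  expect_gt(impaired$aldo_exposure_per_day, 0)
})

test_that("summaries are invariant to the trailing-window choice once settled", {
  sched <- regular_schedule(3, hfcs_drink(), 14)
  traj <- simulate_schedule(sched, params_default)
  s2 <- steady_state_summary(traj, 2)
  s3 <- steady_state_summary(traj, 3)
  expect_equal(s2$mean_map_mmHg, s3$mean_map_mmHg, tolerance = 1e-3)
  expect_equal(s2$mean_colon_capacity_mmol_day,
               s3$mean_colon_capacity_mmol_day, tolerance = 1e-2)
  expect_error(steady_state_summary(traj, 20), "no longer")
})

test_that("schedules and parameters validate their invariants", {
  expect_error(ingestion_schedule(
    list(list(time_h = 200, beverage = hfcs_drink())), 5), "outside")
  expect_error(ingestion_schedule(list(list(time_h = 1)), 5), "beverage")
  expect_error(regular_schedule(-1, hfcs_drink(), 5), "non-negative")
  expect_error(physiology_params(tau_colon = 0.5), "tau_colon")
  expect_error(physiology_params(window_days = 0), "window_days")
  expect_error(physiology_params(k_renal = -1), ">= 0")
  expect_error(physiology_params(fructose_completion_h = 1),
               "fructose_completion_h")
})

test_that("parameter files round-trip to identical simulations", {
  path <- tempfile(fileext = ".yaml")
  p <- physiology_params(c_gain = 321, tau_colon = 1.5)
  write_physiology_params(p, path)
  p2 <- read_physiology_params(path)
  expect_equal(unclass(p2), unclass(p))
  sched <- regular_schedule(1, hfcs_drink(), 2)
  expect_identical(simulate_schedule(sched, p)$data,
                   simulate_schedule(sched, p2)$data)

  shipped <- read_physiology_params(
    system.file("extdata", "params", "default_params.yaml",
                package = "osmotrap"))
  expect_equal(unclass(shipped), unclass(physiology_params()))
})

test_that("grid-search fit recovers the colon parameters it generated", {
  sched <- regular_schedule(3, hfcs_drink(), 6)
  truth <- physiology_params(c_gain = 500, tau_colon = 2)
  obs <- simulate_schedule(sched, truth)
  fit <- fit_colon_params(obs, sched, physiology_params(),
                          c_gain_grid = c(300, 500, 700),
                          tau_grid = c(1, 2, 3))
  expect_equal(unname(coef(fit)), c(500, 2))
  expect_equal(min(fit$sse), 0)
})

test_that("lactulose schedules drive aldosterone without any sugar", {
  sched <- regular_schedule(2, preset_beverage("lactulose_solution"), 3)
  d <- simulate_schedule(sched, params_default)$data
  expect_gt(max(d$aldo_index), 0)
  expect_gt(max(d$stool_cum_L), 0)
  # conservation still closes with the colon (stool) route open
  lhs <- (d$ecf_L + d$luminal_L) - (d$ecf_L[1] + d$luminal_L[1])
  rhs <- d$intake_cum_L - d$urine_cum_L - d$stool_cum_L
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})
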