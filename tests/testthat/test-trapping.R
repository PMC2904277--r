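test_that("trapped volume follows V*O/O_iso - V with clamping", {
  expect_equal(trapped_volume(0.5, 800), 5 / 6)
  expect_equal(trapped_volume(0.5, 400), 1 / 6)
  expect_identical(trapped_volume(0.5, 300), 0)
  expect_identical(trapped_volume(0.5, 245), 0)
  expect_error(trapped_volume(0, 400), "positive")
  expect_error(trapped_volume(0.5, -5), ">= 0")
})

test_that("trapped volume is strictly increasing above the isotonic reference", {
  O <- seq(300, 1200, by = 50)
  vd <- trapped_volume(0.5, O)
  expect_true(all(diff(vd[O >= 300]) > 0 | O[-length(O)] < 300))
  expect_true(all(trapped_volume(0.5, seq(0, 300, by = 25)) == 0))
  V <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(trapped_volume(V, 500)) > 0))
})

test_that("total absorbable volume is the exact sum V + V_d", {
  expect_equal(total_absorbable_volume(0.5, 5 / 6), 4 / 3)
  expect_equal(total_absorbable_volume(0.5, 0), 0.5)
  expect_error(total_absorbable_volume(0.5, -0.1), "V_d")
})

test_that("osmolar-share partition matches the reference beverages", {
  hf <- osmotic_trapping(hfcs_drink(), volume = 0.5)
  p <- hf$partitions
  expect_equal(p$volume[p$class == "fast"], 4 / 3 * 0.45)
  expect_equal(p$volume[p$class == "slow"], 4 / 3 * 0.55)
  expect_equal(hf$fraction_fast, 0.45)

  su <- osmotic_trapping(preset_beverage("sucrose_softdrink"), volume = 0.5)
  expect_equal(su$partitions$volume[1:2], c(1 / 3, 1 / 3))

  soup <- osmotic_trapping(preset_beverage("salty_soup"), volume = 0.5)
  expect_equal(soup$partitions$volume[soup$partitions$class == "fast"], 2 / 3)
  expect_equal(soup$partitions$volume[soup$partitions$class == "slow"], 0)

  expect_error(partition_by_osmotic_share(beverage("w", 0.5), 0.5),
               "partition undefined")
})

test_that("partition shares sum to one and ignore beverage volume", {
  for (bev in list(hfcs_drink(), preset_beverage("who_ors"),
                   preset_beverage("lactulose_solution"))) {
    p1 <- partition_by_osmotic_share(bev, 1)
    expect_equal(sum(p1$share), 1)
    p2 <- partition_by_osmotic_share(bev, 3.7)
    expect_equal(p2$share, p1$share)
    expect_equal(p2$volume, 3.7 * p1$share)
  }
})

test_that("absorption timecourse conserves water and empties by completion", {
  for (bev in list(hfcs_drink(), preset_beverage("sucrose_softdrink"),
                   preset_beverage("salty_soup"))) {
    tr <- osmotic_trapping(bev, volume = 0.5)
    t <- seq(0, 6, by = 0.1)
    tc <- absorption_timecourse(tr, t)
    expect_equal(tc$absorbed_L + tc$luminal_L + tc$to_colon_L,
                 rep(tr$V_a, length(t)))
    expect_equal(tc$absorbed_L[t == 0], 0)
    expect_equal(tc$luminal_L[t >= 4], rep(0, sum(t >= 4)))
    expect_true(all(diff(tc$absorbed_L) >= 0))
  }
})

test_that("closed-form timecourse agrees with a 1-second discrete simulation", {
  for (bev in list(hfcs_drink(), preset_beverage("sucrose_softdrink"))) {
    tr <- osmotic_trapping(bev, volume = 0.5)
    t <- c(0.5, 1.7, 2, 2.9, 3.999, 4.5)
    step_vol <- max(tr$partitions$volume[1:2] / 2) / 3600
    expect_lt(max(abs(absorption_timecourse(tr, t)$absorbed_L -
                        brute_absorbed(tr, t))), step_vol + 1e-12)
  }
})

test_that("circulatory balance runs from -V_d to +V", {
  tr <- osmotic_trapping(hfcs_drink(), volume = 0.5)
  expect_equal(circulatory_balance(tr, 0), -tr$V_d)
  expect_equal(circulatory_balance(tr, 0), -5 / 6)
  expect_equal(circulatory_balance(tr, c(4, 5, 10)), rep(0.5, 3))

  ors <- osmotic_trapping(preset_beverage("who_ors"), volume = 0.5)
  cb <- circulatory_balance(ors, seq(0, 5, by = 0.05))
  expect_true(all(cb >= 0))
  expect_true(all(diff(cb) >= 0))
  expect_equal(cb[length(cb)], 0.5)
})

test_that("pre-dilution to isotonicity removes trapping entirely", {
  for (bev in list(hfcs_drink(), preset_beverage("sucrose_softdrink"),
                   sugar_drink(120))) {
    tr <- osmotic_trapping(dilute_to_osmolarity(bev, 300))
    expect_identical(tr$V_d, 0)
    expect_true(all(circulatory_balance(tr, seq(0, 6, by = 0.1)) >= 0))
  }
})

test_that("a longer fructose completion slows only the slow share", {
  tr8 <- osmotic_trapping(hfcs_drink(), volume = 0.5, slow_completion = 8)
  expect_equal(absorption_timecourse(tr8, 2)$absorbed_L, 0.6)
  expect_equal(absorption_timecourse(tr8, 8)$absorbed_L, 4 / 3)
  expect_gt(absorption_timecourse(osmotic_trapping(hfcs_drink(), volume = 0.5), 3)$absorbed_L,
            absorption_timecourse(tr8, 3)$absorbed_L)
  expect_error(osmotic_trapping(hfcs_drink(), slow_completion = 1), "exceed")
})

test_that("nonabsorbed osmotic loads carry their water to the colon", {
  tr <- osmotic_trapping(preset_beverage("lactulose_solution"), volume = 0.2)
  tc <- absorption_timecourse(tr, c(0, 3.9, 4, 6))
  expect_equal(tc$to_colon_L, c(0, 0, tr$V_a, tr$V_a))
  expect_equal(tc$absorbed_L, rep(0, 4))   # single-solute lactulose drink
  expect_equal(tc$luminal_L[4], 0)
})

test_that("display truncation follows the two-decimal convention", {
  expect_equal(display_2dp(c(1 / 6, 5 / 6, 4 / 3, 0.6, 0.5)),
               c(0.16, 0.83, 1.33, 0.6, 0.5))
})
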