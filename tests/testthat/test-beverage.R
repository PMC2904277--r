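test_that("beverage osmolarity sums components and honours declared overrides", {
  # monosaccharide mix at 100 g/L: 555 mosm/L
  mono <- sugar_drink(100)
  expect_equal(round(beverage_osmolarity(mono)), 555)
  expect_equal(round(beverage_osmolarity(sugar_drink(125))), 694)

  water <- beverage("water", 0.5)
  expect_identical(beverage_osmolarity(water), 0)

  declared <- beverage("labelled", 0.5, hfcs_composition(100),
                       declared_osmolarity = 800)
  expect_identical(beverage_osmolarity(declared), 800)
})

test_that("osmolarity is invariant under component reordering", {
  comps <- list(
    list(solute = registered_solute("glucose"), concentration = 30),
    list(solute = registered_solute("nacl"), concentration = 5),
    list(solute = registered_solute("sucrose"), concentration = 80))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(beverage_osmolarity(beverage("b", 1, comps[perm])),
                 beverage_osmolarity(beverage("b", 1, comps)))
  }
})

test_that("diluting every concentration by k divides osmolarity by k", {
  bev <- beverage("mix", 0.5, list(
    list(solute = registered_solute("fructose"), concentration = 60),
    list(solute = registered_solute("nacl"), concentration = 4)))
  for (k in c(2, 3, 10)) {
    thin <- beverage("mix/k", 0.5, lapply(bev$components, function(cmp) {
      cmp$concentration <- cmp$concentration / k
      cmp
    }))
    expect_equal(beverage_osmolarity(thin), beverage_osmolarity(bev) / k)
  }
})

test_that("dilute_to_osmolarity hits the target and conserves solute mass", {
  bev <- sugar_drink(144.128)
  dil <- dilute_to_osmolarity(bev, 300)
  expect_equal(beverage_osmolarity(dil), 300)
  mass <- function(b) sum(vapply(b$components, function(cmp)
    cmp$concentration * b$volume, numeric(1)))
  expect_equal(mass(dil), mass(bev))
  # already-isotonic drinks are returned unchanged
  expect_identical(dilute_to_osmolarity(preset_beverage("who_ors"), 300),
                   preset_beverage("who_ors"))
})

test_that("beverage validation rejects bad fields", {
  expect_error(beverage("b", 0), "volume")
  expect_error(beverage("b", 0.5, list(list(
    solute = registered_solute("glucose"), concentration = -2))),
    "concentration")
  expect_error(beverage("b", 0.5, declared_osmolarity = -10),
               "declared_osmolarity")
})

test_that("beverage config files round-trip through read_beverage", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "label: test drink",
    "volume_L: 0.33",
    "components:",
    "  - solute: glucose",
    "    concentration_g_L: 50",
    "  - solute: brine",
    "    concentration_g_L: 6",
    "solutes:",
    "  - name: brine",
    "    molar_mass: 58.44",
    "    particles_per_formula: 2",
    "    absorption_class: electrolyte"), path)
  bev <- read_beverage(path)
  expect_equal(bev$volume, 0.33)
  expect_equal(beverage_osmolarity(bev),
               component_osmolarity(registered_solute("glucose"), 50) +
                 component_osmolarity(registered_solute("nacl"), 6))
  expect_error(read_beverage(tempfile()), "not found")
})

test_that("osmolarity_report tabulates labels, volumes and rounded osmolarity", {
  rep <- osmolarity_report(list(preset_beverage("hfcs_softdrink"),
                                preset_beverage("who_ors")))
  expect_equal(rep$osmolarity_mosm_per_L, c(800, 245))
  csv <- tempfile(fileext = ".csv")
  osmolarity_report(list(preset_beverage("water")), csv)
  expect_true(file.exists(csv))
  expect_equal(utils::read.csv(csv)$osmolarity_mosm_per_L, 0)
})
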