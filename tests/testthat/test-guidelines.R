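test_that("diet_profile does linear accounting and flags empty diets", {
  sys <- tiny_system()
  p <- diet_profile(diet(c(a1 = 100), "t"), sys)
  expect_equal(p$totals[["protein"]], 10)  # 10 g/100g at 100 g/day
  expect_equal(p$energy, 200)
  # protein 50 g/day at 2,000 kcal -> 10 E%
  sys2 <- tiny_system()
  sys2$nutrients["a1", "protein"] <- 5
  sys2$items$energy[1] <- 200
  p2 <- diet_profile(diet(c(a1 = 1000), "t"), sys2)
  expect_equal(p2$totals[["protein"]], 50)
  expect_equal(p2$energy, 2000)
  expect_equal(p2$energy_shares[["protein"]], 10)

  p0 <- diet_profile(diet(c(a1 = 0), "t"), sys)
  expect_true(p0$degenerate)
  expect_true(all(is.na(p0$energy_shares)))
  expect_true(all(p0$totals == 0))
})

test_that("diet_profile is additive in quantities", {
  sys <- generate_food_system(small_params(seed = 31))
  set.seed(1)
  ids <- sys$items$item_id
  q1 <- stats::setNames(runif(length(ids), 0, 50), ids)
  q2 <- stats::setNames(runif(length(ids), 0, 50), ids)
  pa <- diet_profile(diet(q1, "a"), sys)
  pb <- diet_profile(diet(q2, "b"), sys)
  pc <- diet_profile(diet(q1 + q2, "c"), sys)
  expect_equal(pc$totals, pa$totals + pb$totals, tolerance = 1e-12)
  expect_equal(pc$energy, pa$energy + pb$energy, tolerance = 1e-12)
})

test_that("macro_deviation is the largest relative bound violation", {
  gs <- guideline_set(
    macro_energy = data.frame(nutrient_id = c("protein", "sfa"),
                              lower = c(10, NA), upper = c(35, 10)),
    macro_mass = data.frame(nutrient_id = "sodium", lower = NA_real_,
                            upper = 2300),
    micro = data.frame(nutrient_id = "iron", rda = 18, ear = 8.1))
  prof <- structure(list(
    totals = c(sodium = 2000, iron = 20),
    energy = 2000,
    energy_shares = c(protein = 20, sfa = 8),
    degenerate = FALSE, label = "t"), class = "nutrient_profile")
  expect_equal(macro_deviation(prof, gs), 0)

  prof$energy_shares[["protein"]] <- 8           # (10-8)/10 = 0.2
  expect_equal(macro_deviation(prof, gs), 0.2)

  prof$energy_shares <- c(protein = 20, sfa = 11) # 0.1
  prof$totals[["sodium"]] <- 2760                 # 0.2 -> max wins
  expect_equal(macro_deviation(prof, gs), 0.2)

  prof$degenerate <- TRUE
  expect_error(macro_deviation(prof, gs), "zero energy")
})

test_that("micro_deviation caps adequacy at 100% and respects EAR <= RDA", {
  gs <- guideline_set(
    macro_energy = data.frame(nutrient_id = character(0), lower = numeric(0),
                              upper = numeric(0)),
    macro_mass = data.frame(nutrient_id = character(0), lower = numeric(0),
                            upper = numeric(0)),
    micro = data.frame(nutrient_id = c("iron", "vit_e"),
                       rda = c(18, 15), ear = c(8.1, 12)))
  prof <- structure(list(totals = c(iron = 9, vit_e = 40), energy = 2000,
                         energy_shares = numeric(0), degenerate = FALSE,
                         label = "t"), class = "nutrient_profile")
  expect_equal(micro_deviation(prof, gs, "rda"), 0.5)  # iron 9 of 18
  prof$totals <- c(iron = 100, vit_e = 100)            # excess never penalized
  expect_equal(micro_deviation(prof, gs, "rda"), 0)
  # ear deviation never exceeds rda deviation
  set.seed(7)
  for (i in 1:50) {
    prof$totals <- c(iron = runif(1, 0, 30), vit_e = runif(1, 0, 30))
    expect_lte(micro_deviation(prof, gs, "ear"),
               micro_deviation(prof, gs, "rda"))
  }
  # zero references are rejected at construction
  expect_error(guideline_set(gs$macro_energy, gs$macro_mass,
                             data.frame(nutrient_id = "x", rda = 0, ear = 0)),
               "> 0")
})

test_that("relax_guidelines widens by 20%, switches to EAR, refuses twice", {
  gs <- default_guidelines("female", 2000)
  low <- relax_guidelines(gs)
  pe <- low$macro_energy[low$macro_energy$nutrient_id == "protein", ]
  expect_equal(c(pe$lower, pe$upper), c(8, 42))
  na <- low$macro_mass[low$macro_mass$nutrient_id == "sodium", ]
  expect_equal(na$upper, 2760)
  fb <- low$macro_mass[low$macro_mass$nutrient_id == "fiber", ]
  expect_equal(fb$lower, 0.8 * 28)
  expect_equal(low$level, "lowered")
  expect_equal(low$micro_target, "ear")
  expect_error(relax_guidelines(low), "twice")
})

test_that("relaxation never increases either deviation", {
  sys <- generate_food_system(small_params(seed = 41))
  gs <- sys$guidelines$female
  low <- relax_guidelines(gs)
  set.seed(2)
  ids <- sys$items$item_id
  for (i in 1:25) {
    q <- stats::setNames(runif(length(ids), 0, 60), ids)
    prof <- diet_profile(diet(q, "t"), sys)
    expect_lte(macro_deviation(prof, low), macro_deviation(prof, gs) + 1e-12)
    expect_lte(micro_deviation(prof, low), micro_deviation(prof, gs) + 1e-12)
  }
})

test_that("the shipped guidelines.json matches the in-code defaults", {
  f <- system.file("extdata", "guidelines.json", package = "dietopt")
  expect_true(nzchar(f))
  gl <- jsonlite::read_json(f, simplifyVector = TRUE)
  gs <- default_guidelines("female", 2000)
  expect_equal(as.data.frame(gl$female$micro_refs), gs$micro)
  pe <- as.data.frame(gl$female$macro_energy_bounds)
  expect_equal(pe$upper[pe$nutrient_id == "protein"], 35)
  expect_equal(as.data.frame(gl$male$micro_refs)$rda,
               default_guidelines("male")$micro$rda)
})
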