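test_that("generation is bit-identical under a fixed seed", {
  a <- generate_food_system(small_params(seed = 71))
  b <- generate_food_system(small_params(seed = 71))
  expect_identical(a$items, b$items)
  expect_identical(a$nutrients, b$nutrients)
  expect_identical(a$diets$female$quantities, b$diets$female$quantities)
  expect_identical(a$commodities$shares, b$commodities$shares)
  c <- generate_food_system(small_params(seed = 72))
  expect_false(identical(a$nutrients, c$nutrients))
})

test_that("observed diets violate exactly the configured bottlenecks", {
  sys <- generate_food_system(small_params(seed = 73))
  gs <- sys$guidelines$female
  prof <- diet_profile(sys$diets$female, sys)
  # iron shortfall 30% (the generator's own self-check enforces +-0.02;
  # the column calibration makes it essentially exact)
  iron <- gs$micro[gs$micro$nutrient_id == "iron", ]
  expect_equal((iron$rda - prof$totals[["iron"]]) / iron$rda, 0.30,
               tolerance = 0.02)
  expect_equal(micro_deviation(prof, gs), 0.30, tolerance = 0.02)
  expect_equal(macro_deviation(prof, gs), 0.25, tolerance = 0.02)  # fiber
  # non-bottleneck guidelines are met
  expect_gt(prof$totals[["calcium"]],
            gs$micro$rda[gs$micro$nutrient_id == "calcium"])
  expect_lt(prof$energy_shares[["protein"]], 35)
  expect_gt(prof$energy_shares[["protein"]], 10)

  # a single-bottleneck spec is honored too
  sys2 <- generate_food_system(small_params(
    seed = 74, bottleneck_spec = c(iron = 0.30)))
  prof2 <- diet_profile(sys2$diets$female, sys2)
  expect_equal(micro_deviation(prof2, sys2$guidelines$female), 0.30,
               tolerance = 0.02)
  expect_equal(macro_deviation(prof2, sys2$guidelines$female), 0,
               tolerance = 1e-6)
})

test_that("zero dispersion makes within-group optimization inert", {
  sys <- generate_food_system(small_params(seed = 75, nutrient_sd = 0,
                                           ghge_sd = 0))
  for (ac in c(50, 100)) {
    cfg <- scenario_config("within_only", "fine", allowed_change_pct = ac)
    r <- solve_experiment1(sys, sys$diets$female, cfg)
    expect_equal(r$status, "optimal")
    expect_equal(r$ghge_reduction, 0, tolerance = 1e-6)
    prof <- diet_profile(sys$diets$female, sys)
    expect_equal(r$d_micro, micro_deviation(prof, sys$guidelines$female),
                 tolerance = 1e-6)
  }
})

test_that("footprints derived from commodities match stored item GHGE", {
  sys <- generate_food_system(small_params(seed = 76))
  fp <- system_item_footprints(sys)
  stored <- stats::setNames(sys$items$ghge, sys$items$item_id)
  expect_lt(max(abs(fp - stored) / stored), 1e-9)
  expect_true(all(sys$commodities$losses$loss_pct >= 0 &
                    sys$commodities$losses$loss_pct < 50))
})

test_that("within-group GHGE dispersion tracks the requested level", {
  sd_target <- 0.5
  sys <- generate_food_system(generator_params(
    n_groups = 12, items_per_group = c(12, 14), ghge_sd = sd_target,
    seed = 77))
  cl <- sys$classifications$fine
  cv <- tapply(sys$items$ghge, cl$assignment[sys$items$item_id],
               function(v) stats::sd(v) / mean(v))
  cv_target <- sqrt(exp(sd_target^2) - 1)  # lognormal CV
  expect_lt(abs(mean(cv) - cv_target) / cv_target, 0.2)
})

test_that("an unrealizable bottleneck fails with a clear error", {
  # fat at +60% E% forces carbohydrate below its own lower bound
  expect_error(
    generate_food_system(small_params(
      seed = 78, bottleneck_spec = c(fat = 0.60), max_retries = 2)),
    "calibration failed")
})

test_that("generated respondents filter and average as designed", {
  sys <- generate_food_system(small_params(seed = 79))
  rs <- generate_respondents(sys$diets, n = 400, seed = 80)
  kept <- filter_respondents(rs)
  expect_lt(nrow(kept$info), nrow(rs$info))  # tails cross the cutoffs
  expect_gt(nrow(kept$info), 0)

  # n = 1: the average is that respondent
  one <- generate_respondents(sys$diets, n = 1, seed = 81)
  avg1 <- average_diet(one, one$info$sex[1])
  ink <- one$intakes
  expect_equal(avg1$quantities[ink$item_id], stats::setNames(
    ink$grams_per_day, ink$item_id), tolerance = 1e-12)

  # law of large numbers: filtered female average within 5% of the target
  big <- generate_respondents(sys$diets, n = 2000, seed = 82)
  avg <- average_diet(filter_respondents(big), "female")
  tgt <- sys$diets$female$quantities
  common <- intersect(names(avg$quantities), names(tgt))
  expect_equal(sum(avg$quantities[common]), sum(tgt[common]),
               tolerance = 0.05)
  rel <- abs(avg$quantities[common] - tgt[common]) / pmax(tgt[common], 1)
  expect_lt(mean(rel), 0.05)
})

test_that("generated systems survive a write/load round trip", {
  sys <- generate_food_system(small_params(seed = 83))
  dir <- tempfile("fs")
  write_food_system(sys, dir)
  expect_no_error(back <- load_food_system(dir))
  expect_equal(back$items$energy, sys$items$energy, tolerance = 1e-12)
})
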