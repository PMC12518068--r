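test_that("zero allowed change reproduces the observed diet", {
  sys <- tiny_system()
  cfg <- scenario_config("within_only", "toy", allowed_change_pct = 0)
  r <- solve_experiment1(sys, sys$diets$female, cfg)
  expect_equal(r$status, "optimal")
  expect_equal(r$diet$quantities, sys$diets$female$quantities,
               tolerance = 1e-7)
  expect_equal(r$c_total, 0, tolerance = 1e-6)
  expect_equal(r$ghge_reduction, 0, tolerance = 1e-6)
  prof <- diet_profile(sys$diets$female, sys)
  expect_equal(r$d_macro, macro_deviation(prof, sys$guidelines$female),
               tolerance = 1e-6)
  expect_equal(r$d_micro, micro_deviation(prof, sys$guidelines$female),
               tolerance = 1e-6)
})

test_that("the change budget and item cap constrain reallocation as stated", {
  # identical items, GHGE 2 vs 1, o = {a: 10, b: 0}
  sys <- swap_system()
  cfg100 <- scenario_config("within_only", "toy", allowed_change_pct = 100)
  r100 <- solve_experiment1(sys, sys$diets$female, cfg100)
  expect_equal(unname(r100$diet$quantities[c("a", "b")]), c(0, 10),
               tolerance = 1e-4)  # full swap: sum(p + n) = 20 = 2 * mass
  cfg50 <- scenario_config("within_only", "toy", allowed_change_pct = 50)
  r50 <- solve_experiment1(sys, sys$diets$female, cfg50)
  expect_equal(unname(r50$diet$quantities[c("a", "b")]), c(5, 5),
               tolerance = 1e-4)  # at most 5 g may move off a

  # cap at the group's highest observed quantity
  ids <- c("a", "b", "c")
  items <- data.frame(item_id = ids, name = ids, energy = 200,
                      fixed = FALSE, occurrences = 9L, ghge = c(2, 1.5, 1))
  nutm <- matrix(rep(c(10, 2, 2), each = 3), ncol = 3,
                 dimnames = list(ids, c("protein", "fiber", "iron")))
  gs <- guideline_set(
    macro_energy = data.frame(nutrient_id = "protein", lower = 5, upper = 60),
    macro_mass = data.frame(nutrient_id = "fiber", lower = NA_real_,
                            upper = NA_real_),
    micro = data.frame(nutrient_id = "iron", rda = 0.01, ear = 0.008))
  cl <- classification("toy", c(g = "G"), stats::setNames(rep("g", 3), ids))
  sys3 <- food_system(items, nutm, tiny_panel(),
                      classifications = list(toy = cl),
                      diets = list(female = diet(c(a = 10, b = 6, c = 0),
                                                 "female")),
                      guidelines = list(female = gs))
  cfgc <- scenario_config("within_only", "toy", allowed_change_pct = 100,
                          item_cap_enabled = TRUE)
  rc <- solve_experiment1(sys3, sys3$diets$female, cfgc)
  expect_lte(max(rc$diet$quantities), 10 + 1e-6)
  expect_equal(unname(rc$diet$quantities[["c"]]), 10, tolerance = 1e-4)
})

test_that("within_swap instance is solved at its analytic optimum", {
  ko <- generate_known_optimum_instance("within_swap")
  r <- solve_experiment1(ko$system, ko$system$diets$female, ko$config)
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$diet$quantities[c("a", "b")]),
               unname(ko$expected$x), tolerance = 1e-3)
  expect_equal(r$ghge, ko$expected$ghge, tolerance = 1e-4)
  expect_equal(r$ghge_reduction, ko$expected$ghge_reduction,
               tolerance = 1e-4)
  expect_lte(r$d_macro + r$d_micro, 1e-6)
})

test_that("adequacy is bought at the price of higher GHGE when necessary", {
  ko <- generate_known_optimum_instance("adequacy_vs_ghge")
  r <- solve_experiment1(ko$system, ko$system$diets$female, ko$config)
  expect_equal(r$status, "optimal")
  expect_lte(r$d_micro, 1e-5)
  expect_equal(r$ghge, ko$expected$ghge, tolerance = 1e-3)
  expect_gt(r$ghge, ko$expected$ghge_observed)  # stage-2 GHGE above observed
  expect_lt(r$ghge_reduction, 0)
})

test_that("an unreachable GHGE cap is reported infeasible, not thrown", {
  ko <- generate_known_optimum_instance("infeasible_cap")
  r <- expect_no_error(
    solve_experiment3(ko$system, ko$system$diets$female, ko$config))
  expect_equal(r$status, "infeasible")
  expect_true(any(grepl("micro_iron|ghge_cap", r$violated)))
})

test_that("between-group scaling removes the dirty group entirely", {
  ko <- generate_known_optimum_instance("between_removal")
  r <- solve_experiment3(ko$system, ko$system$diets$female, ko$config)
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$diet$quantities[c("b1", "b2")]), c(0, 0),
               tolerance = 1e-6)
  expect_gte(r$ghge_reduction,
             ko$config$ghge_reduction_target - 1e-6)
  # item-level freedom salvages the clean item: strictly less change
  cfg2 <- scenario_config("between_and_within", "toy",
                          ghge_reduction_target =
                            ko$config$ghge_reduction_target)
  r2 <- solve_experiment3(ko$system, ko$system$diets$female, cfg2)
  expect_equal(r2$status, "optimal")
  expect_lt(r2$c_total, r$c_total - 1)
})

test_that("experiment 2 relaxation can only help, never hurt", {
  sys <- tiny_system(iron_rda = 3, fiber_lower = 3)
  cfg1 <- scenario_config("within_only", "toy", allowed_change_pct = 50)
  cfg2 <- scenario_config("within_only", "toy", allowed_change_pct = 50,
                          goal_level = "lowered")
  r1 <- solve_experiment1(sys, sys$diets$female, cfg1)
  r2 <- solve_experiment2(sys, sys$diets$female, cfg2)
  expect_lte(r2$objective_stages[["deviation"]],
             r1$objective_stages[["deviation"]] + 1e-9)
  # zero budget: observed diet regardless of goal level
  cfg0 <- scenario_config("within_only", "toy", allowed_change_pct = 0,
                          goal_level = "lowered")
  r0 <- solve_experiment2(sys, sys$diets$female, cfg0)
  expect_equal(r0$diet$quantities, sys$diets$female$quantities,
               tolerance = 1e-7)
  # on synthetic systems the lowered stage-1 optimum is never worse
  gen <- generate_food_system(small_params(seed = 51))
  for (ac in c(25, 100)) {
    f1 <- solve_experiment1(gen, gen$diets$female,
                            scenario_config("within_only", "fine",
                                            allowed_change_pct = ac))
    f2 <- solve_experiment2(gen, gen$diets$female,
                            scenario_config("within_only", "fine",
                                            allowed_change_pct = ac,
                                            goal_level = "lowered"))
    expect_lte(f2$objective_stages[["deviation"]],
               f1$objective_stages[["deviation"]] + 1e-6)
    expect_gte(f2$ghge_reduction, f1$ghge_reduction - 1e-6)
  }
})

test_that("lexicographic and weighted solves agree on small instances", {
  for (seed in c(101, 102)) {
    inst <- oracle_instance_exp1(seed)
    cfg_lex <- inst$config
    cfg_w <- inst$config; cfg_w$lexicographic <- FALSE
    rl <- solve_experiment1(inst$system, inst$system$diets$female, cfg_lex)
    rw <- solve_experiment1(inst$system, inst$system$diets$female, cfg_w)
    expect_equal(rw$d_macro + rw$d_micro, rl$d_macro + rl$d_micro,
                 tolerance = 1e-3)
  }
})

test_that("build_variables exposes the documented variable structure", {
  sys <- tiny_system()
  sys$items$fixed[sys$items$item_id == "b2"] <- TRUE
  cfgw <- scenario_config("within_only", "toy")
  vars <- build_variables(sys, "toy", cfgw)
  expect_false(any(grepl("b2", vars$name)))  # fixed item never a variable
  expect_setequal(unique(vars$kind),
                  c("quantity", "increase", "decrease", "deviation"))
  cfgb <- scenario_config("between_only", "toy",
                          ghge_reduction_target = 0.3)
  varsb <- build_variables(sys, "toy", cfgb)
  expect_setequal(unique(varsb$kind), c("scale", "increase", "decrease"))
  expect_setequal(varsb$ref[varsb$kind == "scale"], c("gA", "gB"))
})

test_that("scenario models export to LP format", {
  sys <- tiny_system()
  cfg <- scenario_config("within_only", "toy")
  path <- tempfile(fileext = ".lp")
  export_scenario_lp(sys, sys$diets$female, cfg, path)
  txt <- readLines(path)
  expect_true(any(grepl("conserve_gA", txt)))
  expect_true(any(grepl("micro_iron", txt)))
})

test_that("LP optima match the exhaustive grid oracle (within mode)", {
  for (s in 1:6) {
    inst <- oracle_instance_exp1(300 + s)
    gr <- oracle_exp1(inst$system, inst$system$diets$female, inst$config)
    expect_true(gr$feasible)
    r <- solve_experiment1(inst$system, inst$system$diets$female,
                           inst$config)
    v <- oracle_check_exp1(gr, r$d_macro + r$d_micro, r$ghge)
    expect_true(v$ok, label = paste("oracle agreement, seed", 300 + s))
  }
})
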