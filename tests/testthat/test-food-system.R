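make_resp <- function(ids, sex, age, energy) {
  respondent_set(
    data.frame(respondent_id = ids, sex = sex, age = age,
               energy_intake = energy),
    data.frame(respondent_id = character(0), item_id = character(0),
               grams_per_day = numeric(0)))
}

test_that("respondent filter applies the documented cutoffs inclusively", {
  r <- make_resp(
    sprintf("r%02d", 1:10),
    c("female", "male", "female", "female", "female", "male", "male",
      "male", "female", "female"),
    c(30, 40, 17, 18, 30, 30, 30, 30, 65, 66),
    c(1100, 3700, 2000, 1200, 3000, 1800, 1799, 3600, 2000, 2000))
  kept <- filter_respondents(r)$info$respondent_id
  expect_false("r01" %in% kept)  # female below 1,200 kcal
  expect_false("r02" %in% kept)  # male above 3,600 kcal
  expect_false("r03" %in% kept)  # age 17
  expect_true("r04" %in% kept)   # exactly 1,200 kcal at age 18
  expect_true("r05" %in% kept)   # exactly 3,000 kcal
  expect_true("r06" %in% kept)   # exactly 1,800 kcal
  expect_false("r07" %in% kept)  # male below 1,800
  expect_true("r08" %in% kept)   # exactly 3,600
  expect_true("r09" %in% kept)   # age 65
  expect_false("r10" %in% kept)  # age 66
  # order preserved and idempotent
  expect_equal(kept, sort(kept))
  twice <- filter_respondents(filter_respondents(r))
  expect_identical(twice$info, filter_respondents(r)$info)
})

test_that("unknown sex labels are rejected with the offending record", {
  expect_error(make_resp("r1", "unknown", 30, 2000), "r1")
})

test_that("average_diet takes the mean with implicit zeros", {
  r <- respondent_set(
    data.frame(respondent_id = c("f1", "f2", "m1", "m2", "m3"),
               sex = c("female", "female", "male", "male", "male"),
               age = 30, energy_intake = 2000),
    data.frame(respondent_id = c("f1", "m1", "m2", "m3"),
               item_id = c("A", "B", "B", "B"),
               grams_per_day = c(100, 30, 60, 90)))
  df <- average_diet(r, "female")
  expect_equal(unname(df$quantities["A"]), 50)  # (100 + 0)/2
  dm <- average_diet(r, "male")
  expect_equal(unname(dm$quantities["B"]), 60)
  expect_error(average_diet(r, "other"))

  # single respondent: identity
  one <- respondent_set(
    data.frame(respondent_id = "f1", sex = "female", age = 30,
               energy_intake = 2000),
    data.frame(respondent_id = "f1", item_id = c("A", "B"),
               grams_per_day = c(12.5, 80)))
  expect_equal(average_diet(one, "female")$quantities,
               c(A = 12.5, B = 80))

  # n identical copies equal that respondent
  n <- 5
  copies <- respondent_set(
    data.frame(respondent_id = paste0("f", 1:n), sex = "female", age = 30,
               energy_intake = 2000),
    data.frame(respondent_id = rep(paste0("f", 1:n), each = 2),
               item_id = rep(c("A", "B"), n),
               grams_per_day = rep(c(12.5, 80), n)))
  expect_equal(average_diet(copies, "female")$quantities,
               c(A = 12.5, B = 80))
})

test_that("mark_fixed_items freezes rare items and the residual group", {
  ids <- c("x1", "x2", "x3")
  items <- data.frame(item_id = ids, name = ids, energy = 100,
                      fixed = FALSE, occurrences = c(3L, 4L, 100L),
                      ghge = 0.5)
  nutm <- matrix(1, 3, 1, dimnames = list(ids, "iron"))
  cl <- classification("c", c(g = "Group", other = "Other"),
                       c(x1 = "g", x2 = "g", x3 = "other"))
  sys <- food_system(items, nutm,
                     nutrient_defs("iron", unit = "mg", kind = "micro"),
                     classifications = list(c = cl))
  sys <- mark_fixed_items(sys, "c")
  fx <- stats::setNames(sys$items$fixed, sys$items$item_id)
  expect_true(fx[["x1"]])    # consumed three times or less
  expect_false(fx[["x2"]])   # just above the threshold
  expect_true(fx[["x3"]])    # residual "other" group, however popular
})

test_that("food systems round-trip through the CSV/JSON schemas", {
  sys <- generate_food_system(small_params(seed = 11))
  dir <- tempfile("fs")
  write_food_system(sys, dir)
  back <- load_food_system(dir)
  expect_equal(back$items$item_id, sys$items$item_id)
  expect_lt(max(abs(back$nutrients - sys$nutrients) /
                  pmax(sys$nutrients, 1e-12)), 1e-9)
  expect_lt(max(abs(back$items$ghge - sys$items$ghge) / sys$items$ghge), 1e-9)
  for (lab in names(sys$diets)) {
    expect_equal(back$diets[[lab]]$quantities, sys$diets[[lab]]$quantities,
                 tolerance = 1e-12)
  }
  expect_equal(back$guidelines$female$macro_energy,
               sys$guidelines$female$macro_energy, tolerance = 1e-12)
  expect_equal(sort(names(back$classifications)),
               sort(names(sys$classifications)))
  expect_equal(back$classifications$fine$assignment,
               sys$classifications$fine$assignment)
  expect_equal(back$commodities$shares$weight_g_per_100g,
               sys$commodities$shares$weight_g_per_100g, tolerance = 1e-12)
  # write -> load -> write is byte-stable
  dir2 <- tempfile("fs")
  write_food_system(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)), label = f)
  }
})

test_that("cross-reference violations are caught with names", {
  sys <- tiny_system()
  bad <- sys
  bad$diets$female$quantities <- c(bad$diets$female$quantities, ghost = 10)
  expect_error(validate_food_system(bad), "ghost")
  bad2 <- sys
  bad2$classifications$toy$assignment <-
    bad2$classifications$toy$assignment[-1]
  expect_error(validate_food_system(bad2), "a1")
  # missing nutrient column on load
  dir <- tempfile("fs")
  write_food_system(sys, dir)
  foods <- utils::read.csv(file.path(dir, "foods.csv"))
  foods$iron <- NULL
  utils::write.csv(foods, file.path(dir, "foods.csv"), row.names = FALSE)
  expect_error(load_food_system(dir), "iron")
})
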