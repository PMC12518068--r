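# Small hand-built fixtures shared across tests. Everything is constructed in
# code; no files are read.

tiny_panel <- function() {
  nutrient_defs(c("protein", "fiber", "iron"),
                unit = c("g", "g", "mg"),
                kind = c("macro_energy", "macro_mass", "micro"),
                atwater = c(4, NA, NA))
}

# Two groups x two items with easy round numbers; observed diet violates the
# iron reference. Guidelines kept loose except where a test tightens them.
tiny_system <- function(iron_rda = 2, fiber_lower = 2,
                        protein_bounds = c(5, 60), ghge = c(1, 2, 0.5, 3),
                        q = c(a1 = 50, a2 = 50, b1 = 40, b2 = 10)) {
  ids <- c("a1", "a2", "b1", "b2")
  items <- data.frame(item_id = ids, name = toupper(ids),
                      energy = c(200, 200, 100, 100),
                      fixed = FALSE, occurrences = 50L, ghge = ghge)
  nutm <- matrix(c(10, 10, 5, 5,      # protein g/100g
                   2, 2, 1, 4,        # fiber g/100g
                   1, 3, 2, 2),       # iron mg/100g
                 ncol = 3, dimnames = list(ids, c("protein", "fiber", "iron")))
  gs <- guideline_set(
    macro_energy = data.frame(nutrient_id = "protein",
                              lower = protein_bounds[1],
                              upper = protein_bounds[2]),
    macro_mass = data.frame(nutrient_id = "fiber", lower = fiber_lower,
                            upper = NA_real_),
    micro = data.frame(nutrient_id = "iron", rda = iron_rda,
                       ear = 0.8 * iron_rda))
  cl <- classification("toy", c(gA = "Group A", gB = "Group B"),
                       c(a1 = "gA", a2 = "gA", b1 = "gB", b2 = "gB"))
  food_system(items, nutm, tiny_panel(),
              classifications = list(toy = cl),
              diets = list(female = diet(q, "female")),
              guidelines = list(female = gs))
}

# One-group system with two items of identical composition but different
# footprints; handy for budget/cap arithmetic.
swap_system <- function(q = c(a = 10, b = 0), ghge = c(2, 1)) {
  ids <- c("a", "b")
  items <- data.frame(item_id = ids, name = toupper(ids), energy = 200,
                      fixed = FALSE, occurrences = 50L, ghge = ghge)
  nutm <- matrix(c(10, 10, 2, 2, 2, 2), ncol = 3,
                 dimnames = list(ids, c("protein", "fiber", "iron")))
  gs <- guideline_set(
    macro_energy = data.frame(nutrient_id = "protein", lower = 5, upper = 60),
    macro_mass = data.frame(nutrient_id = "fiber", lower = NA_real_,
                            upper = NA_real_),
    micro = data.frame(nutrient_id = "iron", rda = 0.01, ear = 0.008))
  cl <- classification("toy", c(g1 = "Group 1"), c(a = "g1", b = "g1"))
  food_system(items, nutm, tiny_panel(),
              classifications = list(toy = cl),
              diets = list(female = diet(q, "female")),
              guidelines = list(female = gs))
}

small_params <- function(seed, n_groups = 6, items_per_group = c(3, 5), ...) {
  generator_params(n_groups = n_groups, items_per_group = items_per_group,
                   seed = seed, ...)
}
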