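#' Construct a nutrient guideline set
#'
#' A guideline set holds the macronutrient bounds (E% for protein,
#' carbohydrate, fat, SFA; mass/day for fiber and sodium) and the
#' micronutrient reference intakes (RDA and EAR) that a diet is evaluated
#' against. `micro_target` records which reference the set currently aims at;
#' [relax_guidelines()] switches it from RDA to EAR while widening the
#' macronutrient bounds.
#'
#' @param macro_energy `data.frame` with columns `nutrient_id`, `lower`,
#'   `upper` in E%; either bound may be `NA` (e.g. SFA is upper-only).
#' @param macro_mass `data.frame` with columns `nutrient_id`, `lower`,
#'   `upper` in the nutrient's mass unit per day (fiber lower, sodium upper).
#' @param micro `data.frame` with columns `nutrient_id`, `rda`, `ear`
#'   (amount/day, `ear <= rda`).
#' @param level `"full"` or `"lowered"`.
#' @param micro_target `"rda"` or `"ear"`.
#' @return an object of class `guideline_set`.
#' @export
guideline_set <- function(macro_energy, macro_mass, micro,
                          level = "full", micro_target = "rda") {
  stopifnot(level %in% c("full", "lowered"),
            micro_target %in% c("rda", "ear"))
  chk_bounds <- function(d, what) {
    stopifnot(all(c("nutrient_id", "lower", "upper") %in% names(d)))
    both <- !is.na(d$lower) & !is.na(d$upper)
    if (any(d$lower[both] >= d$upper[both]))
      stop(what, ": lower bound must be < upper bound where both are present")
    if (any(!is.na(d$lower) & d$lower < 0) || any(!is.na(d$upper) & d$upper <= 0))
      stop(what, ": bounds must be positive where present")
    d
  }
  macro_energy <- chk_bounds(macro_energy, "macro_energy")
  macro_mass <- chk_bounds(macro_mass, "macro_mass")
  stopifnot(all(c("nutrient_id", "rda", "ear") %in% names(micro)))
  if (any(micro$rda <= 0) || any(micro$ear <= 0))
    stop("micro references must be > 0")
  if (any(micro$ear > micro$rda + 1e-12))
    stop("ear must be <= rda for every micronutrient")
  structure(list(macro_energy = macro_energy, macro_mass = macro_mass,
                 micro = micro, level = level, micro_target = micro_target),
            class = "guideline_set")
}

#' Default guideline set
#'
#' Macronutrient acceptable ranges (protein 10-35 E%, carbohydrate 45-65 E%,
#' fat 20-35 E%, SFA <= 10 E%), sodium <= 2,300 mg/day, fiber >=
#' 14 g per 1,000 kcal converted to g/day at the supplied reference energy,
#' and adult micronutrient RDA/EAR values by sex from the US Dietary
#' Reference Intake tables. These defaults are configuration, not ground
#' truth; any of them can be replaced via [guideline_set()].
#'
#' @param sex `"female"` or `"male"` (selects the micronutrient references).
#' @param energy_kcal reference energy intake used to convert the fiber
#'   density recommendation to g/day (default 2,000).
#' @return a `guideline_set` at `level = "full"`, targeting the RDA.
#' @export
default_guidelines <- function(sex = "female", energy_kcal = 2000) {
  stopifnot(sex %in% c("female", "male"), energy_kcal > 0)
  macro_energy <- data.frame(
    nutrient_id = c("protein", "carbohydrate", "fat", "sfa"),
    lower = c(10, 45, 20, NA),
    upper = c(35, 65, 35, 10))
  macro_mass <- data.frame(
    nutrient_id = c("fiber", "sodium"),
    lower = c(14 * energy_kcal / 1000, NA),
    upper = c(NA, 2300))
  micro <- if (sex == "female") data.frame(
    nutrient_id = c("calcium", "folate", "iron", "magnesium", "vit_a", "vit_e"),
    rda = c(1000, 400, 18, 310, 700, 15),
    ear = c(800, 320, 8.1, 255, 500, 12)
  ) else data.frame(
    nutrient_id = c("calcium", "folate", "iron", "magnesium", "vit_a", "vit_e"),
    rda = c(1000, 400, 8, 400, 900, 15),
    ear = c(800, 320, 6, 330, 625, 12)
  )
  guideline_set(macro_energy, macro_mass, micro)
}

#' Nutrient profile of a diet
#'
#' Linear accounting: per-day nutrient totals and energy are quantity-weighted
#' sums of the per-100 g compositions, and energy shares (E%) are computed for
#' the `macro_energy` nutrients as `100 * atwater * grams / energy`.
#'
#' @param d a [diet()].
#' @param system a `food_system` whose compositions cover the consumed items.
#' @return an object of class `nutrient_profile`: list with `totals` (named,
#'   amount/day), `energy` (kcal/day), `energy_shares` (named E%, `NA` with
#'   `degenerate = TRUE` when energy is zero) and `label`.
#' @export
diet_profile <- function(d, system) {
  stopifnot(inherits(d, "diet"), inherits(system, "food_system"))
  q <- diet_on_items(d, system$items$item_id) / 100  # "per 100 g" -> per g
  totals <- as.numeric(crossprod(system$nutrients, q))
  names(totals) <- colnames(system$nutrients)
  energy <- sum(system$items$energy * q)
  defs <- system$nutrient_defs
  me <- defs[defs$kind == "macro_energy", ]
  me <- me[me$nutrient_id %in% names(totals), ]
  degenerate <- energy <= 0
  shares <- if (degenerate) {
    stats::setNames(rep(NA_real_, nrow(me)), me$nutrient_id)
  } else {
    stats::setNames(100 * me$atwater * totals[me$nutrient_id] / energy,
                    me$nutrient_id)
  }
  structure(list(totals = totals, energy = energy, energy_shares = shares,
                 degenerate = degenerate, label = d$label),
            class = "nutrient_profile")
}

#' Largest relative deviation from the macronutrient guidelines
#'
#' For every macronutrient bound, the relative violation is
#' `max(0, (v - u)/u)` against an upper bound `u` and `max(0, (l - v)/l)`
#' against a lower bound `l`, where `v` is the E% share for `macro_energy`
#' nutrients and the mass/day total for `macro_mass` nutrients. The returned
#' deviation is the maximum over all bounds (minimax goal programming), a
#' dimensionless fraction that is zero iff every bound is met.
#'
#' @param profile a [diet_profile()].
#' @param gs a [guideline_set()].
#' @return a single non-negative number.
#' @export
macro_deviation <- function(profile, gs) {
  stopifnot(inherits(profile, "nutrient_profile"), inherits(gs, "guideline_set"))
  if (profile$degenerate) stop("macro_deviation undefined at zero energy")
  dev <- 0
  for (k in seq_len(nrow(gs$macro_energy))) {
    b <- gs$macro_energy[k, ]
    v <- profile$energy_shares[[b$nutrient_id]]
    if (is.null(v) || is.na(v))
      stop("no energy share for nutrient ", b$nutrient_id)
    if (!is.na(b$upper)) dev <- max(dev, (v - b$upper) / b$upper)
    if (!is.na(b$lower)) dev <- max(dev, (b$lower - v) / b$lower)
  }
  for (k in seq_len(nrow(gs$macro_mass))) {
    b <- gs$macro_mass[k, ]
    v <- profile$totals[[b$nutrient_id]]
    if (is.null(v)) stop("no total for nutrient ", b$nutrient_id)
    if (!is.na(b$upper)) dev <- max(dev, (v - b$upper) / b$upper)
    if (!is.na(b$lower)) dev <- max(dev, (b$lower - v) / b$lower)
  }
  max(0, dev)
}

#' Largest relative micronutrient shortfall
#'
#' The deviation against reference intakes (RDA or EAR) is the maximum over
#' micronutrients of `max(0, (ref - intake)/ref)`; intake above the reference
#' is never penalized (adequacy is capped at 100%).
#'
#' @param profile a [diet_profile()].
#' @param gs a [guideline_set()] supplying the references.
#' @param target `"rda"` or `"ear"`; defaults to the set's `micro_target`.
#' @return a single number in `[0, 1]`.
#' @export
micro_deviation <- function(profile, gs, target = gs$micro_target) {
  stopifnot(inherits(profile, "nutrient_profile"), inherits(gs, "guideline_set"),
            target %in% c("rda", "ear"))
  if (!nrow(gs$micro)) stop("guideline set has no micronutrient references")
  refs <- gs$micro[[target]]
  if (any(refs == 0)) stop("micronutrient reference of 0 is not allowed")
  intake <- profile$totals[gs$micro$nutrient_id]
  if (any(is.na(intake)))
    stop("profile lacks totals for: ",
         paste(gs$micro$nutrient_id[is.na(intake)], collapse = ", "))
  max(0, (refs - intake) / refs)
}

#' Relax a guideline set by 20% and lower micronutrient goals to the EAR
#'
#' Every macronutrient lower bound is multiplied by 0.8 and every upper bound
#' by 1.2 (so protein 10-35 E% becomes 8-42 E%), and the micronutrient target
#' switches from the RDA to the EAR. Applying the relaxation twice is an
#' error, preventing silent double relaxation.
#'
#' @param gs a `guideline_set` at `level = "full"`.
#' @return the relaxed `guideline_set` (`level = "lowered"`).
#' @export
relax_guidelines <- function(gs) {
  stopifnot(inherits(gs, "guideline_set"))
  if (gs$level != "full")
    stop("guideline set is already lowered; refusing to relax twice")
  widen <- function(d) {
    d$lower <- d$lower * 0.8
    d$upper <- d$upper * 1.2
    d
  }
  guideline_set(widen(gs$macro_energy), widen(gs$macro_mass), gs$micro,
                level = "lowered", micro_target = "ear")
}
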