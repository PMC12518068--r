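#' Define a nutrient panel
#'
#' A nutrient definition table declares, for every nutrient tracked by a food
#' system, its unit and how it is constrained: `macro_energy` nutrients
#' (protein, carbohydrate, fat, saturated fat) are bounded as a percentage of
#' energy intake (E%) using their Atwater factor; `macro_mass` nutrients
#' (fiber, sodium) are bounded in mass per day; `micro` nutrients are compared
#' against RDA/EAR reference intakes.
#'
#' @param nutrient_id,name,unit,kind,atwater parallel vectors; `kind` in
#'   `c("macro_energy", "macro_mass", "micro")`; `atwater` (kcal/g) must be 4
#'   or 9 for `macro_energy` nutrients and `NA` otherwise.
#' @return a `data.frame` of class `nutrient_defs`.
#' @export
nutrient_defs <- function(nutrient_id, name = nutrient_id, unit, kind,
                          atwater = NA_real_) {
  d <- data.frame(nutrient_id = as.character(nutrient_id),
                  name = as.character(name),
                  unit = as.character(unit),
                  kind = as.character(kind),
                  atwater = as.numeric(atwater),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$nutrient_id))
    stop("duplicated nutrient_id in nutrient definitions")
  if (!all(d$kind %in% c("macro_energy", "macro_mass", "micro")))
    stop("kind must be macro_energy, macro_mass or micro")
  me <- d$kind == "macro_energy"
  if (any(is.na(d$atwater[me])) || any(!d$atwater[me] %in% c(4, 9)))
    stop("macro_energy nutrients need an Atwater factor of 4 or 9 kcal/g")
  if (any(!is.na(d$atwater[!me])))
    stop("atwater must be NA for non macro_energy nutrients")
  class(d) <- c("nutrient_defs", "data.frame")
  d
}

#' Default nutrient panel
#'
#' Energy plus the twelve nutrients the pipeline constrains by default:
#' protein, carbohydrate, total fat and SFA as E% macronutrients; fiber and
#' sodium as mass-per-day macronutrients; calcium, folate, iron, magnesium,
#' vitamin A and vitamin E as micronutrients. Energy itself is carried in the
#' food table, not in the panel.
#'
#' @return a `nutrient_defs` table.
#' @export
default_nutrient_defs <- function() {
  nutrient_defs(
    nutrient_id = c("protein", "carbohydrate", "fat", "sfa",
                    "fiber", "sodium",
                    "calcium", "folate", "iron", "magnesium", "vit_a", "vit_e"),
    name = c("Protein", "Carbohydrate", "Total fat", "Saturated fatty acids",
             "Dietary fiber", "Sodium",
             "Calcium", "Folate", "Iron", "Magnesium",
             "Vitamin A", "Vitamin E"),
    unit = c("g", "g", "g", "g", "g", "mg",
             "mg", "ug", "mg", "mg", "ug", "mg"),
    kind = c(rep("macro_energy", 4), rep("macro_mass", 2), rep("micro", 6)),
    atwater = c(4, 4, 9, 9, rep(NA_real_, 8))
  )
}
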