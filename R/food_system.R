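#' Construct a food-group classification
#'
#' A classification partitions the optimizable food items into named groups at
#' some granularity (the study setting uses three: a fine custom scheme, the
#' WWEIA subgroups and the FNDDS groups). Every optimizable item must belong
#' to exactly one group; fixed items may be left unassigned.
#'
#' @param classification_id short identifier, e.g. `"fine"`.
#' @param groups named character vector, `group_id -> group name`.
#' @param assignment named character vector, `item_id -> group_id`.
#' @return an object of class `classification`.
#' @export
classification <- function(classification_id, groups, assignment) {
  stopifnot(is.character(groups), !is.null(names(groups)),
            is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment)))
    stop("duplicated item_id in classification assignment")
  unknown <- setdiff(unique(assignment), names(groups))
  if (length(unknown))
    stop("assignment references unknown group_id: ",
         paste(unknown, collapse = ", "))
  structure(list(classification_id = classification_id,
                 groups = groups, assignment = assignment),
            class = "classification")
}

#' Construct a diet
#'
#' A diet is a vector of average consumed quantities (g/day) over food items
#' for one target group (e.g. females or males).
#'
#' @param quantities named non-negative numeric vector, `item_id -> g/day`.
#' @param label text label, e.g. `"female"`.
#' @return an object of class `diet`.
#' @export
diet <- function(quantities, label = "diet") {
  stopifnot(is.numeric(quantities), !is.null(names(quantities)))
  if (anyDuplicated(names(quantities))) stop("duplicated item_id in diet")
  if (any(quantities < 0)) stop("diet quantities must be non-negative")
  structure(list(label = label, quantities = quantities), class = "diet")
}

#' Assemble a food system
#'
#' The food system is the complete modeling universe: the item table with
#' compositions per 100 g, optional item-level footprints, one or more
#' classifications, observed diets, guideline sets, and (optionally) the
#' commodity decomposition used by the footprint module.
#'
#' @param items `data.frame` with columns `item_id`, `name`, `energy`
#'   (kcal/100 g), `fixed` (logical), `occurrences` (reporting occurrences
#'   across recalls), `ghge` (kg CO2eq/100 g, may be `NA` if derived later).
#' @param nutrients numeric matrix, rows = items (rownames = `item_id`),
#'   columns = nutrient ids, amounts per 100 g in the panel's units.
#' @param nutrient_defs a [nutrient_defs()] table covering all columns.
#' @param classifications named list of [classification()] objects.
#' @param diets named list of [diet()] objects.
#' @param guidelines named list of [guideline_set()] objects (typically one
#'   per sex).
#' @param commodities `NULL` or a list with elements `shares`
#'   (`item_id, commodity_id, weight_g_per_100g`), `ghge`
#'   (`commodity_id, ghge` in kg CO2eq per g) and `losses`
#'   (`commodity_id, loss_pct`).
#' @return a validated object of class `food_system`.
#' @export
food_system <- function(items, nutrients, nutrient_defs,
                        classifications = list(), diets = list(),
                        guidelines = list(), commodities = NULL) {
  sys <- structure(list(items = items, nutrients = nutrients,
                        nutrient_defs = nutrient_defs,
                        classifications = classifications, diets = diets,
                        guidelines = guidelines, commodities = commodities),
                   class = "food_system")
  validate_food_system(sys)
  sys
}

#' Validate a food system's cross-references and invariants
#'
#' Checks non-negativity of energy, nutrient amounts and footprints; that
#' every classification is total over optimizable items with non-empty groups;
#' and that every diet's domain is a subset of the item universe.
#'
#' @param system a `food_system`.
#' @return `system`, invisibly; stops with an informative error otherwise.
#' @export
validate_food_system <- function(system) {
  it <- system$items
  need <- c("item_id", "name", "energy", "fixed", "occurrences", "ghge")
  miss <- setdiff(need, names(it))
  if (length(miss))
    stop("items table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(it$item_id)) stop("duplicated item_id in items table")
  if (any(it$energy < 0)) stop("item energy must be >= 0")
  if (any(!is.na(it$ghge) & it$ghge < 0)) stop("item ghge must be >= 0")
  nm <- system$nutrients
  if (!is.matrix(nm) || is.null(rownames(nm)))
    stop("nutrients must be a matrix with item_id rownames")
  if (!setequal(rownames(nm), it$item_id))
    stop("nutrient matrix rows must match the items table")
  defs <- system$nutrient_defs
  unknown_nut <- setdiff(colnames(nm), defs$nutrient_id)
  if (length(unknown_nut))
    stop("nutrient column(s) not in the panel: ",
         paste(unknown_nut, collapse = ", "))
  if (any(nm < 0)) stop("nutrient amounts must be >= 0")
  optim_ids <- it$item_id[!it$fixed]
  for (cl in system$classifications) {
    missing_items <- setdiff(optim_ids, names(cl$assignment))
    if (length(missing_items))
      stop("classification '", cl$classification_id,
           "' does not cover optimizable item(s): ",
           paste(utils::head(missing_items, 5), collapse = ", "))
    stray <- setdiff(names(cl$assignment), it$item_id)
    if (length(stray))
      stop("classification '", cl$classification_id,
           "' references unknown item_id: ",
           paste(utils::head(stray, 5), collapse = ", "))
    used <- unique(cl$assignment)
    empty <- setdiff(names(cl$groups), used)
    if (length(empty))
      stop("classification '", cl$classification_id, "' has empty group(s): ",
           paste(empty, collapse = ", "))
  }
  for (d in system$diets) {
    stray <- setdiff(names(d$quantities), it$item_id)
    if (length(stray))
      stop("diet '", d$label, "' references unknown item_id: ",
           paste(utils::head(stray, 5), collapse = ", "))
  }
  if (!is.null(system$commodities)) {
    co <- system$commodities
    stopifnot(all(c("shares", "ghge", "losses") %in% names(co)))
    stray <- setdiff(co$shares$item_id, it$item_id)
    if (length(stray))
      stop("commodity shares reference unknown item_id: ",
           paste(utils::head(stray, 5), collapse = ", "))
    if (any(co$shares$weight_g_per_100g < 0)) stop("commodity weights must be >= 0")
    if (any(co$ghge$ghge < 0)) stop("commodity ghge must be >= 0")
    if (any(co$losses$loss_pct < 0 | co$losses$loss_pct >= 100))
      stop("loss_pct must lie in [0, 100)")
  }
  invisible(system)
}

#' Mark items excluded from optimization
#'
#' Items in the classification's `"other"` group, and items reported at most
#' `min_occurrences` times across all recalls, keep their observed quantities
#' throughout optimization (`fixed = TRUE`).
#'
#' @param system a `food_system`.
#' @param classification_id which classification supplies the `"other"` group.
#' @param min_occurrences occurrence threshold (default 3: consumed three
#'   times or less means fixed).
#' @param other_group group id treated as the residual category.
#' @return the updated `food_system`.
#' @export
mark_fixed_items <- function(system, classification_id,
                             min_occurrences = 3, other_group = "other") {
  cl <- system$classifications[[classification_id]]
  if (is.null(cl)) stop("unknown classification: ", classification_id)
  it <- system$items
  grp <- cl$assignment[it$item_id]
  fixed <- it$occurrences <= min_occurrences |
    (!is.na(grp) & grp == other_group)
  system$items$fixed <- unname(fixed)
  validate_food_system(system)
}

#' @export
print.food_system <- function(x, ...) {
  cat("<food_system>", nrow(x$items), "items (",
      sum(!x$items$fixed), "optimizable ),",
      ncol(x$nutrients), "nutrients,",
      length(x$classifications), "classifications,",
      length(x$diets), "diets\n")
  invisible(x)
}

#' @export
print.diet <- function(x, ...) {
  cat("<diet>", x$label, ":", length(x$quantities), "items,",
      round(sum(x$quantities), 1), "g/day total\n")
  invisible(x)
}

# Quantities of a diet expanded over the full item universe (zeros filled).
diet_on_items <- function(d, item_ids) {
  q <- stats::setNames(numeric(length(item_ids)), item_ids)
  q[names(d$quantities)] <- d$quantities
  q
}
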