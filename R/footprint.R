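#' Loss-adjusted footprint of one composite food
#'
#' A consumed (composite) food is decomposed into primary commodities; its
#' greenhouse gas footprint per 100 g is the sum over commodities of
#' `weight * ghge * 100 / (100 - loss_pct)`: the farm-gate emission intensity
#' of each commodity gram, inflated by the share of farm-gate weight lost
#' between farm and fork, since more than one gram must be produced for every
#' gram eaten.
#'
#' @param shares `data.frame` with columns `commodity_id` and
#'   `weight_g_per_100g` (g of commodity per 100 g of the food); an empty
#'   decomposition yields 0.
#' @param footprints `data.frame` with columns `commodity_id`, `ghge`
#'   (kg CO2eq per **gram** of commodity).
#' @param losses `data.frame` with columns `commodity_id`, `loss_pct`
#'   (% of weight lost farm-to-fork, `< 100` strictly).
#' @param missing_loss `"zero"` (default: a commodity without a loss factor is
#'   treated as 0% loss, with a warning) or `"error"`.
#' @return kg CO2eq per 100 g of the food.
#' @export
item_footprint <- function(shares, footprints, losses,
                           missing_loss = c("zero", "error")) {
  missing_loss <- match.arg(missing_loss)
  if (is.null(shares) || nrow(shares) == 0) return(0)
  stopifnot(all(c("commodity_id", "weight_g_per_100g") %in% names(shares)),
            all(c("commodity_id", "ghge") %in% names(footprints)),
            all(c("commodity_id", "loss_pct") %in% names(losses)))
  if (any(shares$weight_g_per_100g < 0)) stop("commodity weights must be >= 0")
  g <- footprints$ghge[match(shares$commodity_id, footprints$commodity_id)]
  if (anyNA(g))
    stop("no footprint for commodity: ",
         paste(shares$commodity_id[is.na(g)], collapse = ", "))
  l <- losses$loss_pct[match(shares$commodity_id, losses$commodity_id)]
  if (anyNA(l)) {
    if (missing_loss == "error")
      stop("no loss factor for commodity: ",
           paste(shares$commodity_id[is.na(l)], collapse = ", "))
    warning("missing loss factor treated as 0% for: ",
            paste(shares$commodity_id[is.na(l)], collapse = ", "))
    l[is.na(l)] <- 0
  }
  if (any(l >= 100))
    stop("loss_pct >= 100% for commodity: ",
         paste(shares$commodity_id[l >= 100], collapse = ", "))
  sum(shares$weight_g_per_100g * g * 100 / (100 - l))
}

#' Footprints for every item of a food system
#'
#' Applies [item_footprint()] to each item's commodity decomposition.
#'
#' @param system a `food_system` carrying a `commodities` block.
#' @param missing_loss passed to [item_footprint()].
#' @return named numeric vector, kg CO2eq per 100 g per `item_id` (0 for
#'   items without a decomposition).
#' @export
system_item_footprints <- function(system, missing_loss = "zero") {
  stopifnot(inherits(system, "food_system"))
  co <- system$commodities
  if (is.null(co)) stop("food system has no commodity decomposition")
  ids <- system$items$item_id
  fp <- stats::setNames(numeric(length(ids)), ids)
  sp <- split(co$shares, co$shares$item_id)
  for (id in names(sp)) {
    fp[[id]] <- item_footprint(sp[[id]], co$ghge, co$losses,
                               missing_loss = missing_loss)
  }
  fp
}

#' Greenhouse gas emissions of a whole diet
#'
#' Linear in quantities: `sum(quantity/100 * footprint_per_100g)` over
#' consumed items.
#'
#' @param d a [diet()].
#' @param item_footprints named numeric vector, kg CO2eq per 100 g by
#'   `item_id`; must cover every item consumed with positive quantity.
#' @return kg CO2eq per day.
#' @export
diet_ghge <- function(d, item_footprints) {
  stopifnot(inherits(d, "diet"))
  q <- d$quantities
  used <- names(q)[q > 0]
  missing <- setdiff(used, names(item_footprints))
  if (length(missing))
    stop("no footprint for consumed item(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!length(used)) return(0)
  sum(q[used] / 100 * item_footprints[used])
}

#' Per-group contributions to the diet footprint
#'
#' Splits the diet's GHGE across the groups of a classification; items the
#' classification does not assign (typically fixed items) are pooled under
#' `"(unassigned)"`. Contributions always sum to [diet_ghge()]. Optionally the
#' returned table can be limited to groups carrying at least `min_items` food
#' items, the convention used when reporting top-contributing groups.
#'
#' @param d a [diet()].
#' @param item_footprints as in [diet_ghge()].
#' @param cl a [classification()].
#' @param min_items if not `NULL`, drop groups with fewer consumed items from
#'   the returned vector (the conservation property then holds only for the
#'   full, unfiltered vector).
#' @return named numeric vector, kg CO2eq/day by `group_id`, decreasing.
#' @export
group_ghge_contributions <- function(d, item_footprints, cl, min_items = NULL) {
  stopifnot(inherits(d, "diet"), inherits(cl, "classification"))
  q <- d$quantities
  used <- names(q)[q > 0]
  grp <- cl$assignment[used]
  grp[is.na(grp)] <- "(unassigned)"
  contrib <- q[used] / 100 * item_footprints[used]
  out <- tapply(contrib, grp, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  if (!is.null(min_items)) {
    counts <- table(grp)
    out <- out[names(out) %in% names(counts)[counts >= min_items]]
  }
  sort(out, decreasing = TRUE)
}
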