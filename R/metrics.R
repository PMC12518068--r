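#' Total dietary change between two diets
#'
#' The aggregate absolute quantity difference relative to total observed
#' intake: `100 * sum(|x_i - o_i|) / sum(o_i)` over the union of items
#' (missing items count as zero). No halving is applied, so removing and
#' replacing mass both count; the measure is 0 iff the diets are identical
#' and can exceed 100%.
#'
#' @param observed,optimized [diet()] objects on the same item universe.
#' @return percentage (non-negative numeric scalar).
#' @export
total_dietary_change <- function(observed, optimized) {
  stopifnot(inherits(observed, "diet"), inherits(optimized, "diet"))
  items <- union(names(observed$quantities), names(optimized$quantities))
  o <- diet_on_items(observed, items)
  x <- diet_on_items(optimized, items)
  denom <- sum(o)
  if (denom <= 0) stop("total observed intake is zero")
  100 * sum(abs(x - o)) / denom
}

#' Diversity and acceptability report for an optimized diet
#'
#' Counts the unique food items retained, the share of observed items driven
#' (essentially) to zero, and the concentration of each food group on its
#' most prevalent item.
#'
#' @param d the optimized [diet()].
#' @param observed the observed [diet()].
#' @param cl a [classification()].
#' @param presence_threshold quantity (g/day) below which an item counts as
#'   absent (default 0.01).
#' @return a list of class `diversity_report`: `n_items` (optimized items
#'   above threshold), `pct_removed` (% of observed items whose optimized
#'   quantity fell below threshold), `avg_max_share` (mean over groups with
#'   positive optimized mass of the largest item share), `per_group_shares`
#'   (named vector of those max shares) and `n_empty_groups` (groups whose
#'   whole mass was removed, excluded from the share average).
#' @export
diversity_report <- function(d, observed, cl, presence_threshold = 0.01) {
  stopifnot(inherits(d, "diet"), inherits(observed, "diet"),
            inherits(cl, "classification"), presence_threshold >= 0)
  items <- union(names(d$quantities), names(observed$quantities))
  x <- diet_on_items(d, items)
  o <- diet_on_items(observed, items)
  present_obs <- names(o)[o > presence_threshold]
  removed <- present_obs[x[present_obs] < presence_threshold]
  pct_removed <- if (length(present_obs)) {
    100 * length(removed) / length(present_obs)
  } else 0
  grp <- cl$assignment[items]
  keep <- !is.na(grp)
  shares <- tapply(x[keep], grp[keep], function(v) {
    tot <- sum(v)
    if (tot > presence_threshold) max(v) / tot else NA_real_
  })
  shares <- stats::setNames(as.numeric(shares), names(shares))
  empty <- sum(is.na(shares))
  shares_ok <- shares[!is.na(shares)]
  structure(list(
    n_items = sum(x > presence_threshold),
    pct_removed = pct_removed,
    avg_max_share = if (length(shares_ok)) mean(shares_ok) else NA_real_,
    per_group_shares = shares_ok,
    n_empty_groups = empty
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report>", x$n_items, "items;",
      sprintf("%.1f%% removed;", x$pct_removed),
      sprintf("avg max share %.2f;", x$avg_max_share),
      x$n_empty_groups, "emptied group(s)\n")
  invisible(x)
}
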