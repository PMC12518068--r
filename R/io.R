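#' @title Food-system file formats
#' @description
#' A food system is persisted as a directory of plain-text tables (UTF-8,
#' dot decimal, header row): `foods.csv`
#' (`item_id,name,energy,fixed,occurrences,<nutrient columns>,ghge`),
#' `nutrients.json` (the panel), `classification_<id>.csv`
#' (`item_id,group_id,group_name`), `diet_<label>.csv`
#' (`item_id,grams_per_day`), `guidelines.json` (one guideline set per
#' label), and optionally `commodity_shares.csv`, `commodity_ghge.csv`
#' (`commodity_id,ghge,unit` with unit `kg_per_g` or `kg_per_kg`) and
#' `loss_factors.csv`. Writing then loading reproduces every value to
#' better than 1e-9 relative error.
#' @name food-system-io
NULL

#' Write a food system to a directory
#'
#' @param system a `food_system`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_food_system <- function(system, dir) {
  validate_food_system(system)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE, quote = TRUE)
  foods <- cbind(system$items[c("item_id", "name", "energy", "fixed",
                                "occurrences")],
                 as.data.frame(system$nutrients[system$items$item_id, ,
                                                drop = FALSE]),
                 ghge = system$items$ghge)
  w(foods, "foods.csv")
  jsonlite::write_json(system$nutrient_defs, file.path(dir, "nutrients.json"),
                       dataframe = "rows", digits = NA, na = "null")
  for (cl in system$classifications) {
    d <- data.frame(item_id = names(cl$assignment),
                    group_id = unname(cl$assignment),
                    group_name = unname(cl$groups[cl$assignment]))
    w(d, paste0("classification_", cl$classification_id, ".csv"))
  }
  for (lab in names(system$diets)) {
    dd <- system$diets[[lab]]
    w(data.frame(item_id = names(dd$quantities),
                 grams_per_day = unname(dd$quantities)),
      paste0("diet_", lab, ".csv"))
  }
  if (length(system$guidelines)) {
    gl <- lapply(system$guidelines, function(gs) {
      list(level = gs$level, micro_target = gs$micro_target,
           macro_energy_bounds = gs$macro_energy,
           macro_mass_bounds = gs$macro_mass,
           micro_refs = gs$micro)
    })
    jsonlite::write_json(gl, file.path(dir, "guidelines.json"),
                         dataframe = "rows", digits = NA, na = "null",
                         auto_unbox = TRUE)
  }
  if (!is.null(system$commodities)) {
    co <- system$commodities
    w(co$shares, "commodity_shares.csv")
    w(cbind(co$ghge, unit = "kg_per_g"), "commodity_ghge.csv")
    w(co$losses, "loss_factors.csv")
  }
  invisible(dir)
}

#' Load a food system from a directory
#'
#' Reads the tables written by [write_food_system()] (or prepared by hand in
#' the same schemas), validating every cross-reference: a diet or
#' classification referencing an unknown `item_id`, or a nutrient column
#' missing from `foods.csv`, is an error naming the offender.
#'
#' @param dir directory containing the files.
#' @return a validated `food_system`.
#' @export
load_food_system <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  foods <- rd("foods.csv")
  defs_raw <- jsonlite::read_json(file.path(dir, "nutrients.json"),
                                  simplifyVector = TRUE)
  defs <- nutrient_defs(defs_raw$nutrient_id, defs_raw$name, defs_raw$unit,
                        defs_raw$kind,
                        if ("atwater" %in% names(defs_raw)) defs_raw$atwater
                        else NA_real_)
  missing_cols <- setdiff(defs$nutrient_id, names(foods))
  if (length(missing_cols))
    stop("foods.csv is missing nutrient column(s): ",
         paste(missing_cols, collapse = ", "))
  nutm <- as.matrix(foods[defs$nutrient_id])
  rownames(nutm) <- foods$item_id
  items <- foods[c("item_id", "name", "energy", "fixed", "occurrences",
                   "ghge")]
  items$fixed <- as.logical(items$fixed)
  cls <- list()
  for (f in list.files(dir, pattern = "^classification_.*\\.csv$")) {
    id <- sub("^classification_(.*)\\.csv$", "\\1", f)
    d <- rd(f)
    groups <- d$group_name[!duplicated(d$group_id)]
    names(groups) <- d$group_id[!duplicated(d$group_id)]
    cls[[id]] <- classification(id, groups,
                                stats::setNames(d$group_id, d$item_id))
  }
  diets <- list()
  for (f in list.files(dir, pattern = "^diet_.*\\.csv$")) {
    lab <- sub("^diet_(.*)\\.csv$", "\\1", f)
    d <- rd(f)
    diets[[lab]] <- diet(stats::setNames(d$grams_per_day, d$item_id), lab)
  }
  guidelines <- list()
  gfile <- file.path(dir, "guidelines.json")
  if (file.exists(gfile)) {
    gl <- jsonlite::read_json(gfile, simplifyVector = TRUE)
    # a zero-row bounds table serializes as [], losing its columns
    fix_bounds <- function(d) {
      d <- as.data.frame(d)
      if (!nrow(d))
        return(data.frame(nutrient_id = character(0), lower = numeric(0),
                          upper = numeric(0)))
      for (col in c("lower", "upper")) {
        d[[col]] <- if (col %in% names(d)) as.numeric(d[[col]]) else NA_real_
      }
      d[c("nutrient_id", "lower", "upper")]
    }
    for (lab in names(gl)) {
      g <- gl[[lab]]
      guidelines[[lab]] <- guideline_set(
        fix_bounds(g$macro_energy_bounds),
        fix_bounds(g$macro_mass_bounds),
        as.data.frame(g$micro_refs),
        level = g$level, micro_target = g$micro_target)
    }
  }
  commodities <- NULL
  if (file.exists(file.path(dir, "commodity_shares.csv"))) {
    gh <- rd("commodity_ghge.csv")
    if (!"unit" %in% names(gh)) gh$unit <- "kg_per_g"
    bad <- !gh$unit %in% c("kg_per_g", "kg_per_kg")
    if (any(bad)) stop("unknown commodity ghge unit: ",
                       paste(unique(gh$unit[bad]), collapse = ", "))
    gh$ghge <- ifelse(gh$unit == "kg_per_kg", gh$ghge / 1000, gh$ghge)
    commodities <- list(shares = rd("commodity_shares.csv"),
                        ghge = gh[c("commodity_id", "ghge")],
                        losses = rd("loss_factors.csv"))
  }
  food_system(items, nutm, defs, classifications = cls, diets = diets,
              guidelines = guidelines, commodities = commodities)
}

#' Write / read a respondent set
#'
#' `respondents.csv` holds the record-level fields and
#' `respondent_intakes.csv` the long per-item intakes.
#'
#' @param respondents a [respondent_set()].
#' @param dir directory.
#' @return `dir` (write) or a `respondent_set` (read).
#' @export
write_respondents <- function(respondents, dir) {
  stopifnot(inherits(respondents, "respondent_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(respondents$info, file.path(dir, "respondents.csv"),
                   row.names = FALSE)
  utils::write.csv(respondents$intakes,
                   file.path(dir, "respondent_intakes.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_respondents
#' @export
read_respondents <- function(dir) {
  respondent_set(
    utils::read.csv(file.path(dir, "respondents.csv"),
                    stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "respondent_intakes.csv"),
                    stringsAsFactors = FALSE))
}
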