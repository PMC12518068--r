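#' Construct a respondent set
#'
#' Dietary-recall respondents with per-item intakes, the raw material from
#' which observed diets are averaged.
#'
#' @param info `data.frame` with columns `respondent_id`, `sex` (`"female"` or
#'   `"male"`), `age` (years), `energy_intake` (kcal/day).
#' @param intakes long `data.frame` with columns `respondent_id`, `item_id`,
#'   `grams_per_day`.
#' @return an object of class `respondent_set`.
#' @export
respondent_set <- function(info, intakes) {
  need <- c("respondent_id", "sex", "age", "energy_intake")
  if (!all(need %in% names(info)))
    stop("info must have columns: ", paste(need, collapse = ", "))
  bad <- !info$sex %in% c("female", "male")
  if (any(bad))
    stop("unknown sex label for respondent(s): ",
         paste(info$respondent_id[bad], collapse = ", "))
  if (any(info$age < 0)) stop("age must be >= 0")
  if (any(info$energy_intake < 0)) stop("energy_intake must be >= 0")
  if (!all(c("respondent_id", "item_id", "grams_per_day") %in% names(intakes)))
    stop("intakes must have columns respondent_id, item_id, grams_per_day")
  stray <- setdiff(intakes$respondent_id, info$respondent_id)
  if (length(stray))
    stop("intakes reference unknown respondent(s): ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(info = info, intakes = intakes), class = "respondent_set")
}

#' Apply the study's respondent inclusion filter
#'
#' Retains adults aged 18 to 65 (inclusive) whose reported energy intake is
#' neither implausibly low (< 1,200 kcal for women, < 1,800 kcal for men) nor
#' implausibly high (> 3,000 kcal for women, > 3,600 kcal for men). Boundary
#' values are retained: exactly 1,200 kcal is not "less than 1,200".
#' Idempotent; record order is preserved.
#'
#' @param respondents a [respondent_set()].
#' @return the filtered `respondent_set`.
#' @export
filter_respondents <- function(respondents) {
  stopifnot(inherits(respondents, "respondent_set"))
  info <- respondents$info
  lo <- ifelse(info$sex == "female", 1200, 1800)
  hi <- ifelse(info$sex == "female", 3000, 3600)
  keep <- info$age >= 18 & info$age <= 65 &
    info$energy_intake >= lo & info$energy_intake <= hi
  kept_ids <- info$respondent_id[keep]
  respondent_set(info[keep, , drop = FALSE],
                 respondents$intakes[
                   respondents$intakes$respondent_id %in% kept_ids, ,
                   drop = FALSE])
}

#' Average per-item intake over respondents of one sex
#'
#' The observed diet of a sex is the arithmetic mean of g/day per food item
#' over that sex's respondents; a respondent who did not report an item
#' contributes zero for it.
#'
#' @param respondents a [respondent_set()].
#' @param sex `"female"` or `"male"`.
#' @return a [diet()] labelled by `sex`.
#' @export
average_diet <- function(respondents, sex) {
  stopifnot(inherits(respondents, "respondent_set"),
            sex %in% c("female", "male"))
  ids <- respondents$info$respondent_id[respondents$info$sex == sex]
  if (!length(ids)) stop("no respondents of sex '", sex, "'")
  ink <- respondents$intakes[respondents$intakes$respondent_id %in% ids, ,
                             drop = FALSE]
  sums <- tapply(ink$grams_per_day, ink$item_id, sum)
  q <- as.numeric(sums) / length(ids)
  diet(stats::setNames(q, names(sums)), label = sex)
}
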