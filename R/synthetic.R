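#' Parameters of the synthetic food-system generator
#'
#' The generator emulates the statistical structure the pipeline assumes in
#' real survey data: a hierarchy of food groups, strong within-group spread of
#' nutrient content and GHGE (log-normal), consumption concentrated on a few
#' items per group (Dirichlet shares), a subset of rarely-reported fixed
#' items, and observed diets that violate a configured set of guidelines
#' (the "bottlenecks") by stated magnitudes.
#'
#' @param n_groups number of fine-level food groups (default 40; the medium
#'   and coarse classifications are nested mergers at roughly 40%/15% of
#'   that count, emulating the 345/153/46-group hierarchy at reduced scale).
#' @param items_per_group integer range, items drawn per group (default 3-8).
#' @param nutrient_sd log-scale within-group dispersion of nutrient content
#'   (default 0.5).
#' @param ghge_sd log-scale within-group dispersion of item GHGE (default
#'   0.6).
#' @param frac_fixed expected fraction of items excluded from optimization
#'   via low reporting occurrences (default 0.08).
#' @param bottleneck_spec named numeric vector of target relative violations
#'   the calibrated (female) observed diet must show. Supported names: any
#'   micronutrient of the default panel (shortfall vs RDA), `fiber`
#'   (shortfall vs the lower bound), `sodium`, `sfa`, `fat` (excess over the
#'   upper bound). Default: iron 30%, vitamin E 25%, fiber 25% short;
#'   sodium 20%, SFA 15%, fat 10% over.
#' @param diet_mass_per_group range of observed group mass in g/day
#'   (default 10-120).
#' @param target_energy calibrated female energy intake in kcal/day
#'   (default 2,000); the male diet scales from it.
#' @param male_mass_factor male group masses relative to female (default 1.3).
#' @param n_commodities size of the shared primary-commodity pool
#'   (default 50).
#' @param max_retries redraw attempts before the generator gives up on
#'   realizing the bottlenecks (default 5).
#' @param seed RNG seed; the same seed always yields a bit-identical system.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_groups = 40, items_per_group = c(3, 8),
                             nutrient_sd = 0.5, ghge_sd = 0.6,
                             frac_fixed = 0.08,
                             bottleneck_spec = c(iron = 0.30, vit_e = 0.25,
                                                 fiber = 0.25, sodium = 0.20,
                                                 sfa = 0.15, fat = 0.10),
                             diet_mass_per_group = c(10, 120),
                             target_energy = 2000, male_mass_factor = 1.3,
                             n_commodities = 50, max_retries = 5, seed = 1) {
  stopifnot(n_groups >= 1, length(items_per_group) == 2,
            items_per_group[1] >= 1,
            items_per_group[2] >= items_per_group[1],
            nutrient_sd >= 0, ghge_sd >= 0,
            frac_fixed >= 0, frac_fixed < 1,
            diet_mass_per_group[1] > 0,
            diet_mass_per_group[2] >= diet_mass_per_group[1],
            target_energy > 0, male_mass_factor > 0, n_commodities >= 1)
  ok <- c("calcium", "folate", "iron", "magnesium", "vit_a", "vit_e",
          "fiber", "sodium", "sfa", "fat")
  if (length(bottleneck_spec)) {
    stopifnot(!is.null(names(bottleneck_spec)),
              all(names(bottleneck_spec) %in% ok),
              all(bottleneck_spec > 0), all(bottleneck_spec < 1))
  }
  structure(list(n_groups = n_groups, items_per_group = items_per_group,
                 nutrient_sd = nutrient_sd, ghge_sd = ghge_sd,
                 frac_fixed = frac_fixed, bottleneck_spec = bottleneck_spec,
                 diet_mass_per_group = diet_mass_per_group,
                 target_energy = target_energy,
                 male_mass_factor = male_mass_factor,
                 n_commodities = n_commodities, max_retries = max_retries,
                 seed = seed),
            class = "generator_params")
}

# lognormal draw with unit mean at dispersion sd (exact mean preserved)
rlnorm1 <- function(n, sd) exp(stats::rnorm(n, -sd^2 / 2, sd))

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

#' Generate a synthetic food system
#'
#' Draws a complete food system (items, compositions, commodity-based
#' footprints, three nested classifications, female and male observed diets,
#' per-sex guideline sets) and calibrates the nutrient composition columns so
#' that the female observed diet violates exactly the configured bottleneck
#' guidelines at their stated magnitudes while meeting all others. Item-level
#' GHGE is realized through a shared commodity pool with loss factors in
#' \[0, 50)%, with per-item weights scaled so the loss-adjusted footprint
#' reproduces the item GHGE exactly.
#'
#' @param params a [generator_params()].
#' @return a validated `food_system`.
#' @export
generate_food_system <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  last_err <- NULL
  for (attempt in seq_len(max(1L, params$max_retries))) {
    set.seed(params$seed + (attempt - 1L) * 7919L)
    sys <- try(generate_once(params), silent = TRUE)
    if (!inherits(sys, "try-error")) return(sys)
    last_err <- attr(sys, "condition")$message
  }
  stop("bottleneck calibration failed after ", params$max_retries,
       " attempts: ", last_err)
}

generate_once <- function(params) {
  defs <- default_nutrient_defs()
  G <- params$n_groups
  npg <- sample(seq(params$items_per_group[1], params$items_per_group[2]),
                G, replace = TRUE)
  n_items <- sum(npg)
  item_id <- sprintf("i%04d", seq_len(n_items))
  fine_grp <- rep(sprintf("f%03d", seq_len(G)), npg)
  # typical per-100g levels before calibration (only dispersion matters; the
  # calibration below rescales every column)
  base <- c(protein = 8, carbohydrate = 20, fat = 8, sfa = 3,
            fiber = 2, sodium = 300, calcium = 80, folate = 40,
            iron = 1.5, magnesium = 30, vit_a = 80, vit_e = 1.5)
  group_sd <- 0.6
  nut <- matrix(0, n_items, length(base),
                dimnames = list(item_id, names(base)))
  for (j in seq_along(base)) {
    gmean <- base[j] * rlnorm1(G, group_sd)
    nut[, j] <- rep(gmean, npg) * rlnorm1(n_items, params$nutrient_sd)
  }
  ghge_gmean <- 0.35 * rlnorm1(G, 0.8)
  ghge <- rep(ghge_gmean, npg) * rlnorm1(n_items, params$ghge_sd)

  occurrences <- ifelse(stats::runif(n_items) < params$frac_fixed,
                        sample(0:3, n_items, replace = TRUE),
                        sample(4:200, n_items, replace = TRUE))
  fixed <- occurrences <= 3

  # observed diets: group mass x Dirichlet(1) shares within group
  draw_diet <- function(mass_factor) {
    masses <- stats::runif(G, params$diet_mass_per_group[1],
                           params$diet_mass_per_group[2]) * mass_factor
    q <- numeric(n_items)
    off <- 0L
    for (g in seq_len(G)) {
      idx <- off + seq_len(npg[g])
      q[idx] <- masses[g] * rdirichlet1(npg[g])
      off <- off + npg[g]
    }
    stats::setNames(q, item_id)
  }
  q_f <- draw_diet(1)
  q_m <- draw_diet(params$male_mass_factor)

  # --- calibrate composition columns against the female diet ---------------
  bn <- params$bottleneck_spec
  E0 <- params$target_energy
  tf <- if ("fat" %in% names(bn)) 35 * (1 + bn[["fat"]]) else 30
  tp <- 16
  tc <- 100 - tp - tf
  if (tc < 45 || tc > 65)
    stop("macro share targets inconsistent: carbohydrate lands at ",
         round(tc, 1), " E%")
  ts <- if ("sfa" %in% names(bn)) 10 * (1 + bn[["sfa"]]) else 8
  w <- q_f / 100  # grams eaten per "per-100g" unit
  raw <- as.numeric(crossprod(nut, w)); names(raw) <- colnames(nut)
  scale_col <- function(nid, target_intake) {
    if (raw[[nid]] <= 0) stop("zero raw intake for ", nid)
    nut[, nid] <<- nut[, nid] * target_intake / raw[[nid]]
  }
  scale_col("protein", tp / 100 * E0 / 4)
  scale_col("carbohydrate", tc / 100 * E0 / 4)
  scale_col("fat", tf / 100 * E0 / 9)
  scale_col("sfa", ts / 100 * E0 / 9)
  fiber_lower <- 14 * E0 / 1000
  scale_col("fiber", fiber_lower *
              (if ("fiber" %in% names(bn)) 1 - bn[["fiber"]] else 1.2))
  scale_col("sodium", 2300 *
              (if ("sodium" %in% names(bn)) 1 + bn[["sodium"]] else 0.8))
  gs_f_ref <- default_guidelines("female", E0)
  for (k in seq_len(nrow(gs_f_ref$micro))) {
    nid <- gs_f_ref$micro$nutrient_id[k]
    rda <- gs_f_ref$micro$rda[k]
    scale_col(nid, rda *
                (if (nid %in% names(bn)) 1 - bn[[nid]] else 1.25))
  }
  energy <- 4 * nut[, "protein"] + 4 * nut[, "carbohydrate"] +
    9 * nut[, "fat"]

  # --- commodity pool, weights scaled for exact footprint consistency ------
  cid <- sprintf("c%03d", seq_len(params$n_commodities))
  com_ghge <- data.frame(commodity_id = cid,
                         ghge = 3e-4 * rlnorm1(params$n_commodities, 0.8))
  losses <- data.frame(commodity_id = cid,
                       loss_pct = stats::runif(params$n_commodities, 0, 50))
  sh_item <- character(0); sh_com <- character(0); sh_w <- numeric(0)
  for (i in seq_len(n_items)) {
    k <- sample(1:4, 1)
    pick <- sample(cid, k)
    wts <- rdirichlet1(k) * stats::runif(1, 30, 95)
    l <- losses$loss_pct[match(pick, cid)]
    g <- com_ghge$ghge[match(pick, cid)]
    fp <- sum(wts * g * 100 / (100 - l))
    wts <- wts * ghge[i] / fp
    sh_item <- c(sh_item, rep(item_id[i], k))
    sh_com <- c(sh_com, pick); sh_w <- c(sh_w, wts)
  }
  commodities <- list(
    shares = data.frame(item_id = sh_item, commodity_id = sh_com,
                        weight_g_per_100g = sh_w),
    ghge = com_ghge, losses = losses)

  # --- nested classifications ----------------------------------------------
  n_med <- max(1L, round(G * 0.4)); n_coa <- max(1L, round(G * 0.15))
  med_of <- ceiling(seq_len(G) * n_med / G)
  coa_of <- ceiling(seq_len(G) * n_coa / G)
  mk_cl <- function(id, gid_of_item, pretty) {
    gids <- sort(unique(gid_of_item))
    classification(id, stats::setNames(paste(pretty, gids), gids),
                   stats::setNames(gid_of_item, item_id))
  }
  fine_cl <- mk_cl("fine", fine_grp, "Fine group")
  med_cl <- mk_cl("medium",
                  sprintf("m%03d", med_of[match(fine_grp,
                                                sprintf("f%03d", seq_len(G)))]),
                  "Medium group")
  coa_cl <- mk_cl("coarse",
                  sprintf("c%02d", coa_of[match(fine_grp,
                                                sprintf("f%03d", seq_len(G)))]),
                  "Coarse group")

  items <- data.frame(item_id = item_id,
                      name = paste0("Food ", item_id, " (", fine_grp, ")"),
                      energy = as.numeric(energy),
                      fixed = fixed,
                      occurrences = as.integer(occurrences),
                      ghge = as.numeric(ghge))
  d_f <- diet(q_f, "female")
  d_m <- diet(q_m, "male")
  sys <- food_system(items, nut, defs,
                     classifications = list(fine = fine_cl, medium = med_cl,
                                            coarse = coa_cl),
                     diets = list(female = d_f, male = d_m),
                     guidelines = list(), commodities = commodities)
  E_m <- diet_profile(d_m, sys)$energy
  sys$guidelines <- list(female = default_guidelines("female", E0),
                         male = default_guidelines("male", E_m))
  check_bottlenecks(sys, params)
  sys
}

# Verify the calibrated (female) diet violates exactly the bottleneck set at
# the stated magnitudes, and nothing else.
check_bottlenecks <- function(sys, params, tol = 1e-6) {
  bn <- params$bottleneck_spec
  gs <- sys$guidelines$female
  prof <- diet_profile(sys$diets$female, sys)
  viol <- c()
  for (k in seq_len(nrow(gs$macro_energy))) {
    b <- gs$macro_energy[k, ]
    v <- prof$energy_shares[[b$nutrient_id]]
    dev <- max(if (!is.na(b$upper)) (v - b$upper) / b$upper else 0,
               if (!is.na(b$lower)) (b$lower - v) / b$lower else 0)
    if (dev > tol) viol[b$nutrient_id] <- dev
  }
  for (k in seq_len(nrow(gs$macro_mass))) {
    b <- gs$macro_mass[k, ]
    v <- prof$totals[[b$nutrient_id]]
    dev <- max(if (!is.na(b$upper)) (v - b$upper) / b$upper else 0,
               if (!is.na(b$lower)) (b$lower - v) / b$lower else 0)
    if (dev > tol) viol[b$nutrient_id] <- dev
  }
  for (k in seq_len(nrow(gs$micro))) {
    r <- gs$micro$rda[k]
    dev <- (r - prof$totals[[gs$micro$nutrient_id[k]]]) / r
    if (dev > tol) viol[gs$micro$nutrient_id[k]] <- dev
  }
  if (!setequal(names(viol), names(bn)))
    stop("bottleneck set not realized; wanted {",
         paste(names(bn), collapse = ","), "} got {",
         paste(names(viol), collapse = ","), "}")
  for (nid in names(bn)) {
    if (abs(viol[[nid]] - bn[[nid]]) > 0.02)
      stop("bottleneck magnitude for ", nid, " is ", round(viol[[nid]], 3),
           ", wanted ", bn[[nid]])
  }
  invisible(TRUE)
}

#' Generate synthetic dietary-recall respondents
#'
#' Respondent ages are uniform on 16-70 and reported energies normal around
#' sex-specific means with tails crossing the study's exclusion cutoffs, so a
#' realistic share of records is filtered out. Item intakes are the target
#' observed diet times independent unit-mean gamma noise, hence the filtered
#' average diet converges to the target as n grows.
#'
#' @param target_diets named list with [diet()]s `female` and `male`.
#' @param n number of respondents.
#' @param seed RNG seed.
#' @param energy_mean,energy_sd named vectors (female/male) of the normal
#'   energy-report distribution, kcal/day.
#' @param noise_shape gamma shape of the per-item intake noise (default 4).
#' @return a [respondent_set()].
#' @export
generate_respondents <- function(target_diets, n, seed = 1,
                                 energy_mean = c(female = 2100, male = 2700),
                                 energy_sd = c(female = 450, male = 450),
                                 noise_shape = 4) {
  stopifnot(n >= 1, all(c("female", "male") %in% names(target_diets)))
  set.seed(seed)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  info <- data.frame(
    respondent_id = sprintf("r%05d", seq_len(n)),
    sex = sex,
    age = sample(16:70, n, replace = TRUE),
    energy_intake = pmax(0, stats::rnorm(n, energy_mean[sex], energy_sd[sex])))
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    tgt <- target_diets[[sex[i]]]$quantities
    noise <- stats::rgamma(length(tgt), shape = noise_shape,
                           rate = noise_shape)
    q <- tgt * noise
    keep <- q > 1e-9
    blocks[[i]] <- data.frame(respondent_id = info$respondent_id[i],
                              item_id = names(tgt)[keep],
                              grams_per_day = unname(q[keep]))
  }
  respondent_set(info, do.call(rbind, blocks))
}

#' Construct an adversarial instance with an analytically known optimum
#'
#' Four constructions exercise the optimizer's corner behavior:
#' \describe{
#' \item{within_swap}{one group, two nutritionally identical items with a
#'   2:1 GHGE gap; the unique optimum shifts all mass to the cleaner item,
#'   cutting GHGE by exactly one third.}
#' \item{between_removal}{three groups; reaching the (aggressive) GHGE cap
#'   under between-group scaling requires removing the dirty group entirely,
#'   while item-level optimization salvages its clean item and needs
#'   strictly less dietary change.}
#' \item{infeasible_cap}{meeting the iron RDA forces a GHGE floor above the
#'   cap; the solver must report infeasibility.}
#' \item{adequacy_vs_ghge}{meeting the iron RDA requires shifting mass onto
#'   a high-GHGE item, so the optimized diet emits more than the observed
#'   one — nutritional adequacy is prioritized over emissions.}
#' }
#'
#' @param kind one of `"within_swap"`, `"between_removal"`,
#'   `"infeasible_cap"`, `"adequacy_vs_ghge"`.
#' @param seed unused by the deterministic constructions; kept for interface
#'   stability.
#' @return a list with `system`, `config` (ready to pass to the matching
#'   solver), `experiment` (1 or 3) and `expected` (a list of analytically
#'   derived facts about the optimum).
#' @export
generate_known_optimum_instance <- function(kind = c("within_swap",
                                                     "between_removal",
                                                     "infeasible_cap",
                                                     "adequacy_vs_ghge"),
                                            seed = 1) {
  kind <- match.arg(kind)
  defs <- nutrient_defs("iron", "Iron", "mg", "micro")
  mk <- function(ids, groups, energy, iron, ghge, q, micro_rda, micro_ear) {
    items <- data.frame(item_id = ids, name = ids, energy = energy,
                        fixed = FALSE, occurrences = 100L, ghge = ghge)
    nutm <- matrix(iron, ncol = 1, dimnames = list(ids, "iron"))
    gs <- guideline_set(
      macro_energy = data.frame(nutrient_id = character(0), lower = numeric(0),
                                upper = numeric(0)),
      macro_mass = data.frame(nutrient_id = character(0), lower = numeric(0),
                              upper = numeric(0)),
      micro = data.frame(nutrient_id = "iron", rda = micro_rda,
                         ear = micro_ear))
    cl <- classification("toy",
                         stats::setNames(paste("Group", unique(groups)),
                                         unique(groups)),
                         stats::setNames(groups, ids))
    food_system(items, nutm, defs, classifications = list(toy = cl),
                diets = list(female = diet(stats::setNames(q, ids), "female")),
                guidelines = list(female = gs))
  }
  switch(kind,
    within_swap = {
      sys <- mk(c("a", "b"), c("g1", "g1"), energy = c(200, 200),
                iron = c(5, 5), ghge = c(1, 2), q = c(50, 50),
                micro_rda = 2, micro_ear = 1.6)
      cfg <- scenario_config("within_only", "toy", allowed_change_pct = 100,
                             item_cap_enabled = FALSE)
      list(system = sys, config = cfg, experiment = 1,
           expected = list(x = c(a = 100, b = 0), ghge = 1.0,
                           ghge_observed = 1.5, ghge_reduction = 1 / 3,
                           d_macro = 0, d_micro = 0))
    },
    between_removal = {
      # dirty group B must vanish under between-group scaling: the required
      # saving (80% of observed GHGE) exceeds what partial scaling of B can
      # give once the clean group C backfills the energy.
      sys <- mk(c("a1", "b1", "b2", "c1"), c("gA", "gB", "gB", "gC"),
                energy = c(200, 200, 200, 200),
                iron = c(5, 5, 5, 5),
                ghge = c(1, 6, 0.5, 0.1),
                q = c(50, 25, 5, 20),
                micro_rda = 2, micro_ear = 1.6)
      cfg <- scenario_config("between_only", "toy",
                             ghge_reduction_target = 0.80)
      list(system = sys, config = cfg, experiment = 3,
           expected = list(removed_group = "gB",
                           ghge_observed = 2.045))
    },
    infeasible_cap = {
      # iron >= 6 mg forces >= 50 g of the dirty item -> GHGE floor 2.0,
      # far above the 30%-reduction cap of 0.98.
      sys <- mk(c("a", "b"), c("g1", "g1"), energy = c(200, 200),
                iron = c(2, 10), ghge = c(1, 3), q = c(80, 20),
                micro_rda = 6, micro_ear = 5)
      cfg <- scenario_config("between_and_within", "toy",
                             ghge_reduction_target = 0.30)
      list(system = sys, config = cfg, experiment = 3,
           expected = list(status = "infeasible", ghge_floor = 2.0,
                           ghge_cap = 0.7 * 1.4))
    },
    adequacy_vs_ghge = {
      # meeting iron (>= 5 mg) needs x_b >= 400/9 g of the dirty item;
      # stage-2 GHGE = 1.1667 kg/day versus 0.65 observed.
      sys <- mk(c("a", "b"), c("g1", "g1"), energy = c(200, 200),
                iron = c(1, 10), ghge = c(0.5, 2), q = c(90, 10),
                micro_rda = 5, micro_ear = 4)
      cfg <- scenario_config("within_only", "toy", allowed_change_pct = 100)
      list(system = sys, config = cfg, experiment = 1,
           expected = list(ghge_observed = 0.65,
                           ghge = (0.5 * (100 - 400 / 9) + 2 * 400 / 9) / 100,
                           x_b = 400 / 9, d_micro = 0))
    })
}
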