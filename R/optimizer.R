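#' Configure an optimization scenario
#'
#' @param mode `"within_only"` (reallocate inside groups, group totals
#'   conserved), `"between_only"` (scale whole groups, within-group
#'   distribution fixed) or `"between_and_within"` (item quantities free).
#' @param classification_id which classification of the food system to use.
#' @param allowed_change_pct within-group change budget in percent of twice
#'   the group mass, so 100 permits full redistribution (default 100).
#' @param item_cap_enabled cap every item at the highest observed average
#'   quantity in its group (default `FALSE`).
#' @param goal_level `"full"` or `"lowered"` (guidelines passed through
#'   [relax_guidelines()]).
#' @param ghge_reduction_target required GHGE reduction as a fraction of the
#'   observed diet footprint (e.g. `0.30`); only used by experiment 3.
#' @param epsilon1,epsilon2 weights of the GHGE and dietary-change terms in
#'   the single weighted solve (`epsilon1 > epsilon2 > 0`); ignored when
#'   `lexicographic = TRUE` except as documentation of priority order.
#' @param epsilon weight of the GHGE tiebreak in experiment 3's weighted form.
#' @param solver_tol tolerance used when locking in stage optima and judging
#'   constraint satisfaction.
#' @param lexicographic solve the prioritized objectives as sequential stages
#'   (default `TRUE`); otherwise one weighted objective is solved.
#' @param energy_band_pct energy intake is constrained to the observed energy
#'   plus/minus this percentage (default 5); without an energy anchor the E%
#'   and GHGE objectives degenerate by shrinking the diet.
#' @param guideline_label which guideline set of the system to use; defaults
#'   to the diet's label, falling back to the first set.
#' @param seed only used by synthetic-data generation, never by the solver.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("within_only", "between_only",
                                     "between_and_within"),
                            classification_id,
                            allowed_change_pct = 100,
                            item_cap_enabled = FALSE,
                            goal_level = c("full", "lowered"),
                            ghge_reduction_target = NULL,
                            epsilon1 = 1e-3, epsilon2 = 1e-6, epsilon = 1e-3,
                            solver_tol = 1e-6, lexicographic = TRUE,
                            energy_band_pct = 5,
                            guideline_label = NULL, seed = NULL) {
  mode <- match.arg(mode)
  goal_level <- match.arg(goal_level)
  stopifnot(allowed_change_pct >= 0, allowed_change_pct <= 100,
            epsilon1 > epsilon2, epsilon2 > 0, epsilon > 0,
            solver_tol > 0, energy_band_pct >= 0)
  if (!is.null(ghge_reduction_target))
    stopifnot(ghge_reduction_target >= 0, ghge_reduction_target < 1)
  structure(list(mode = mode, classification_id = classification_id,
                 allowed_change_pct = allowed_change_pct,
                 item_cap_enabled = item_cap_enabled,
                 goal_level = goal_level,
                 ghge_reduction_target = ghge_reduction_target,
                 epsilon1 = epsilon1, epsilon2 = epsilon2, epsilon = epsilon,
                 solver_tol = solver_tol, lexicographic = lexicographic,
                 energy_band_pct = energy_band_pct,
                 guideline_label = guideline_label, seed = seed),
            class = "scenario_config")
}

# Everything the model builders need, precomputed once per scenario.
# Variable ordering is fixed (sorted item_id within the items table order)
# so repeated runs visit identical bases.
opt_context <- function(system, d, config) {
  stopifnot(inherits(system, "food_system"), inherits(d, "diet"),
            inherits(config, "scenario_config"))
  cl <- system$classifications[[config$classification_id]]
  if (is.null(cl)) stop("unknown classification: ", config$classification_id)
  it <- system$items
  fp <- it$ghge
  if (anyNA(fp)) fp <- system_item_footprints(system)
  names(fp) <- it$item_id
  o_full <- diet_on_items(d, it$item_id)
  opt_ids <- sort(it$item_id[!it$fixed])
  fix_ids <- setdiff(it$item_id, opt_ids)
  per_g <- system$nutrients / 100          # nutrient grams (etc.) per g food
  e_g <- stats::setNames(it$energy / 100, it$item_id)
  g_g <- fp / 100                          # kg CO2eq per g food
  fix_q <- o_full[fix_ids]
  gs <- if (!is.null(config$guideline_label)) {
    system$guidelines[[config$guideline_label]]
  } else if (d$label %in% names(system$guidelines)) {
    system$guidelines[[d$label]]
  } else if (length(system$guidelines)) {
    system$guidelines[[1]]
  } else stop("food system carries no guideline set")
  if (config$goal_level == "lowered" && gs$level == "full")
    gs <- relax_guidelines(gs)
  groups <- cl$assignment[opt_ids]
  profile_obs <- diet_profile(d, system)
  ghge_obs <- sum(o_full * g_g)
  list(system = system, diet = d, config = config, cl = cl, gs = gs,
       opt_ids = opt_ids, fix_ids = fix_ids,
       o = o_full[opt_ids], o_full = o_full,
       groups = groups,
       nut_g = per_g[opt_ids, , drop = FALSE],
       e_g = e_g[opt_ids], g_g = g_g[opt_ids],
       fix_nut = as.numeric(crossprod(per_g[fix_ids, , drop = FALSE],
                                      fix_q)) |>
         stats::setNames(colnames(per_g)),
       fix_energy = sum(e_g[fix_ids] * fix_q),
       fix_ghge = sum(g_g[fix_ids] * fix_q),
       fix_mass = sum(fix_q),
       energy_obs = profile_obs$energy,
       ghge_obs = ghge_obs,
       profile_obs = profile_obs)
}

#' Describe the decision variables of a scenario
#'
#' In `within_only` and `between_and_within` modes each optimizable item gets
#' a quantity variable `x_i` plus non-negative split variables `p_i`, `n_i`
#' with `x_i = o_i + p_i - n_i`, the standard linearization of absolute
#' change; fixed items never appear. In `between_only` mode there is one
#' scale factor `s_g >= 0` per food group (plus split variables around 1), so
#' a group scaled to zero is removed entirely.
#'
#' @param system a `food_system`.
#' @param classification_id classification to build against.
#' @param config a [scenario_config()].
#' @param d observed [diet()] (defaults to the system's first diet).
#' @return a `data.frame` with columns `name`, `kind`
#'   (`quantity`/`increase`/`decrease`/`scale`/`deviation`) and `ref`
#'   (item or group id).
#' @export
build_variables <- function(system, classification_id, config,
                            d = system$diets[[1]]) {
  config$classification_id <- classification_id
  ctx <- opt_context(system, d, config)
  if (config$mode == "between_only") {
    gids <- sort(unique(ctx$groups))
    data.frame(
      name = c(paste0("s_", gids), paste0("u_", gids), paste0("v_", gids)),
      kind = rep(c("scale", "increase", "decrease"), each = length(gids)),
      ref = rep(gids, 3))
  } else {
    ids <- ctx$opt_ids
    vars <- data.frame(
      name = c(paste0("x_", ids), paste0("p_", ids), paste0("n_", ids)),
      kind = rep(c("quantity", "increase", "decrease"), each = length(ids)),
      ref = rep(ids, 3))
    if (is.null(config$ghge_reduction_target)) {
      vars <- rbind(vars, data.frame(name = c("D_macro", "D_micro"),
                                     kind = "deviation", ref = NA))
    }
    vars
  }
}

# --- constraint blocks ------------------------------------------------------

# Deviation-block rows for the goal program (soft = TRUE) or the hard
# guideline rows of experiment 3 (soft = FALSE). `xs` maps item index ->
# variable column for the quantity-like variables; `coef_of` turns a per-item
# coefficient vector into (idx, coef) on the model.
add_guideline_rows <- function(model, ctx, xs_idx, soft,
                               i_dmac = NULL, i_dmic = NULL) {
  gs <- ctx$gs
  defs <- ctx$system$nutrient_defs
  E0 <- ctx$energy_obs
  # helper: diet-level total of nutrient nid as linear fn of the variables:
  # coefficient vector over model columns plus constant from fixed items.
  lin_nut <- function(nid) {
    list(coef = as.numeric(ctx$nut_mat_vars[, nid]),
         const = ctx$fix_nut[[nid]])
  }
  lin_energy <- list(coef = ctx$energy_vars, const = ctx$fix_energy)
  for (k in seq_len(nrow(gs$macro_energy))) {
    b <- gs$macro_energy[k, ]
    a <- defs$atwater[defs$nutrient_id == b$nutrient_id]
    ln <- lin_nut(b$nutrient_id)
    if (!is.na(b$upper)) {
      coef <- 100 * a * ln$coef - b$upper * lin_energy$coef
      rhs <- b$upper * lin_energy$const - 100 * a * ln$const
      if (soft) {
        model <- lp_add_constraint(model, c(xs_idx, i_dmac),
                                   c(coef, -b$upper * E0), "<=", rhs,
                                   paste0("macro_up_", b$nutrient_id))
      } else {
        model <- lp_add_constraint(model, xs_idx, coef, "<=", rhs,
                                   paste0("macro_up_", b$nutrient_id))
      }
    }
    if (!is.na(b$lower)) {
      coef <- b$lower * lin_energy$coef - 100 * a * ln$coef
      rhs <- 100 * a * ln$const - b$lower * lin_energy$const
      if (soft) {
        model <- lp_add_constraint(model, c(xs_idx, i_dmac),
                                   c(coef, -b$lower * E0), "<=", rhs,
                                   paste0("macro_lo_", b$nutrient_id))
      } else {
        model <- lp_add_constraint(model, xs_idx, coef, "<=", rhs,
                                   paste0("macro_lo_", b$nutrient_id))
      }
    }
  }
  for (k in seq_len(nrow(gs$macro_mass))) {
    b <- gs$macro_mass[k, ]
    ln <- lin_nut(b$nutrient_id)
    if (!is.na(b$upper)) {
      if (soft) {
        model <- lp_add_constraint(model, c(xs_idx, i_dmac),
                                   c(ln$coef, -b$upper), "<=",
                                   b$upper - ln$const,
                                   paste0("mass_up_", b$nutrient_id))
      } else {
        model <- lp_add_constraint(model, xs_idx, ln$coef, "<=",
                                   b$upper - ln$const,
                                   paste0("mass_up_", b$nutrient_id))
      }
    }
    if (!is.na(b$lower)) {
      if (soft) {
        model <- lp_add_constraint(model, c(xs_idx, i_dmac),
                                   c(-ln$coef, -b$lower), "<=",
                                   ln$const - b$lower,
                                   paste0("mass_lo_", b$nutrient_id))
      } else {
        model <- lp_add_constraint(model, xs_idx, ln$coef, ">=",
                                   b$lower - ln$const,
                                   paste0("mass_lo_", b$nutrient_id))
      }
    }
  }
  refs <- gs$micro[[gs$micro_target]]
  for (k in seq_len(nrow(gs$micro))) {
    nid <- gs$micro$nutrient_id[k]
    r <- refs[k]
    ln <- lin_nut(nid)
    if (soft) {
      model <- lp_add_constraint(model, c(xs_idx, i_dmic),
                                 c(-ln$coef, -r), "<=", ln$const - r,
                                 paste0("micro_", nid))
    } else {
      model <- lp_add_constraint(model, xs_idx, ln$coef, ">=", r - ln$const,
                                 paste0("micro_", nid))
    }
  }
  model
}

add_energy_band <- function(model, ctx, xs_idx) {
  band <- ctx$config$energy_band_pct / 100
  E0 <- ctx$energy_obs
  coef <- ctx$energy_vars
  model <- lp_add_constraint(model, xs_idx, coef, "<=",
                             (1 + band) * E0 - ctx$fix_energy, "energy_hi")
  lp_add_constraint(model, xs_idx, coef, ">=",
                    (1 - band) * E0 - ctx$fix_energy, "energy_lo")
}

# Item-level model shared by the within-only goal programs (soft guideline
# rows, group conservation + change budget) and experiment 3's
# between_and_within mode (hard guideline rows, GHGE cap, no group rows).
build_item_model <- function(ctx) {
  config <- ctx$config
  soft <- is.null(config$ghge_reduction_target)
  n <- length(ctx$opt_ids)
  if (n == 0L) stop("no optimizable items")
  nv <- 3L * n + if (soft) 2L else 0L
  nm <- c(paste0("x_", ctx$opt_ids), paste0("p_", ctx$opt_ids),
          paste0("n_", ctx$opt_ids),
          if (soft) c("D_macro", "D_micro"))
  model <- lp_model(nv, nm)
  ix <- seq_len(n); ip <- n + ix; im <- 2L * n + ix
  i_dmac <- if (soft) 3L * n + 1L else NULL
  i_dmic <- if (soft) 3L * n + 2L else NULL
  # link x = o + p - n
  for (i in ix) {
    model <- lp_add_constraint(model, c(i, n + i, 2L * n + i), c(1, -1, 1),
                               "=", ctx$o[i], paste0("link_", ctx$opt_ids[i]))
  }
  if (config$mode == "within_only") {
    for (g in sort(unique(ctx$groups))) {
      members <- which(ctx$groups == g)
      mass_g <- sum(ctx$o[members])
      model <- lp_add_constraint(model, members, rep(1, length(members)), "=",
                                 mass_g, paste0("conserve_", g))
      budget <- (config$allowed_change_pct / 100) * 2 * mass_g
      model <- lp_add_constraint(model, c(n + members, 2L * n + members),
                                 rep(1, 2L * length(members)), "<=", budget,
                                 paste0("budget_", g))
      if (config$item_cap_enabled) {
        cap <- max(ctx$o[members])
        for (i in members) {
          model <- lp_add_constraint(model, i, 1, "<=", cap,
                                     paste0("cap_", ctx$opt_ids[i]))
        }
      }
    }
  }
  # coefficient plumbing used by add_guideline_rows / add_energy_band:
  ctx$nut_mat_vars <- ctx$nut_g
  ctx$energy_vars <- ctx$e_g
  model <- add_energy_band(model, ctx, ix)
  model <- add_guideline_rows(model, ctx, ix, soft, i_dmac, i_dmic)
  if (!soft) {
    cap <- (1 - config$ghge_reduction_target) * ctx$ghge_obs
    model <- lp_add_constraint(model, ix, ctx$g_g, "<=", cap - ctx$fix_ghge,
                               "ghge_cap")
  }
  list(model = model, ix = ix, ip = ip, im = im,
       i_dmac = i_dmac, i_dmic = i_dmic)
}

# Group-scale model for experiment 3 between_only mode.
build_group_model <- function(ctx) {
  config <- ctx$config
  gids <- sort(unique(ctx$groups))
  G <- length(gids)
  agg <- function(v) vapply(gids, function(g) sum(v[ctx$groups == g]), 0.0)
  M_g <- agg(ctx$o)
  E_g <- agg(ctx$e_g * ctx$o)
  G_g <- agg(ctx$g_g * ctx$o)
  N_g <- vapply(colnames(ctx$nut_g),
                function(nid) agg(ctx$nut_g[, nid] * ctx$o),
                numeric(G))
  if (is.null(dim(N_g))) N_g <- matrix(N_g, nrow = G,
                                       dimnames = list(NULL, colnames(ctx$nut_g)))
  nv <- 3L * G
  model <- lp_model(nv, c(paste0("s_", gids), paste0("u_", gids),
                          paste0("v_", gids)))
  is_ <- seq_len(G); iu <- G + is_; iv <- 2L * G + is_
  for (k in is_) {
    model <- lp_add_constraint(model, c(k, G + k, 2L * G + k), c(1, -1, 1),
                               "=", 1, paste0("split_", gids[k]))
    model <- lp_add_constraint(model, 2L * G + k, 1, "<=", 1,
                               paste0("vmax_", gids[k]))
  }
  ctx$nut_mat_vars <- N_g
  ctx$energy_vars <- E_g
  model <- add_energy_band(model, ctx, is_)
  model <- add_guideline_rows(model, ctx, is_, soft = FALSE)
  cap <- (1 - config$ghge_reduction_target) * ctx$ghge_obs
  model <- lp_add_constraint(model, is_, G_g, "<=", cap - ctx$fix_ghge,
                             "ghge_cap")
  list(model = model, gids = gids, is_ = is_, iu = iu, iv = iv,
       M_g = M_g, G_g = G_g)
}

# --- result assembly --------------------------------------------------------

make_solve_result <- function(ctx, x_opt, status, objective_stages,
                              stage_status, log, violated = NULL) {
  config <- ctx$config
  if (is.null(x_opt)) {
    return(structure(list(diet = NULL, status = status,
                          d_macro = NA_real_, d_micro = NA_real_,
                          ghge = NA_real_, ghge_reduction = NA_real_,
                          c_within = NULL, c_total = NA_real_,
                          objective_stages = objective_stages,
                          stage_status = stage_status,
                          violated = violated, solver_log = log,
                          config = config), class = "solve_result"))
  }
  q <- ctx$o_full
  x_opt <- pmax(x_opt, 0)
  x_opt[x_opt < ctx$config$solver_tol] <- 0  # snap solver noise, not fixed items
  q[names(x_opt)] <- x_opt
  d_new <- diet(q, label = paste0(ctx$diet$label, "_optimized"))
  prof <- diet_profile(d_new, ctx$system)
  gs <- ctx$gs
  dmac <- macro_deviation(prof, gs)
  dmic <- micro_deviation(prof, gs)
  fp_all <- ctx$system$items$ghge
  if (anyNA(fp_all)) fp_all <- system_item_footprints(ctx$system)
  g_all <- stats::setNames(fp_all / 100, ctx$system$items$item_id)[names(q)]
  ghge <- sum(q * g_all)
  cw <- vapply(sort(unique(ctx$groups)), function(g) {
    members <- ctx$opt_ids[ctx$groups == g]
    mass_g <- sum(ctx$o_full[members])
    if (mass_g <= 0) return(0)
    sum(abs(q[members] - ctx$o_full[members])) / (2 * mass_g)
  }, 0.0)
  structure(list(
    diet = d_new, status = status,
    d_macro = dmac, d_micro = dmic,
    ghge = ghge,
    ghge_reduction = 1 - ghge / ctx$ghge_obs,
    c_within = cw,
    c_total = total_dietary_change(ctx$diet, d_new),
    objective_stages = objective_stages,
    stage_status = stage_status,
    violated = violated, solver_log = log,
    config = config), class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("<solve_result>", x$status)
  if (x$status == "optimal") {
    cat(sprintf(": d_macro %.4f, d_micro %.4f, GHGE %.3f kg/day (%.1f%% vs observed), c_total %.1f%%",
                x$d_macro, x$d_micro, x$ghge, 100 * x$ghge_reduction,
                x$c_total))
  }
  cat("\n")
  invisible(x)
}

# --- experiment drivers -----------------------------------------------------

solve_goal_program <- function(system, d, config) {
  ctx <- opt_context(system, d, config)
  built <- build_item_model(ctx)
  model <- built$model
  n <- length(ctx$opt_ids)
  # stage objectives
  gids <- sort(unique(ctx$groups))
  cw_coef <- numeric(2L * n)
  for (g in gids) {
    members <- which(ctx$groups == g)
    mass_g <- sum(ctx$o[members])
    if (mass_g > 0) {
      cw_coef[members] <- 1 / (2 * mass_g)
      cw_coef[n + members] <- 1 / (2 * mass_g)
    }
  }
  stages <- list(
    list(name = "deviation", idx = c(built$i_dmac, built$i_dmic),
         coef = c(1, 1)),
    list(name = "ghge", idx = built$ix, coef = ctx$g_g,
         constant = ctx$fix_ghge),
    list(name = "c_within", idx = c(built$ip, built$im), coef = cw_coef)
  )
  log <- sprintf("goal program: %d items, %d groups, mode %s, budget %s%%, cap %s, goals %s",
                 n, length(gids), config$mode, config$allowed_change_pct,
                 config$item_cap_enabled, ctx$gs$level)
  if (config$lexicographic) {
    res <- lexicographic_solve(model, stages, tol = config$solver_tol)
    xsol <- if (!is.null(res$x)) res$x[built$ix] else NULL
    if (!is.null(xsol)) names(xsol) <- ctx$opt_ids
    make_solve_result(ctx, xsol, res$status, res$stage_values,
                      res$stage_status, log, res$violated)
  } else {
    ghge_norm <- if (ctx$ghge_obs > 0) ctx$ghge_obs else 1
    obj_idx <- c(built$i_dmac, built$i_dmic, built$ix, built$ip, built$im)
    obj_coef <- c(1, 1, config$epsilon1 * ctx$g_g / ghge_norm,
                  config$epsilon2 * cw_coef / max(1, length(gids)))
    model <- lp_set_objective(model, obj_idx, obj_coef)
    res <- lp_solve(model)
    xsol <- if (!is.null(res$x)) res$x[built$ix] else NULL
    if (!is.null(xsol)) names(xsol) <- ctx$opt_ids
    make_solve_result(ctx, xsol, res$status,
                      c(weighted = res$objval),
                      c(weighted = res$status), log, res$violated)
  }
}

#' Experiment 1: within-food-group goal program under full nutrient goals
#'
#' Reallocates quantities inside each food group (group totals conserved,
#' absolute change limited by the allowed-change budget, optionally capped at
#' the group's highest observed quantity) to lexicographically minimize
#' (1) the largest deviations from the macronutrient and micronutrient (RDA)
#' guidelines, then (2) diet GHGE, then (3) within-group dietary change.
#'
#' @param system a `food_system`.
#' @param d the observed [diet()].
#' @param config a [scenario_config()] with `mode = "within_only"` and
#'   `goal_level = "full"`.
#' @return a `solve_result`.
#' @export
solve_experiment1 <- function(system, d, config) {
  stopifnot(config$mode == "within_only", config$goal_level == "full",
            is.null(config$ghge_reduction_target))
  solve_goal_program(system, d, config)
}

#' Experiment 2: within-food-group goal program under lowered nutrient goals
#'
#' Identical machinery to [solve_experiment1()] after passing the guidelines
#' through [relax_guidelines()]: macronutrient bounds widened by 20% and
#' micronutrient goals lowered from the RDA to the EAR.
#'
#' @inheritParams solve_experiment1
#' @param config a [scenario_config()] with `goal_level = "lowered"`.
#' @return a `solve_result`.
#' @export
solve_experiment2 <- function(system, d, config) {
  stopifnot(config$mode == "within_only", config$goal_level == "lowered",
            is.null(config$ghge_reduction_target))
  solve_goal_program(system, d, config)
}

#' Experiment 3: minimal dietary change under a GHGE cap
#'
#' Finds the diet closest to the observed one (minimal total dietary change,
#' with a small GHGE tiebreak) that meets all macronutrient bounds and
#' micronutrient RDAs as hard constraints and reduces GHGE by at least the
#' configured target. In `between_only` mode whole groups are scaled with the
#' within-group distribution fixed; in `between_and_within` mode item
#' quantities move freely. Infeasibility (the guidelines plus the cap cannot
#' be met) is reported in the result status together with the violated
#' constraint rows, never as an exception.
#'
#' @inheritParams solve_experiment1
#' @param config a [scenario_config()] with `mode` `"between_only"` or
#'   `"between_and_within"` and a `ghge_reduction_target`.
#' @return a `solve_result`.
#' @export
solve_experiment3 <- function(system, d, config) {
  stopifnot(config$mode %in% c("between_only", "between_and_within"),
            !is.null(config$ghge_reduction_target))
  ctx <- opt_context(system, d, config)
  M_tot <- sum(ctx$o_full)
  log <- sprintf("experiment 3: mode %s, target %.0f%% GHGE reduction",
                 config$mode, 100 * config$ghge_reduction_target)
  if (config$mode == "between_only") {
    built <- build_group_model(ctx)
    stages <- list(
      list(name = "c_total", idx = c(built$iu, built$iv),
           coef = rep(built$M_g, 2) / M_tot),
      list(name = "ghge", idx = built$is_, coef = built$G_g,
           constant = ctx$fix_ghge))
    if (config$lexicographic) {
      res <- lexicographic_solve(built$model, stages, tol = config$solver_tol)
    } else {
      model <- lp_set_objective(built$model,
                                c(built$iu, built$iv, built$is_),
                                c(rep(built$M_g, 2) / M_tot,
                                  config$epsilon * built$G_g /
                                    max(ctx$ghge_obs, 1e-9)))
      res <- lp_solve(model)
      res$stage_values <- c(weighted = res$objval)
      res$stage_status <- c(weighted = res$status)
    }
    if (is.null(res$x)) {
      return(make_solve_result(ctx, NULL, res$status, res$stage_values,
                               res$stage_status, log, res$violated))
    }
    s <- res$x[built$is_]
    xsol <- ctx$o * s[match(ctx$groups, built$gids)]
    names(xsol) <- ctx$opt_ids
    make_solve_result(ctx, xsol, res$status, res$stage_values,
                      res$stage_status, log, res$violated)
  } else {
    built <- build_item_model(ctx)
    stages <- list(
      list(name = "c_total", idx = c(built$ip, built$im),
           coef = rep(1 / M_tot, 2 * length(built$ix))),
      list(name = "ghge", idx = built$ix, coef = ctx$g_g,
           constant = ctx$fix_ghge))
    if (config$lexicographic) {
      res <- lexicographic_solve(built$model, stages, tol = config$solver_tol)
    } else {
      model <- lp_set_objective(built$model,
                                c(built$ip, built$im, built$ix),
                                c(rep(1 / M_tot, 2 * length(built$ix)),
                                  config$epsilon * ctx$g_g /
                                    max(ctx$ghge_obs, 1e-9)))
      res <- lp_solve(model)
      res$stage_values <- c(weighted = res$objval)
      res$stage_status <- c(weighted = res$status)
    }
    xsol <- if (!is.null(res$x)) res$x[built$ix] else NULL
    if (!is.null(xsol)) names(xsol) <- ctx$opt_ids
    make_solve_result(ctx, xsol, res$status, res$stage_values,
                      res$stage_status, log, res$violated)
  }
}

#' Export a scenario's linear program in LP file format
#'
#' Builds the model for a scenario without solving it and writes it in the
#' conventional LP text format for inspection with external tools.
#'
#' @param system a `food_system`; @param d observed [diet()];
#' @param config a [scenario_config()]; @param path output file.
#' @return `path`, invisibly.
#' @export
export_scenario_lp <- function(system, d, config, path) {
  ctx <- opt_context(system, d, config)
  built <- if (config$mode == "between_only") build_group_model(ctx)
           else build_item_model(ctx)
  lp_write(built$model, path)
}
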