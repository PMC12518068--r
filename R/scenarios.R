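#' Run an experiment over a scenario grid
#'
#' Sweeps the requested axes (sex, classification, allowed within-group
#' change for experiments 1-2, goal level for experiment 2, optimization mode
#' for experiment 3) and collects one result row per cell. Infeasible or
#' failed cells are recorded with their status, never dropped.
#'
#' @param system a `food_system`.
#' @param experiment 1 (within-group goal program, full goals), 2 (adds the
#'   lowered-goal axis) or 3 (minimal change under a GHGE cap).
#' @param sexes diet labels to run (default: all diets of the system).
#' @param classification_ids classifications to run (default: all).
#' @param allowed_change within-group change budgets in percent
#'   (default `c(0, 25, 50, 75, 100)`; experiments 1-2).
#' @param goal_levels for experiment 2 (default `c("full", "lowered")`).
#' @param modes for experiment 3
#'   (default `c("between_only", "between_and_within")`).
#' @param ghge_reduction_target experiment 3 GHGE cap (default 0.30).
#' @param item_cap_enabled cap items at the group's highest observed
#'   quantity (experiments 1-2; default `FALSE`).
#' @param lexicographic,solver_tol passed to [scenario_config()].
#' @param verbose print one line per cell.
#' @return a `data.frame` with one row per cell: scenario id, axes, solver
#'   status, deviations, GHGE (absolute and relative), total dietary change
#'   and the diversity metrics.
#' @export
run_experiment_grid <- function(system, experiment,
                                sexes = names(system$diets),
                                classification_ids =
                                  names(system$classifications),
                                allowed_change = c(0, 25, 50, 75, 100),
                                goal_levels = c("full", "lowered"),
                                modes = c("between_only",
                                          "between_and_within"),
                                ghge_reduction_target = 0.30,
                                item_cap_enabled = FALSE,
                                lexicographic = TRUE, solver_tol = 1e-6,
                                verbose = FALSE) {
  stopifnot(experiment %in% 1:3)
  cells <- switch(as.character(experiment),
    "1" = expand.grid(sex = sexes, classification_id = classification_ids,
                      allowed_change_pct = allowed_change,
                      goal_level = "full", mode = "within_only",
                      stringsAsFactors = FALSE),
    "2" = expand.grid(sex = sexes, classification_id = classification_ids,
                      allowed_change_pct = allowed_change,
                      goal_level = goal_levels, mode = "within_only",
                      stringsAsFactors = FALSE),
    "3" = expand.grid(sex = sexes, classification_id = classification_ids,
                      allowed_change_pct = 100, goal_level = "full",
                      mode = modes, stringsAsFactors = FALSE))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    tag <- if (experiment == 3) cell$mode else cell$allowed_change_pct
    scenario_id <- paste("scenario", experiment, cell$classification_id,
                         tag, cell$sex, sep = "_")
    if (experiment == 2 && cell$goal_level == "lowered")
      scenario_id <- paste0(scenario_id, "_lowered")
    res <- tryCatch({
      cfg <- scenario_config(
        mode = cell$mode, classification_id = cell$classification_id,
        allowed_change_pct = cell$allowed_change_pct,
        item_cap_enabled = item_cap_enabled,
        goal_level = cell$goal_level,
        ghge_reduction_target =
          if (experiment == 3) ghge_reduction_target else NULL,
        lexicographic = lexicographic, solver_tol = solver_tol)
      d <- system$diets[[cell$sex]]
      r <- switch(as.character(experiment),
                  "1" = solve_experiment1(system, d, cfg),
                  "2" = if (cell$goal_level == "full")
                          solve_experiment1(system, d, cfg)
                        else solve_experiment2(system, d, cfg),
                  "3" = solve_experiment3(system, d, cfg))
      cl <- system$classifications[[cell$classification_id]]
      div <- if (!is.null(r$diet)) diversity_report(r$diet, d, cl) else NULL
      data.frame(scenario_id = scenario_id, experiment = experiment,
                 sex = cell$sex, classification_id = cell$classification_id,
                 allowed_change_pct = cell$allowed_change_pct,
                 goal_level = cell$goal_level, mode = cell$mode,
                 status = r$status,
                 d_macro = r$d_macro, d_micro = r$d_micro,
                 ghge = r$ghge, ghge_reduction = r$ghge_reduction,
                 c_total_pct = r$c_total,
                 stage_deviation =
                   if ("deviation" %in% names(r$objective_stages))
                     unname(r$objective_stages[["deviation"]])
                   else NA_real_,
                 n_items = if (is.null(div)) NA_integer_ else div$n_items,
                 pct_removed =
                   if (is.null(div)) NA_real_ else div$pct_removed,
                 avg_max_share =
                   if (is.null(div)) NA_real_ else div$avg_max_share)
    }, error = function(e) {
      data.frame(scenario_id = scenario_id, experiment = experiment,
                 sex = cell$sex, classification_id = cell$classification_id,
                 allowed_change_pct = cell$allowed_change_pct,
                 goal_level = cell$goal_level, mode = cell$mode,
                 status = paste("error:", conditionMessage(e)),
                 d_macro = NA_real_, d_micro = NA_real_, ghge = NA_real_,
                 ghge_reduction = NA_real_, c_total_pct = NA_real_,
                 stage_deviation = NA_real_, n_items = NA_integer_,
                 pct_removed = NA_real_, avg_max_share = NA_real_)
    })
    if (verbose)
      message(scenario_id, ": ", res$status[1])
    rows[[k]] <- res
  }
  do.call(rbind, rows)
}

#' Write scenario report tables (and optional figures)
#'
#' Writes one CSV per experiment present in `tables` with deterministic
#' naming, so re-rendering identical tables yields byte-identical files.
#'
#' @param tables a result `data.frame` from [run_experiment_grid()], or a
#'   list of them.
#' @param out_dir output directory (created if missing).
#' @param plot also write a bar chart of GHGE reduction (experiments 1-2) or
#'   total dietary change (experiment 3) per cell as a PDF.
#' @return character vector of files written, invisibly.
#' @export
render_reports <- function(tables, out_dir, plot = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  for (tab in tables) {
    exps <- if (nrow(tab)) unique(tab$experiment) else NA_integer_
    for (e in exps) {
      sub <- if (nrow(tab)) tab[tab$experiment %in% e, , drop = FALSE] else tab
      f <- file.path(out_dir,
                     if (is.na(e)) "experiment_empty_report.csv"
                     else sprintf("experiment_%d_report.csv", e))
      utils::write.csv(sub, f, row.names = FALSE)
      written <- c(written, f)
      if (plot && nrow(sub)) {
        pf <- sub(".csv$", ".pdf", f)
        grDevices::pdf(pf, width = 9, height = 5)
        val <- if (!is.na(e) && e == 3) sub$c_total_pct
               else 100 * sub$ghge_reduction
        graphics::par(mar = c(10, 4, 2, 1))
        graphics::barplot(val, names.arg = sub$scenario_id, las = 2,
                          cex.names = 0.6,
                          ylab = if (!is.na(e) && e == 3)
                                   "total dietary change (%)"
                                 else "GHGE reduction (%)")
        grDevices::dev.off()
        written <- c(written, pf)
      }
    }
  }
  invisible(written)
}
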