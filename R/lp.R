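#' @title Small dense linear-programming backend
#'
#' @description
#' The goal programs built by this package are small (a few hundred rows and
#' columns), dense, and must solve deterministically so that repeated runs are
#' bit-identical.  They are handled by a classical two-phase primal simplex on
#' a dense tableau: Dantzig pricing with a switch to Bland's rule after a fixed
#' number of iterations guarantees termination on degenerate bases, and ties in
#' the ratio test are broken by the smallest basis index so the optimal vertex
#' is reproducible.  All variables are non-negative; upper bounds are expressed
#' as explicit rows by the model builders.
#'
#' @name lp-backend
NULL

#' Create an empty linear program
#'
#' @param n_vars number of (non-negative) decision variables.
#' @param var_names optional character vector of variable names, used in the
#'   LP-file export and in infeasibility diagnostics.
#' @return an object of class `lp_model`.
#' @export
lp_model <- function(n_vars, var_names = NULL) {
  stopifnot(n_vars >= 1)
  if (is.null(var_names)) var_names <- paste0("x", seq_len(n_vars))
  stopifnot(length(var_names) == n_vars, !anyDuplicated(var_names))
  structure(list(
    n_vars = as.integer(n_vars),
    var_names = var_names,
    obj = numeric(n_vars),
    obj_const = 0,
    con_idx = list(),   # integer indices per row
    con_coef = list(),  # coefficients per row
    con_sense = character(0),
    con_rhs = numeric(0),
    con_name = character(0)
  ), class = "lp_model")
}

#' Add a linear constraint to a model
#'
#' @param model an `lp_model`.
#' @param idx integer indices of the variables with non-zero coefficients.
#' @param coef coefficients, same length as `idx`.
#' @param sense one of `"<="`, `">="`, `"="`.
#' @param rhs right-hand side.
#' @param name row name used in diagnostics and LP export.
#' @return the updated model.
#' @export
lp_add_constraint <- function(model, idx, coef, sense, rhs, name = NULL) {
  stopifnot(inherits(model, "lp_model"),
            length(idx) == length(coef),
            sense %in% c("<=", ">=", "="),
            is.finite(rhs))
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= model$n_vars))
  k <- length(model$con_rhs) + 1L
  if (is.null(name)) name <- paste0("c", k)
  model$con_idx[[k]] <- idx
  model$con_coef[[k]] <- as.numeric(coef)
  model$con_sense[k] <- sense
  model$con_rhs[k] <- rhs
  model$con_name[k] <- name
  model
}

#' Set the (minimization) objective of a model
#'
#' @param model an `lp_model`.
#' @param idx,coef sparse objective specification.
#' @param constant additive constant reported with the optimum.
#' @return the updated model.
#' @export
lp_set_objective <- function(model, idx, coef, constant = 0) {
  stopifnot(inherits(model, "lp_model"), length(idx) == length(coef))
  obj <- numeric(model$n_vars)
  obj[as.integer(idx)] <- as.numeric(coef)
  model$obj <- obj
  model$obj_const <- constant
  model
}

# Materialize the dense constraint matrix of a model.
lp_dense <- function(model) {
  m <- length(model$con_rhs)
  A <- matrix(0, m, model$n_vars)
  for (k in seq_len(m)) A[k, model$con_idx[[k]]] <- model$con_coef[[k]]
  A
}

#' Solve a linear program
#'
#' Minimizes the model objective subject to its constraints and `x >= 0`.
#'
#' @param model an `lp_model`.
#' @param tol numerical tolerance for pivoting and feasibility (default 1e-9).
#' @return a list with elements `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"tolerance"`), `x` (solution, named by variable),
#'   `objval` (objective value including the model constant) and, when
#'   infeasible, `violated` (names of constraint rows whose phase-1
#'   artificials stayed positive — the binding constraint groups).
#' @export
lp_solve <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "lp_model"))
  A <- lp_dense(model)
  res <- simplex_two_phase(model$obj, A, model$con_sense, model$con_rhs,
                           tol = tol)
  if (!is.null(res$x)) {
    names(res$x) <- model$var_names
    res$objval <- res$objval + model$obj_const
  }
  if (!is.null(res$violated_rows)) {
    res$violated <- model$con_name[res$violated_rows]
  }
  res
}

# Two-phase dense tableau simplex. Minimizes c'x s.t. A x (sense) b, x >= 0.
simplex_two_phase <- function(cvec, A, sense, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # unconstrained non-negative minimization
    if (any(cvec < -tol)) return(list(status = "unbounded", x = NULL, objval = NA_real_))
    return(list(status = "optimal", x = numeric(n), objval = 0))
  }
  row_ids <- seq_len(m)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }
  slack_rows <- which(sense == "<=")
  surp_rows  <- which(sense == ">=")
  art_rows   <- which(sense != "<=")
  n_sl <- length(slack_rows); n_su <- length(surp_rows); n_ar <- length(art_rows)
  N <- n + n_sl + n_su + n_ar
  Tb <- matrix(0, m, N + 1L)
  Tb[, seq_len(n)] <- A
  if (n_sl) Tb[cbind(slack_rows, n + seq_len(n_sl))] <- 1
  if (n_su) Tb[cbind(surp_rows, n + n_sl + seq_len(n_su))] <- -1
  if (n_ar) Tb[cbind(art_rows, n + n_sl + n_su + seq_len(n_ar))] <- 1
  Tb[, N + 1L] <- b
  basis <- integer(m)
  if (n_sl) basis[slack_rows] <- n + seq_len(n_sl)
  if (n_ar) basis[art_rows] <- n + n_sl + n_su + seq_len(n_ar)
  art_cols <- if (n_ar) n + n_sl + n_su + seq_len(n_ar) else integer(0)
  is_art <- logical(N); is_art[art_cols] <- TRUE

  max_iter <- 200L * (m + N)
  bland_after <- 10L * (m + N)

  # One simplex run over the current tableau with cost vector cost (length N).
  run <- function(Tb, basis, cost, allowed) {
    zrow <- cost - as.vector(crossprod(Tb[, seq_len(N), drop = FALSE],
                                       cost[basis]))
    zval <- sum(cost[basis] * Tb[, N + 1L])
    iter <- 0L
    repeat {
      cand <- which(allowed & zrow < -tol)
      if (!length(cand)) return(list(Tb = Tb, basis = basis, objval = zval,
                                     status = "optimal"))
      if (iter > max_iter) return(list(Tb = Tb, basis = basis, objval = zval,
                                       status = "tolerance"))
      j <- if (iter > bland_after) cand[1L] else cand[which.min(zrow[cand])]
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, objval = zval,
                                    status = "unbounded"))
      ratio <- Tb[pos, N + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
      r <- ties[which.min(basis[ties])]
      piv <- Tb[r, j]
      prow <- Tb[r, ] / piv
      colv <- Tb[, j]; colv[r] <- 0
      Tb <- Tb - tcrossprod(colv, prow)
      Tb[r, ] <- prow
      Tb[, j] <- 0; Tb[r, j] <- 1
      zval <- zval + zrow[j] * prow[N + 1L]
      zrow <- zrow - zrow[j] * prow[seq_len(N)]
      zrow[j] <- 0
      basis[r] <- j
      iter <- iter + 1L
    }
  }

  allowed <- !is_art
  if (n_ar) {
    cost1 <- numeric(N); cost1[art_cols] <- 1
    ph1 <- run(Tb, basis, cost1, allowed = rep(TRUE, N))
    if (ph1$status != "optimal" || ph1$objval > 1e-7 * (1 + max(abs(b)))) {
      viol <- row_ids[ph1$basis %in% art_cols & ph1$Tb[, N + 1L] > tol]
      return(list(status = "infeasible", x = NULL, objval = NA_real_,
                  violated_rows = viol))
    }
    Tb <- ph1$Tb; basis <- ph1$basis
    # drive remaining (zero-valued) artificials out of the basis
    keep <- rep(TRUE, m)
    for (r in which(basis %in% art_cols)) {
      pivot_j <- which(!is_art & abs(Tb[r, seq_len(N)]) > tol)[1L]
      if (is.na(pivot_j)) { keep[r] <- FALSE; next }  # redundant row
      piv <- Tb[r, pivot_j]
      prow <- Tb[r, ] / piv
      colv <- Tb[, pivot_j]; colv[r] <- 0
      Tb <- Tb - tcrossprod(colv, prow)
      Tb[r, ] <- prow
      Tb[, pivot_j] <- 0; Tb[r, pivot_j] <- 1
      basis[r] <- pivot_j
    }
    if (!all(keep)) {
      Tb <- Tb[keep, , drop = FALSE]
      basis <- basis[keep]
      m <- nrow(Tb)
    }
  }
  cost2 <- numeric(N); cost2[seq_len(n)] <- cvec
  ph2 <- run(Tb, basis, cost2, allowed = allowed)
  if (ph2$status %in% c("unbounded", "tolerance")) {
    return(list(status = ph2$status, x = NULL, objval = NA_real_))
  }
  x <- numeric(n)
  str_basic <- ph2$basis <= n
  x[ph2$basis[str_basic]] <- ph2$Tb[str_basic, N + 1L]
  x[abs(x) < tol] <- 0
  list(status = "optimal", x = x, objval = ph2$objval)
}

#' Solve a sequence of prioritized objectives lexicographically
#'
#' Stage `k + 1` is solved subject to all original constraints plus
#' `objective_k <= optimum_k * (1 + tol) + tol`, so each achieved optimum is
#' (numerically) locked in before the next objective is considered.
#'
#' @param model an `lp_model` (its own objective is ignored).
#' @param stages a list of stage objectives, each a list with elements `idx`,
#'   `coef` and optionally `constant` and `name`.
#' @param tol relative/absolute slack allowed when fixing a stage optimum
#'   (default `1e-7`).
#' @return a list with `status`, `x` (solution of the last solved stage),
#'   `stage_values` (named numeric of per-stage optima, constants included),
#'   `stage_status` (per-stage solver status) and, on failure, `failed_stage`.
#' @export
lexicographic_solve <- function(model, stages, tol = 1e-7) {
  stopifnot(inherits(model, "lp_model"), length(stages) >= 1, tol > 0)
  stage_values <- numeric(0)
  stage_status <- character(0)
  res <- NULL
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    nm <- if (!is.null(st$name)) st$name else paste0("stage", k)
    konst <- if (!is.null(st$constant)) st$constant else 0
    model <- lp_set_objective(model, st$idx, st$coef, constant = konst)
    res <- lp_solve(model)
    stage_status[nm] <- res$status
    if (res$status != "optimal") {
      return(list(status = res$status, x = res$x,
                  stage_values = stage_values, stage_status = stage_status,
                  failed_stage = k, violated = res$violated))
    }
    stage_values[nm] <- res$objval
    raw_opt <- res$objval - konst
    model <- lp_add_constraint(model, st$idx, st$coef, "<=",
                               raw_opt * (1 + sign(raw_opt) * tol) + tol,
                               name = paste0("lex_", nm))
  }
  list(status = "optimal", x = res$x, stage_values = stage_values,
       stage_status = stage_status)
}

#' Export a model in LP file format
#'
#' Writes the model in the conventional CPLEX LP text format for inspection
#' with external tools.
#'
#' @param model an `lp_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
lp_write <- function(model, path) {
  stopifnot(inherits(model, "lp_model"))
  term <- function(idx, coef) {
    keep <- coef != 0
    if (!any(keep)) return("0")
    paste(sprintf("%+.12g %s", coef[keep], model$var_names[idx[keep]]),
          collapse = " ")
  }
  lines <- c("Minimize",
             paste0(" obj: ", term(seq_len(model$n_vars), model$obj)),
             "Subject To")
  sym <- c("<=" = "<=", ">=" = ">=", "=" = "=")
  for (k in seq_along(model$con_rhs)) {
    lines <- c(lines, sprintf(" %s: %s %s %.12g", model$con_name[k],
                              term(model$con_idx[[k]], model$con_coef[[k]]),
                              sym[[model$con_sense[k]]], model$con_rhs[k]))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}
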