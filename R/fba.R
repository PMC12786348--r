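# Flux balance analysis and friends, on top of the built-in simplex.
#
# assemble_lp() lowers a model + constraint_set to one LP:
#   columns  = reaction fluxes, then auxiliary columns for group caps,
#   equality = S v = 0, ratio pins, split-variable definitions,
#   inequality = consumer-overestimator rows and the cap rows themselves.

assemble_lp <- function(model, constraints = NULL) {
  rx <- model$reactions
  n <- nrow(rx)
  lb <- rx$lb; ub <- rx$ub
  vnames <- rx$id
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    bo <- constraints$bounds
    for (i in seq_len(nrow(bo))) {
      j <- match(bo$reaction[i], rx$id)
      if (is.na(j)) stop("bound override for unknown reaction: ", bo$reaction[i])
      if (!is.na(bo$lb[i])) lb[j] <- bo$lb[i]
      if (!is.na(bo$ub[i])) ub[j] <- bo$ub[i]
    }
    fx <- constraints$fixed
    for (i in seq_len(nrow(fx))) {
      j <- match(fx$reaction[i], rx$id)
      if (is.na(j)) stop("fixed flux for unknown reaction: ", fx$reaction[i])
      if (fx$value[i] < lb[j] - 1e-9 || fx$value[i] > ub[j] + 1e-9) {
        stop("fixed flux for '", fx$reaction[i], "' (", fx$value[i],
             ") lies outside its declared bounds [", lb[j], ", ", ub[j], "]")
      }
      lb[j] <- fx$value[i]; ub[j] <- fx$value[i]
    }
  }
  Aeq <- as.matrix(model$stoich)
  beq <- rep(0, nrow(Aeq))
  Ale <- matrix(0, 0, n); ble <- numeric(0)

  grow <- function(M, extra) cbind(M, matrix(0, nrow(M), extra))

  if (!is.null(constraints)) {
    for (i in seq_len(nrow(constraints$ratios))) {
      r <- constraints$ratios[i, ]
      ja <- match(r$rxn_a, rx$id); jb <- match(r$rxn_b, rx$id)
      if (is.na(ja) || is.na(jb)) stop("ratio pin references unknown reaction")
      row <- rep(0, ncol(Aeq)); row[ja] <- r$b; row[jb] <- -r$a
      Aeq <- rbind(Aeq, row); beq <- c(beq, 0)
    }
    for (cap in constraints$group_caps) {
      wt <- function(r, sgn) {
        if (is.null(cap$metabolite)) return(1)
        w <- sgn * as.numeric(model$stoich[cap$metabolite, r])
        # reactions not touching the capped metabolite (e.g. terminal route
        # steps feeding the precursor pool) count as plain flux
        if (w == 0) return(1)
        if (w < 0) stop("reaction '", r, "' does not ",
                        if (sgn < 0) "consume" else "produce",
                        " metabolite '", cap$metabolite, "'")
        w
      }
      caprow <- rep(0, ncol(Aeq))
      for (r in cap$consumers) {
        j <- match(r, rx$id)
        if (is.na(j)) stop("group cap references unknown reaction: ", r)
        w <- wt(r, -1)
        if (lb[j] >= 0) {
          caprow[j] <- caprow[j] + w  # irreversible: positive part is w*v
        } else {
          # aux p >= w*v, p >= 0; p overestimates but is driven down when
          # the cap binds, so the cap is exact at the optimum
          Aeq <- grow(Aeq, 1); Ale <- grow(Ale, 1); caprow <- c(caprow, 1)
          lb <- c(lb, 0); ub <- c(ub, Inf)
          vnames <- c(vnames, paste0(".pos_", r))
          row <- rep(0, ncol(Ale)); row[j] <- w; row[length(row)] <- -1
          Ale <- rbind(Ale, row); ble <- c(ble, 0)
        }
      }
      cap_rhs <- 0
      if (!is.null(cap$rhs_value)) {
        # frozen reference: consumption <= delta * initial production
        cap_rhs <- cap$delta * cap$rhs_value
      } else {
        for (r in cap$producers) {
          j <- match(r, rx$id)
          if (is.na(j)) stop("group cap references unknown reaction: ", r)
          w <- wt(r, +1)
          if (lb[j] >= 0) {
            caprow[j] <- caprow[j] - cap$delta * w
          } else {
            # split w*v = q - s with q, s >= 0 (LP relaxation for reversible
            # producers; exact whenever the split is not inflated)
            Aeq <- grow(Aeq, 2); Ale <- grow(Ale, 2)
            caprow <- c(caprow, -cap$delta, 0)
            lb <- c(lb, 0, 0); ub <- c(ub, Inf, Inf)
            vnames <- c(vnames, paste0(".q_", r), paste0(".s_", r))
            row <- rep(0, ncol(Aeq)); row[j] <- w
            row[length(row) - 1] <- -1; row[length(row)] <- 1
            Aeq <- rbind(Aeq, row); beq <- c(beq, 0)
          }
        }
      }
      Ale <- rbind(Ale, caprow); ble <- c(ble, cap_rhs)
    }
  }
  list(Aeq = Aeq, beq = beq, Ale = Ale, ble = ble, lb = lb, ub = ub,
       vnames = vnames, n_rxn = n)
}

lp_objective <- function(lp, weights) {
  obj <- rep(0, length(lp$lb))
  idx <- match(names(weights), lp$vnames[seq_len(lp$n_rxn)])
  if (anyNA(idx)) stop("objective references unknown reaction: ",
                       paste(names(weights)[is.na(idx)], collapse = ", "))
  obj[idx] <- as.numeric(weights)
  obj
}

as_flux_state <- function(lp, sol, model, objective_value = sol$objective) {
  if (sol$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = sol$status), class = "flux_state"))
  }
  v <- stats::setNames(sol$x[seq_len(lp$n_rxn)], lp$vnames[seq_len(lp$n_rxn)])
  structure(list(fluxes = v, objective_value = objective_value,
                 status = "optimal"), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state>", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

normalize_objective <- function(model, objective) {
  if (is.null(objective)) {
    if (!length(model$objective)) stop("model has no objective; pass one explicitly")
    return(model$objective)
  }
  if (is.character(objective)) return(stats::setNames(rep(1, length(objective)), objective))
  stopifnot(is.numeric(objective), !is.null(names(objective)))
  objective
}

#' Flux balance analysis
#'
#' Maximizes the objective over the steady-state flux polytope
#' `S v = 0`, `lb <= v <= ub`, plus whatever the constraint set adds.
#'
#' @param model a `cb_model`.
#' @param constraints a `constraint_set` or `NULL`.
#' @param objective named weight vector, a character vector of reaction ids
#'   (weight 1 each), or `NULL` for the model's stored objective.
#' @param maximize direction (default maximize).
#' @return a `flux_state`: `fluxes` (named vector), `objective_value`,
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @export
fba <- function(model, constraints = NULL, objective = NULL, maximize = TRUE) {
  lp <- assemble_lp(model, constraints)
  w <- normalize_objective(model, objective)
  sol <- solve_lp(lp_objective(lp, w), lp$Aeq, lp$beq, lp$Ale, lp$ble,
                  lp$lb, lp$ub, maximize = maximize)
  as_flux_state(lp, sol, model)
}

#' Parsimonious baseline flux distribution
#'
#' Runs FBA, fixes the objective at its optimum, and minimizes the total
#' absolute flux over the reaction columns. The L1 step removes the
#' degeneracy of raw FBA, giving a reproducible single baseline (the solver
#' is deterministic, so repeated calls return identical vectors).
#'
#' @inheritParams fba
#' @return a `flux_state`; `objective_value` is the FBA optimum.
#' @export
baseline_flux <- function(model, constraints = NULL, objective = NULL) {
  w <- normalize_objective(model, objective)
  first <- fba(model, constraints, w)
  if (first$status != "optimal") return(first)
  lp <- assemble_lp(model, constraints)
  nv <- length(lp$lb); n <- lp$n_rxn
  # columns [x, p], p_i >= |x_i|
  Aeq <- cbind(lp$Aeq, matrix(0, nrow(lp$Aeq), n))
  objrow <- c(lp_objective(lp, w), rep(0, n))
  Aeq <- rbind(Aeq, objrow)
  beq <- c(lp$beq, first$objective_value)
  Ale <- cbind(lp$Ale, matrix(0, nrow(lp$Ale), n))
  # x_i - p_i <= 0 and -x_i - p_i <= 0
  for (i in seq_len(n)) {
    r1 <- rep(0, nv + n); r1[i] <- 1; r1[nv + i] <- -1
    r2 <- rep(0, nv + n); r2[i] <- -1; r2[nv + i] <- -1
    Ale <- rbind(Ale, r1, r2)
  }
  ble <- c(lp$ble, rep(0, 2 * n))
  obj <- c(rep(0, nv), rep(1, n))
  sol <- solve_lp(obj, Aeq, beq, Ale, ble,
                  lb = c(lp$lb, rep(0, n)),
                  ub = c(lp$ub, rep(Inf, n)), maximize = FALSE)
  if (sol$status != "optimal") {
    stop("parsimonious step failed with status '", sol$status, "'")
  }
  v <- stats::setNames(sol$x[seq_len(n)], lp$vnames[seq_len(n)])
  structure(list(fluxes = v, objective_value = first$objective_value,
                 status = "optimal"), class = "flux_state")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective staying at
#' or above `fraction` of its optimum (the objective row is omitted when the
#' model has no objective or `fraction <= 0`, giving the pure feasibility
#' polytope).
#'
#' @inheritParams fba
#' @param fraction fraction of the optimum in `(0, 1]`, or `0` for pure
#'   feasibility.
#' @param reactions reaction ids to analyze (default: all).
#' @param keep_solutions also return the argmin/argmax flux vectors (used as
#'   sampler warmup points).
#' @return a `fva_result`: data.frame `reaction`, `min`, `max` with attributes
#'   `fraction` and (optionally) `solutions`.
#' @export
fva <- function(model, constraints = NULL, fraction = 1.0, objective = NULL,
                reactions = NULL, keep_solutions = FALSE) {
  lp <- assemble_lp(model, constraints)
  use_obj <- fraction > 0 && (length(model$objective) || !is.null(objective))
  Ale <- lp$Ale; ble <- lp$ble
  if (use_obj) {
    if (fraction > 1) stop("fraction must lie in (0, 1]")
    w <- normalize_objective(model, objective)
    first <- fba(model, constraints, w)
    if (first$status != "optimal") {
      stop("FVA requires a feasible model; FBA status was '", first$status,
           "' under the supplied constraint set")
    }
    objrow <- lp_objective(lp, w)
    Ale <- rbind(Ale, -objrow)
    ble <- c(ble, -fraction * first$objective_value)
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  res <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  sols <- if (keep_solutions) vector("list", 2L * length(reactions)) else NULL
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], lp$vnames)
    if (is.na(j)) stop("FVA: unknown reaction '", reactions[k], "'")
    e <- rep(0, length(lp$lb)); e[j] <- 1
    lo <- solve_lp(e, lp$Aeq, lp$beq, Ale, ble, lp$lb, lp$ub, maximize = FALSE)
    hi <- solve_lp(e, lp$Aeq, lp$beq, Ale, ble, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA solve failed for '", reactions[k], "' (status ",
           lo$status, "/", hi$status, ") under the supplied constraint set")
    }
    res$min[k] <- lo$objective; res$max[k] <- hi$objective
    if (keep_solutions) { sols[[2 * k - 1]] <- lo$x; sols[[2 * k]] <- hi$x }
  }
  attr(res, "fraction") <- if (use_obj) fraction else 0
  if (keep_solutions) attr(res, "solutions") <- sols
  class(res) <- c("fva_result", "data.frame")
  res
}

#' Multi-objective specification
#'
#' @param reactions reaction ids, in priority order for lexicographic mode.
#' @param mode `"lexicographic"` (default: optimize in order, fixing each
#'   term at `slack` times its optimum before the next) or `"weighted"`
#'   (maximize the weighted sum of fluxes normalized by their standalone
#'   optima).
#' @param weights weights for weighted mode (default equal).
#' @param slack lexicographic slack in `(0, 1]` (default `0.999`).
#' @return an `objective_spec`.
#' @export
objective_spec <- function(reactions, mode = c("lexicographic", "weighted"),
                           weights = rep(1, length(reactions)), slack = 0.999) {
  mode <- match.arg(mode)
  stopifnot(length(reactions) >= 1, length(weights) == length(reactions),
            all(is.finite(weights)), slack > 0, slack <= 1)
  structure(list(reactions = reactions, mode = mode, weights = weights,
                 slack = slack), class = "objective_spec")
}

#' Multi-objective flux balance analysis
#'
#' Implements "simultaneously maximizing" several reactions either
#' lexicographically (maintain each higher-priority optimum within a slack,
#' then optimize the next term) or as a weighted sum of optima-normalized
#' fluxes `sum_i w_i v_i / opt_i`.
#'
#' @inheritParams fba
#' @param objective an [objective_spec()] with at least 2 terms.
#' @return a `flux_state`; attribute `"term_optima"` holds each term's
#'   standalone (lexicographic: sequential) optimum.
#' @export
optimize_multi <- function(model, constraints = NULL, objective) {
  stopifnot(inherits(objective, "objective_spec"))
  if (length(objective$reactions) < 2) {
    stop("multi-objective optimization needs at least two terms")
  }
  lp <- assemble_lp(model, constraints)
  term_opt <- numeric(0)
  if (objective$mode == "weighted") {
    for (r in objective$reactions) {
      st <- fba(model, constraints, r)
      if (st$status != "optimal") return(st)
      if (abs(st$objective_value) < 1e-12) {
        stop("weighted multi-objective: standalone optimum of '", r,
             "' is 0, normalization undefined; use lexicographic mode or ",
             "rescale the term")
      }
      term_opt[r] <- st$objective_value
    }
    w <- stats::setNames(objective$weights / term_opt, objective$reactions)
    sol <- solve_lp(lp_objective(lp, w), lp$Aeq, lp$beq, lp$Ale, lp$ble,
                    lp$lb, lp$ub, maximize = TRUE)
    out <- as_flux_state(lp, sol, model)
  } else {
    Ale <- lp$Ale; ble <- lp$ble
    sol <- NULL
    for (r in objective$reactions) {
      e <- lp_objective(lp, stats::setNames(1, r))
      sol <- solve_lp(e, lp$Aeq, lp$beq, Ale, ble, lp$lb, lp$ub, maximize = TRUE)
      if (sol$status != "optimal") {
        return(as_flux_state(lp, sol, model))
      }
      term_opt[r] <- sol$objective
      thr <- sol$objective - (1 - objective$slack) * abs(sol$objective)
      Ale <- rbind(Ale, -e); ble <- c(ble, -thr)
    }
    out <- as_flux_state(lp, sol, model,
                         objective_value = term_opt[[length(term_opt)]])
  }
  attr(out, "term_optima") <- term_opt
  out
}

#' Check the steady-state invariants of a flux state
#' @param model a `cb_model`.
#' @param state a `flux_state`.
#' @param tol mass-balance tolerance.
#' @return `TRUE` invisibly; errors with the violating metabolite otherwise.
#' @export
check_steady_state <- function(model, state, tol = 1e-6) {
  stopifnot(state$status == "optimal")
  resid <- as.numeric(model$stoich %*% state$fluxes[model$reactions$id])
  bad <- which(abs(resid) > tol)
  if (length(bad)) {
    stop("mass balance violated at: ",
         paste(model$metabolites$id[bad], collapse = ", "))
  }
  invisible(TRUE)
}
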