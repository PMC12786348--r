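# In-silico interventions: graded knockdown of branch reactions and
# expression-scaled overexpression sweeps of downstream steps.

#' Graded knockdown of target reactions
#'
#' Determines a parsimonious baseline flux under the supplied constraints and
#' multi-objective, then, for each inhibition factor `k`, divides the targets'
#' baseline fluxes by `k` and uses the result as new bounds (both directions
#' for reversible targets), re-solving the multi-objective program each time.
#' Fold-changes are reported relative to the factor-1 row, so the uninhibited
#' fold-change is exactly 1.
#'
#' @inheritParams fba
#' @param targets reaction ids to inhibit jointly (e.g. `c("DMATT", "GRTT")`).
#' @param product reaction id whose flux is the product readout (a secretion
#'   exchange, e.g. `"EX_CS_OH"`).
#' @param factors inhibition factors; 1 is prepended when absent.
#' @param objective an [objective_spec()]; default: lexicographic biomass
#'   (model objective) first, `product` second.
#' @param flux_sum_of optional metabolite id: additionally record its
#'   production flux-sum per row (the "total flux" reading of the product).
#' @return a `knockdown_curve` data.frame: one row per factor with applied
#'   bounds, biomass flux, product flux (`flux_cs`), `fold_change`, `status`.
#'   Attributes: `baseline` (the factor-1 `flux_state`), `targets`, `product`.
#' @export
simulate_knockdown <- function(model, constraints = NULL,
                               targets = c("DMATT", "GRTT"),
                               product = "EX_CS_OH",
                               factors = 2^(0:8),
                               objective = NULL,
                               flux_sum_of = NULL) {
  stopifnot(all(targets %in% model$reactions$id),
            product %in% model$reactions$id,
            all(factors > 0))
  if (!any(factors == 1)) factors <- c(1, factors)
  factors <- sort(unique(factors))
  if (is.null(objective)) {
    if (!length(model$objective)) stop("model has no objective to maximize")
    objective <- objective_spec(c(names(model$objective)[1], product))
  }
  biomass_rxn <- objective$reactions[1]
  base <- baseline_flux(model, constraints,
                        stats::setNames(1, biomass_rxn))
  if (base$status != "optimal") {
    stop("baseline solve failed with status '", base$status, "'")
  }
  base_v <- base$fluxes[targets]
  degenerate <- all(abs(base_v) < 1e-9)
  rows <- lapply(factors, function(k) {
    bnds <- do.call(rbind, lapply(targets, function(tg) {
      v <- base$fluxes[[tg]]
      lb0 <- model$reactions$lb[match(tg, model$reactions$id)]
      data.frame(reaction = tg,
                 lb = if (lb0 < 0) -abs(v) / k else 0,
                 ub = abs(v) / k, stringsAsFactors = FALSE)
    }))
    cs <- merge_constraints(constraints, constraint_set(bounds = bnds))
    st <- optimize_multi(model, cs, objective)
    if (st$status != "optimal") {
      return(data.frame(factor = k, bound = NA_real_, biomass = NA_real_,
                        flux_cs = NA_real_, flux_sum = NA_real_,
                        status = st$status, stringsAsFactors = FALSE))
    }
    data.frame(factor = k, bound = max(bnds$ub),
               biomass = st$fluxes[[biomass_rxn]],
               flux_cs = st$fluxes[[product]],
               flux_sum = if (is.null(flux_sum_of)) NA_real_ else
                 flux_sum(model, st, flux_sum_of),
               status = "optimal", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref <- out$flux_cs[out$factor == 1]
  out$fold_change <- if (length(ref) == 1 && !is.na(ref) && abs(ref) > 0) {
    out$flux_cs / ref
  } else NA_real_
  class(out) <- c("knockdown_curve", "data.frame")
  attr(out, "baseline") <- base
  attr(out, "targets") <- targets
  attr(out, "product") <- product
  attr(out, "degenerate") <- degenerate
  if (degenerate) {
    warning("baseline flux through the target reactions is 0; ",
            "knockdown is degenerate")
  }
  out
}

#' Yield-improvement ratios of a knockdown curve
#'
#' @param curve a `knockdown_curve`.
#' @return data.frame `factor`, `ratio`; attributes `max_ratio` and
#'   `best_factor`. When the uninhibited product flux is 0 the ratios are a
#'   sentinel `NA` (no division is performed) and a warning is raised.
#' @export
yield_improvement <- function(curve) {
  stopifnot(inherits(curve, "knockdown_curve"))
  ref <- curve$flux_cs[curve$factor == 1]
  out <- data.frame(factor = curve$factor, ratio = NA_real_)
  if (length(ref) != 1 || is.na(ref) || ref <= 0) {
    warning("uninhibited product flux is 0; yield ratio undefined")
    attr(out, "max_ratio") <- NA_real_
    attr(out, "best_factor") <- NA_real_
    return(out)
  }
  out$ratio <- curve$flux_cs / ref
  ok <- !is.na(out$ratio)
  attr(out, "max_ratio") <- max(out$ratio[ok])
  attr(out, "best_factor") <- out$factor[ok][which.max(out$ratio[ok])]
  out
}

#' Initial maximal-rate ratio of two enzymes
#'
#' `RVmax = (kcat_1 * EXP_1) / (kcat_2 * EXP_2)` — the theta and unit factors
#' shared by both Vmax values cancel.
#'
#' @param kcat1,kcat2 turnover numbers (1/s).
#' @param exp1,exp2 expression levels (TPM).
#' @return the ratio (0 when the numerator expression is 0).
#' @export
rvmax_ratio <- function(kcat1, kcat2, exp1, exp2) {
  den <- kcat2 * exp2
  if (!is.finite(den) || den <= 0) {
    stop("RVmax denominator kcat2 * EXP2 must be positive")
  }
  (kcat1 * exp1) / den
}

#' Overexpression sweep of two downstream reactions
#'
#' Scales the upper bounds of reactions `f1` and `f2` to `n * f1_base` and
#' `n * f2_base` over a grid of factors and records the product flux per
#' cell. The base bounds encode the initial expression-scaled maximal rates
#' (their ratio is RVmax); the sweep itself explores the landscape with the
#' ratio constraint released. Modes: vary `f1` only, `f2` only, or both
#' (full grid).
#'
#' @inheritParams fba
#' @param f1,f2 reaction ids (alcohol- and aldehyde-dehydrogenase steps).
#' @param f1_base,f2_base base upper bounds; default: the reactions' current
#'   upper bounds (finite and positive required).
#' @param n_grid scaling factors (default `c(1, 2, 4, 8, 16, 32)`).
#' @param product product readout reaction id.
#' @param objective an [objective_spec()]; default lexicographic: model
#'   objective first, `product` second.
#' @param mode `"both"` (full grid), `"f1_only"` or `"f2_only"`.
#' @return an `oe_surface`: list with `grid` (matrix of product fluxes,
#'   rows = f1 factors, cols = f2 factors), `f1_curve`, `f2_curve`,
#'   `joint_curve` (diagonal), `rvmax`, `n_grid`, ids.
#' @export
sweep_overexpression <- function(model, constraints = NULL, f1, f2,
                                 f1_base = NULL, f2_base = NULL,
                                 n_grid = c(1, 2, 4, 8, 16, 32),
                                 product = NULL, objective = NULL,
                                 mode = c("both", "f1_only", "f2_only")) {
  mode <- match.arg(mode)
  stopifnot(all(c(f1, f2) %in% model$reactions$id), length(n_grid) >= 1)
  rx <- model$reactions
  if (is.null(f1_base)) f1_base <- rx$ub[match(f1, rx$id)]
  if (is.null(f2_base)) f2_base <- rx$ub[match(f2, rx$id)]
  if (!is.finite(f1_base) || !is.finite(f2_base) || f1_base <= 0 || f2_base <= 0) {
    stop("base bounds for f1 and f2 must be finite and positive")
  }
  if (is.null(product)) {
    stop("supply the product readout reaction id")
  }
  if (is.null(objective)) {
    if (!length(model$objective)) stop("model has no objective")
    objective <- objective_spec(c(names(model$objective)[1], product))
  }
  n_grid <- sort(unique(n_grid))
  cell <- function(n1, n2) {
    cs <- merge_constraints(constraints, constraint_set(bounds = data.frame(
      reaction = c(f1, f2), lb = c(0, 0),
      ub = c(n1 * f1_base, n2 * f2_base), stringsAsFactors = FALSE)))
    st <- optimize_multi(model, cs, objective)
    if (st$status != "optimal") NA_real_ else st$fluxes[[product]]
  }
  g <- matrix(NA_real_, length(n_grid), length(n_grid),
              dimnames = list(paste0("f1x", n_grid), paste0("f2x", n_grid)))
  if (mode %in% c("both")) {
    for (i in seq_along(n_grid)) for (j in seq_along(n_grid)) {
      g[i, j] <- cell(n_grid[i], n_grid[j])
    }
  } else if (mode == "f1_only") {
    for (i in seq_along(n_grid)) g[i, 1] <- cell(n_grid[i], 1)
  } else {
    for (j in seq_along(n_grid)) g[1, j] <- cell(1, n_grid[j])
  }
  f1_curve <- g[, 1]
  f2_curve <- g[1, ]
  joint <- if (mode == "both") diag(g) else rep(NA_real_, length(n_grid))
  structure(list(grid = g, n_grid = n_grid,
                 f1_curve = f1_curve, f2_curve = f2_curve, joint_curve = joint,
                 f1 = f1, f2 = f2, f1_base = f1_base, f2_base = f2_base,
                 rvmax = f1_base / f2_base, product = product, mode = mode),
            class = "oe_surface")
}

#' @export
print.oe_surface <- function(x, ...) {
  cat("<oe_surface>", x$f1, "x", x$f2, " RVmax =", format(x$rvmax), "\n")
  print(round(x$grid, 6))
  invisible(x)
}
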