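# Constraint sets: bound overrides, fixed fluxes, flux-ratio pins,
# Delta-scaled grouped consumption caps, and expression-scaled Vmax bounds
# built from enzyme kinetics (kcat) and transcript abundance (TPM).

#' Create an (optionally empty) constraint set
#'
#' A constraint set collects, without touching the model, everything the
#' workflow layers on top of plain mass balance:
#' * bound overrides (`lb`/`ub` per reaction, e.g. Vmax caps),
#' * fixed fluxes (`lb = ub = value`),
#' * ratio pins `v_A : v_B = a : b`, enforced as `b v_A - a v_B = 0`,
#' * grouped consumption caps
#'   `sum(consumers) <= delta * sum(producers)` with fluxes measured as the
#'   metabolite-directed positive part (see [group_cap()]).
#'
#' @param bounds data.frame with columns `reaction`, `lb`, `ub` (`NA` keeps
#'   the model's value).
#' @param fixed data.frame with columns `reaction`, `value`.
#' @param ratios data.frame with columns `rxn_a`, `rxn_b`, `a`, `b`.
#' @param group_caps list of objects made by [group_cap()].
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(bounds = NULL, fixed = NULL, ratios = NULL,
                           group_caps = list()) {
  empty <- function(x, cols) {
    if (is.null(x)) {
      stats::setNames(as.data.frame(replicate(length(cols), numeric(0),
                                              simplify = FALSE)), cols)
    } else as.data.frame(x, stringsAsFactors = FALSE)
  }
  cs <- structure(list(
    bounds = empty(bounds, c("reaction", "lb", "ub")),
    fixed = empty(fixed, c("reaction", "value")),
    ratios = empty(ratios, c("rxn_a", "rxn_b", "a", "b")),
    group_caps = group_caps), class = "constraint_set")
  if (nrow(cs$ratios) && any(cs$ratios$a <= 0 | cs$ratios$b <= 0)) {
    stop("ratio pin terms must be positive")
  }
  cs
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>",
      nrow(x$bounds), "bound override(s),",
      nrow(x$fixed), "fixed flux(es),",
      nrow(x$ratios), "ratio pin(s),",
      length(x$group_caps), "group cap(s)\n")
  invisible(x)
}

#' Merge constraint sets (later sets win on conflicting bounds)
#' @param ... `constraint_set` objects.
#' @export
merge_constraints <- function(...) {
  sets <- list(...)
  out <- constraint_set()
  for (cs in sets) {
    if (is.null(cs)) next
    stopifnot(inherits(cs, "constraint_set"))
    out$bounds <- rbind(out$bounds[!(out$bounds$reaction %in% cs$bounds$reaction), ,
                                   drop = FALSE], cs$bounds)
    out$fixed <- rbind(out$fixed[!(out$fixed$reaction %in% cs$fixed$reaction), ,
                                 drop = FALSE], cs$fixed)
    out$ratios <- rbind(out$ratios, cs$ratios)
    out$group_caps <- c(out$group_caps, cs$group_caps)
  }
  out
}

#' Pin the ratio of two reaction fluxes
#'
#' Feasible solutions satisfy `v_A : v_B = a : b`, i.e. `b v_A - a v_B = 0`.
#'
#' @param rxn_a,rxn_b reaction ids.
#' @param a,b positive ratio terms.
#' @return a `constraint_set` holding the single pin.
#' @export
ratio_pin <- function(rxn_a, rxn_b, a, b) {
  if (a <= 0 || b <= 0) stop("ratio pin terms must be positive")
  constraint_set(ratios = data.frame(rxn_a = rxn_a, rxn_b = rxn_b, a = a, b = b,
                                     stringsAsFactors = FALSE))
}

#' Cap grouped consumption at a fraction of grouped production
#'
#' Enforces `sum(F_out) <= delta * sum(F_in)` where each term is the
#' metabolite-directed positive part of a reaction's flux: for a consumer
#' with stoichiometric coefficient `S[met, r] < 0`, consumption is
#' `max(-S[met, r] * v_r, 0)`; for a producer, production is
#' `max(S[met, j] * v_j, 0)`. For reactions that can only run in the
#' metabolite-directed sense (the usual case: irreversible consumers and
#' producers) the term is exact; a reversible consumer is handled with an
#' auxiliary overestimating variable (exact when the cap binds), a reversible
#' producer with a split-variable relaxation.
#'
#' When `metabolite` is `NULL` every reaction participates with weight 1
#' (plain flux cap: `sum(v_cons) <= delta * sum(v_prod)`).
#'
#' With `rhs_value` the producer side is frozen at a reference ("initial")
#' production total and the cap becomes
#' `sum(F_out) <= delta * rhs_value` — the form used when consumption must
#' not exceed a fraction of the *initial* production rate of a reference
#' state. Note that with the variable form and complete consumer/producer
#' sets, steady state forces `sum(F_out) = sum(F_in)`, so any `delta < 1`
#' would shut the pool down entirely; a fractional cap is only meaningful
#' against a partial producer set (upstream supply) or a frozen reference.
#'
#' @param consumers,producers disjoint, non-empty character vectors of
#'   reaction ids.
#' @param delta correction factor in `(0, 1]`.
#' @param metabolite metabolite id whose turnover is capped, or `NULL`.
#' @param rhs_value optional frozen producer total (before `delta` scaling).
#' @return a `constraint_set` holding the single cap.
#' @export
group_cap <- function(consumers, producers, delta, metabolite = NULL,
                      rhs_value = NULL) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]")
  }
  if (!length(consumers) || !length(producers)) {
    stop("consumer and producer sets must be non-empty")
  }
  if (length(intersect(consumers, producers))) {
    stop("consumer and producer sets must be disjoint")
  }
  if (!is.null(rhs_value) && (!is.numeric(rhs_value) || rhs_value < 0)) {
    stop("rhs_value must be a non-negative number")
  }
  cap <- list(consumers = consumers, producers = producers,
              delta = delta, metabolite = metabolite, rhs_value = rhs_value)
  constraint_set(group_caps = list(cap))
}

#' Expression-scaled maximum reaction rate (Vmax) from kinetics and TPM
#'
#' Converts an enzyme's turnover number and transcript abundance into a flux
#' bound: the enzyme amount is taken proportional to its transcript level,
#' `Etotal = theta * TPM` (mmol/gDW), and
#' `Vmax = kcat * 3600 * Etotal` (mmol/gDW/hr) — the factor 3600 converts the
#' per-second turnover number to the per-hour flux unit, applied exactly once.
#'
#' @param kcat turnover number (1/s), positive.
#' @param tpm transcript abundance (TPM), non-negative.
#' @param theta scaling factor (mmol gDW^-1 per TPM unit), positive;
#'   default `1e-5`.
#' @return list with `etotal` and `vmax`.
#' @export
vmax_bound <- function(kcat, tpm, theta = 1e-5) {
  if (!is.numeric(theta) || any(theta <= 0)) stop("theta must be positive")
  if (any(kcat <= 0)) stop("kcat must be positive")
  if (any(tpm < 0)) stop("TPM must be non-negative")
  etotal <- theta * tpm
  list(etotal = etotal, vmax = kcat * 3600 * etotal)
}

#' Build Vmax bound overrides for all reactions covered by a kinetics table
#'
#' Joins the kinetics table (gene -> reaction, kcat, Km) with the expression
#' table at `condition`, computes `Vmax = kcat * 3600 * theta * TPM` per
#' reaction, and returns a `constraint_set` whose upper bounds (and, for
#' reversible reactions, symmetric lower bounds) are capped at Vmax. Where
#' several enzymes map to one reaction their Vmax values are summed.
#'
#' @param model a `cb_model`.
#' @param kinetics data.frame as from [read_kinetics()].
#' @param expression data.frame as from [read_expression()].
#' @param condition condition id to look up in `expression`.
#' @param theta scaling factor, see [vmax_bound()].
#' @return a `constraint_set` of bound overrides; attribute `"vmax"` holds
#'   the per-reaction Vmax table.
#' @export
vmax_constraints <- function(model, kinetics, expression, condition, theta = 1e-5) {
  tab <- vmax_table(kinetics, expression, condition, theta)
  tab <- tab[tab$reaction %in% model$reactions$id, , drop = FALSE]
  agg <- stats::aggregate(vmax ~ reaction, tab, sum)
  lb0 <- model$reactions$lb[match(agg$reaction, model$reactions$id)]
  bounds <- data.frame(reaction = agg$reaction,
                       lb = ifelse(lb0 < 0, -agg$vmax, lb0),
                       ub = agg$vmax, stringsAsFactors = FALSE)
  out <- constraint_set(bounds = bounds)
  attr(out, "vmax") <- tab
  out
}

# per (gene, reaction) Vmax rows; lookup errors are loud
vmax_table <- function(kinetics, expression, condition, theta = 1e-5) {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")
  ex <- expression[expression$condition == condition, , drop = FALSE]
  if (!nrow(ex)) stop("no expression rows for condition '", condition, "'")
  idx <- match(kinetics$gene, ex$gene)
  if (anyNA(idx)) {
    stop("TPM missing for gene(s) in condition '", condition, "': ",
         paste(unique(kinetics$gene[is.na(idx)]), collapse = ", "))
  }
  tpm <- ex$tpm[idx]
  vb <- vmax_bound(kinetics$kcat_per_s, tpm, theta)
  data.frame(gene = kinetics$gene, reaction = kinetics$reaction,
             kcat_per_s = kinetics$kcat_per_s, km_mM = kinetics$km_mM,
             tpm = tpm, theta = theta, etotal = vb$etotal, vmax = vb$vmax,
             stringsAsFactors = FALSE)
}

#' Fit a global theta so a reference reaction's Vmax equals a target flux
#'
#' Vmax is homogeneous of degree 1 in theta, so a single reference
#' (reaction, flux) pair determines the global scaling factor.
#'
#' @param kinetics,expression,condition as in [vmax_constraints()].
#' @param reference_reaction reaction id whose Vmax should equal
#'   `reference_flux`.
#' @param reference_flux target Vmax (mmol/gDW/hr), positive.
#' @return fitted theta.
#' @export
calibrate_theta <- function(kinetics, expression, condition,
                            reference_reaction, reference_flux) {
  if (reference_flux <= 0) stop("reference flux must be positive")
  tab <- vmax_table(kinetics, expression, condition, theta = 1)
  v1 <- sum(tab$vmax[tab$reaction == reference_reaction])
  if (v1 <= 0) stop("reference reaction '", reference_reaction,
                    "' has zero Vmax at theta = 1 (TPM = 0?)")
  reference_flux / v1
}

#' The CS5-style production-strain constraint preset
#'
#' The five constraints the engineered production strain is simulated under:
#' glucose uptake capacity 20 mmol/gDW/hr, biomass flux fixed at 1.706,
#' chrysanthemol secretion floor 0.0023, mevalonate:MEP route flux ratio
#' 6461:1 (DPMVD : CDPMEK), and a DMAPP consumption cap at
#' `delta = 0.4` times precursor-route production.
#'
#' Reaction ids default to the conventional BiGG-style names and can be
#' re-pointed at any model through `aliases`. The DMAPP cap limits total
#' consumption to `delta` times the precursor's *initial* production rate:
#' with `cap_rhs = "initial"` (default) a reference solve of the model under
#' the other preset constraints (but no cap) is performed at construction
#' time, and the producers' production total in that parsimonious reference
#' state is frozen as the cap's right-hand side. (At steady state total
#' consumption of a metabolite always equals its total concurrent
#' production, so a fractional cap against *concurrent* production with
#' complete sets would force the pool to zero; the frozen reference is what
#' makes `delta = 0.4` meaningful.) `cap_rhs = "flux"` instead caps against
#' the concurrent flux of the producer set.
#'
#' @param model a `cb_model`.
#' @param aliases named character vector re-mapping any of
#'   `glucose_exchange`, `biomass`, `product_exchange`, `mva_ratio_rxn`,
#'   `mep_ratio_rxn` to model reaction ids.
#' @param dmapp metabolite id of the capped precursor (default `"dmapp_c"`).
#' @param dmapp_consumers consumer reaction ids; default: every reaction
#'   consuming `dmapp` in the model.
#' @param dmapp_producers producer reaction ids (terminal route reactions).
#' @param glucose_uptake uptake capacity (mmol/gDW/hr).
#' @param biomass_flux fixed biomass flux; the value is applied verbatim on
#'   the model's biomass reaction.
#' @param product_floor secretion lower bound for the product exchange.
#' @param mva_mep_ratio route flux ratio (MVA : MEP).
#' @param delta correction factor of the DMAPP cap.
#' @param fix_biomass fix biomass at `biomass_flux` (`TRUE`, the reference
#'   preset) or leave it free for sweeps that maximize growth (`FALSE`).
#' @param cap_rhs `"initial"` (freeze the cap against the reference state's
#'   production, see above) or `"flux"` (concurrent producer flux).
#' @return a `constraint_set`.
#' @export
cs5_preset <- function(model,
                       aliases = character(),
                       dmapp = "dmapp_c",
                       dmapp_consumers = NULL,
                       dmapp_producers,
                       glucose_uptake = 20,
                       biomass_flux = 1.706,
                       product_floor = 0.0023,
                       mva_mep_ratio = c(6461, 1),
                       delta = 0.4,
                       fix_biomass = TRUE,
                       cap_rhs = c("initial", "flux")) {
  cap_rhs <- match.arg(cap_rhs)
  ids <- c(glucose_exchange = "EX_glc__D_e",
           biomass = "BIOMASS_Ec_iJO1366_WT_53p95M",
           product_exchange = "EX_CS_OH",
           mva_ratio_rxn = "DPMVD",
           mep_ratio_rxn = "CDPMEK")
  ids[names(aliases)] <- aliases
  missing_ids <- ids[!(ids %in% model$reactions$id)]
  if (length(missing_ids)) {
    stop("preset reaction(s) absent from model (provide aliases): ",
         paste(sprintf("%s='%s'", names(missing_ids), missing_ids), collapse = ", "),
         "; candidates: ",
         paste(utils::head(model$reactions$id, 30), collapse = ", "))
  }
  if (is.null(dmapp_consumers)) {
    dmapp_consumers <- consumers_of(model, dmapp)
  }
  rx <- model$reactions
  glb <- -abs(glucose_uptake)  # uptake is negative exchange flux
  bounds <- data.frame(reaction = ids[["glucose_exchange"]],
                       lb = glb,
                       ub = rx$ub[match(ids[["glucose_exchange"]], rx$id)],
                       stringsAsFactors = FALSE)
  bounds <- rbind(bounds, data.frame(
    reaction = ids[["product_exchange"]], lb = product_floor,
    ub = rx$ub[match(ids[["product_exchange"]], rx$id)], stringsAsFactors = FALSE))
  fixed <- if (fix_biomass) {
    data.frame(reaction = ids[["biomass"]], value = biomass_flux,
               stringsAsFactors = FALSE)
  } else NULL
  partial <- merge_constraints(
    constraint_set(bounds = bounds, fixed = fixed),
    ratio_pin(ids[["mva_ratio_rxn"]], ids[["mep_ratio_rxn"]],
              mva_mep_ratio[1], mva_mep_ratio[2]))
  rhs_value <- NULL
  if (cap_rhs == "initial") {
    ref <- baseline_flux(model, partial)
    if (ref$status != "optimal") {
      stop("cannot freeze the DMAPP cap: reference solve is ", ref$status)
    }
    srow <- stats::setNames(as.numeric(model$stoich[dmapp, ]), model$reactions$id)
    wgt <- ifelse(srow[dmapp_producers] != 0, srow[dmapp_producers], 1)
    rhs_value <- sum(pmax(wgt * ref$fluxes[dmapp_producers], 0))
  }
  merge_constraints(
    partial,
    group_cap(dmapp_consumers, dmapp_producers, delta, metabolite = dmapp,
              rhs_value = rhs_value))
}

#' Reactions consuming / producing a metabolite (forward sense)
#' @param model a `cb_model`.
#' @param metabolite metabolite id.
#' @return character vector of reaction ids.
#' @export
consumers_of <- function(model, metabolite) {
  if (!(metabolite %in% model$metabolites$id)) {
    stop("metabolite '", metabolite, "' not in model")
  }
  model$reactions$id[as.numeric(model$stoich[metabolite, ]) < 0]
}

#' @rdname consumers_of
#' @export
producers_of <- function(model, metabolite) {
  if (!(metabolite %in% model$metabolites$id)) {
    stop("metabolite '", metabolite, "' not in model")
  }
  model$reactions$id[as.numeric(model$stoich[metabolite, ]) > 0]
}

#' Serialize / deserialize a constraint set as YAML
#' @param cs a `constraint_set`.
#' @param path file path.
#' @export
write_constraints_yaml <- function(cs, path) {
  obj <- list(
    bounds = if (nrow(cs$bounds)) cs$bounds else NULL,
    fixed = if (nrow(cs$fixed)) cs$fixed else NULL,
    ratios = if (nrow(cs$ratios)) cs$ratios else NULL,
    group_caps = lapply(cs$group_caps, function(g) {
      list(consumers = as.list(g$consumers), producers = as.list(g$producers),
           delta = g$delta, metabolite = g$metabolite,
           rhs_value = g$rhs_value)
    }))
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_constraints_yaml
#' @export
read_constraints_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  df <- function(x) if (is.null(x)) NULL else do.call(rbind, lapply(x, as.data.frame))
  caps <- lapply(obj$group_caps %||% list(), function(g) {
    list(consumers = unlist(g$consumers), producers = unlist(g$producers),
         delta = g$delta, metabolite = g$metabolite,
         rhs_value = g$rhs_value)
  })
  constraint_set(bounds = df(obj$bounds), fixed = df(obj$fixed),
                 ratios = df(obj$ratios), group_caps = caps)
}
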