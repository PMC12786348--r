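# Synthetic ground-truth fixtures: a small terpenoid-factory network with
# glucose uptake, lumped glycolysis, parallel MEP and MVA routes to the C5
# prenyl pool (IPP/DMAPP), competing DMAPP consumers (a prenyltransferase
# pair standing in for ispA, a phosphatase shunt, and the chrysanthemol
# route), a two-step dehydrogenase tail to chrysanthemic acid, and a biomass
# pseudo-reaction that requires the prenyltransferase product — so the branch
# is essential (knockout is lethal, knockdown is not), mirroring the
# biological situation the workflow was built for.
#
# Metabolite formulas carry carbon only; the toy is carbon-balanced by
# construction, which keeps the mass-balance check meaningful and trivially
# auditable.

#' Specification of the synthetic toy network
#'
#' @param seed integer seed for the noise generators built on top.
#' @param dominance ratio of the planted dominant consumer's `kcat * TPM`
#'   capacity to each competitor's (`>= 1`).
#' @param delta default correction factor of the DMAPP consumption cap.
#' @param biomass_quota stoichiometric demand of the prenyl product (FPP
#'   analogue) in the biomass reaction (`> 0`: makes full branch knockout
#'   lethal).
#' @param glc_uptake default glucose uptake capacity (mmol/gDW/hr).
#' @param big_bound default finite bound magnitude for unconstrained
#'   reactions.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(seed = 1, dominance = 8, delta = 0.4, biomass_quota = 0.1,
                     glc_uptake = 10, big_bound = 1000) {
  stopifnot(dominance >= 1, biomass_quota > 0, delta > 0, delta <= 1,
            glc_uptake > 0)
  structure(list(seed = as.integer(seed), dominance = dominance, delta = delta,
                 biomass_quota = biomass_quota, glc_uptake = glc_uptake,
                 big_bound = big_bound), class = "toy_spec")
}

toy_reaction_defs <- function(spec) {
  B <- spec$big_bound
  q <- spec$biomass_quota
  # module: core = wild-type-like chassis, mva = heterologous mevalonate
  # route, chr = chrysanthemate tail + shunt
  defs <- list(
    list("EX_glc__D_e", "glucose exchange", "glc__D_e ->", -spec$glc_uptake, B, NA, "core"),
    list("GLCt",  "glucose transport", "glc__D_e -> glc__D_c", 0, B, "glcP_t", "core"),
    list("GLYCL", "glycolysis (lumped)", "glc__D_c -> g3p_c + pyr_c", 0, B, NA, "core"),
    list("G3PD",  "lower glycolysis (lumped)", "g3p_c -> pyr_c", 0, B, NA, "core"),
    list("PDHL",  "pyruvate dehydrogenase (lumped)", "pyr_c -> accoa_c + co2_c", 0, B, NA, "core"),
    list("DXSL",  "MEP route entry (lumped)", "g3p_c + pyr_c -> dxp_c + co2_c", 0, B, NA, "core"),
    list("CDPMEK", "CDP-ME kinase (MEP route)", "dxp_c -> cdpme_c", 0, B, NA, "core"),
    list("MEPL",  "MEP route terminal (lumped)", "cdpme_c -> ipp_c", 0, B, NA, "core"),
    list("IDI",   "IPP isomerase", "ipp_c <=> dmapp_c", -B, B, "idi_t", "core"),
    list("DMATT", "DMAPP+IPP prenyltransferase (GPP synthase)",
         "dmapp_c + ipp_c -> gpp_c", 0, B, "ispA_t", "core"),
    list("GRTT",  "GPP+IPP prenyltransferase (FPP synthase)",
         "gpp_c + ipp_c -> fpp_c", 0, B, "ispA_t", "core"),
    list("GPPH",  "GPP phosphatase (geraniol shunt)", "gpp_c -> ger_c", 0, B, "gpph_t", "core"),
    list("FPPH",  "FPP phosphatase (farnesol shunt)", "fpp_c -> far_c", 0, B, "fpph_t", "core"),
    list("BIOMASS_toy", "biomass pseudo-reaction",
         sprintf("accoa_c + %s fpp_c ->", format(q, trim = TRUE)), 0, B, NA, "core"),
    list("EX_co2", "CO2 exchange", "co2_c ->", 0, B, NA, "core"),
    list("EX_ger", "geraniol exchange", "ger_c ->", 0, B, NA, "core"),
    list("EX_far", "farnesol exchange", "far_c ->", 0, B, NA, "core"),
    # heterologous mevalonate route
    list("MVAS",  "acetyl-CoA to mevalonate (lumped)", "3 accoa_c -> mev_c", 0, B, "mvaS_t", "mva"),
    list("DPMVD", "mevalonate decarboxylase (MVA terminal)",
         "mev_c -> ipp_c + co2_c", 0, B, "mvaD_t", "mva"),
    # chrysanthemate tail and DMAP shunt
    list("CDS",   "chrysanthemyl diphosphate synthase", "2 dmapp_c -> cdpchr_c", 0, B, "cds_t", "chr"),
    list("NUDX1", "CDP-chrysanthemol phosphatase", "cdpchr_c -> chol_c", 0, B, "nudix1_t", "chr"),
    list("NUDX2", "DMAPP phosphatase shunt", "dmapp_c -> dmap_c", 0, B, "nudix2_t", "chr"),
    list("ADH2",  "chrysanthemol dehydrogenase", "chol_c -> chal_c", 0, B, "adh2_t", "chr"),
    list("ALDH1", "chrysanthemal dehydrogenase", "chal_c -> chac_c", 0, B, "aldh1_t", "chr"),
    list("EX_CS_OH", "chrysanthemol exchange", "chol_c ->", 0, B, NA, "chr"),
    list("EX_chac", "chrysanthemic acid exchange", "chac_c ->", 0, B, NA, "chr"),
    list("EX_dmap", "DMAP exchange", "dmap_c ->", 0, B, NA, "chr"))
  do.call(rbind, lapply(defs, function(d) {
    data.frame(reaction_id = d[[1]], name = d[[2]], equation = d[[3]],
               lb = d[[4]], ub = d[[5]], gene_rule = d[[6]], module = d[[7]],
               stringsAsFactors = FALSE)
  }))
}

toy_metabolites <- function() {
  m <- rbind(
    c("glc__D_e", "D-glucose (extracellular)", "e", "C6"),
    c("glc__D_c", "D-glucose", "c", "C6"),
    c("g3p_c", "glyceraldehyde 3-phosphate (lumped C3)", "c", "C3"),
    c("pyr_c", "pyruvate", "c", "C3"),
    c("accoa_c", "acetyl-CoA (acetyl moiety)", "c", "C2"),
    c("co2_c", "CO2", "c", "C1"),
    c("dxp_c", "DXP (MEP route intermediate)", "c", "C5"),
    c("cdpme_c", "CDP-ME (MEP route intermediate)", "c", "C5"),
    c("mev_c", "mevalonate", "c", "C6"),
    c("ipp_c", "isopentenyl diphosphate (C5 moiety)", "c", "C5"),
    c("dmapp_c", "dimethylallyl diphosphate (C5 moiety)", "c", "C5"),
    c("gpp_c", "geranyl diphosphate (C10 moiety)", "c", "C10"),
    c("fpp_c", "farnesyl diphosphate (C15 moiety)", "c", "C15"),
    c("dmap_c", "dimethylallyl monophosphate", "c", "C5"),
    c("cdpchr_c", "chrysanthemyl diphosphate", "c", "C10"),
    c("chol_c", "chrysanthemol", "c", "C10"),
    c("chal_c", "chrysanthemal", "c", "C10"),
    c("chac_c", "chrysanthemic acid", "c", "C10"),
    c("ger_c", "geraniol", "c", "C10"),
    c("far_c", "farnesol", "c", "C15"))
  data.frame(id = m[, 1], name = m[, 2], compartment = m[, 3], formula = m[, 4],
             charge = 0L, stringsAsFactors = FALSE)
}

#' Generate the synthetic toy model and its ground truth
#'
#' @param spec a [toy_spec()].
#' @return list with
#'   * `model` — the full engineered-strain toy (`cb_model`, objective =
#'     biomass),
#'   * `core` — the wild-type-like chassis (no MVA route, no chrysanthemate
#'     tail),
#'   * `extensions` — named list of pathway-extension tables (`mva`, `chr`)
#'     such that extending `core` with both reproduces `model`,
#'   * `truth` — planted ground truth: dominant consumer and gene, true
#'     kinetics and expression tables, consumer/producer sets of the DMAPP
#'     cap, preset aliases, dehydrogenase base capacities.
#' @export
make_toy_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  defs <- toy_reaction_defs(spec)
  mets <- toy_metabolites()
  build <- function(rows) {
    stoich <- lapply(rows$equation, function(e) parse_equation(e)$coef)
    names(stoich) <- rows$reaction_id
    used <- unique(unlist(lapply(stoich, names)))
    cb_model("toy_CS", mets[mets$id %in% used, , drop = FALSE],
             data.frame(id = rows$reaction_id, name = rows$name,
                        lb = rows$lb, ub = rows$ub, gene_rule = rows$gene_rule,
                        is_exchange = grepl("^(EX|DM|SK)_", rows$reaction_id),
                        stringsAsFactors = FALSE),
             stoich, objective = c(BIOMASS_toy = 1))
  }
  model <- build(defs)
  core <- build(defs[defs$module == "core", , drop = FALSE])
  core$id <- "toy_WT"
  extensions <- lapply(split(defs, defs$module)[c("mva", "chr")], function(d) {
    d[c("reaction_id", "name", "equation", "lb", "ub", "gene_rule")]
  })
  names(extensions) <- c("mva", "chr")

  # planted kinetics: competitor capacity c0, dominant = dominance * c0
  theta <- 1e-5
  tpm <- c(glcP_t = 200, idi_t = 90, ispA_t = 160, gpph_t = 40, fpph_t = 40,
           mvaS_t = 150, mvaD_t = 150, cds_t = 80, nudix1_t = 120,
           nudix2_t = 60, adh2_t = 100, aldh1_t = 100)
  c0 <- 720  # competitor kcat*TPM capacity
  kin <- data.frame(
    gene = c("ispA_t", "ispA_t", "nudix2_t", "cds_t", "adh2_t", "aldh1_t"),
    reaction = c("DMATT", "GRTT", "NUDX2", "CDS", "ADH2", "ALDH1"),
    kcat_per_s = c(spec$dominance * c0 / tpm[["ispA_t"]],  # dominant branch
                   30,
                   c0 / tpm[["nudix2_t"]],
                   c0 / tpm[["cds_t"]],
                   0.2 / (3600 * theta * tpm[["adh2_t"]]),   # Vmax(ADH2) = 0.2
                   0.002 / (3600 * theta * tpm[["aldh1_t"]])), # Vmax(ALDH1) = 0.002
    km_mM = c(0.04, 0.06, 0.5, 0.25, 1.0, 2.0),
    source = "synthetic",
    stringsAsFactors = FALSE)

  truth <- list(
    substrate = "dmapp_c",
    dominant_consumer = "DMATT",
    dominant_gene = "ispA_t",
    consumers = c("CDS", "DMATT", "NUDX2"),
    producers = c("MEPL", "DPMVD"),  # terminal C5-precursor route steps
    aliases = c(biomass = "BIOMASS_toy"),
    delta = spec$delta,
    theta = theta,
    tpm = tpm,
    kinetics = kin,
    f1 = "ADH2", f2 = "ALDH1",
    f1_base = 0.2, f2_base = 0.002,
    product_alcohol = "EX_CS_OH",
    product_acid = "EX_chac",
    knockdown_targets = c("DMATT", "GRTT"))

  chk <- fba(model)
  if (chk$status != "optimal" || chk$objective_value <= 1e-6) {
    stop("toy specification yields an infeasible or zero-growth base model")
  }
  list(model = model, core = core, extensions = extensions, truth = truth)
}

#' Kinetics table with multiplicative log-normal noise around the truth
#'
#' @param truth ground-truth list from [make_toy_model()].
#' @param noise_sd standard deviation of the log-normal noise (`0` = exact).
#' @param seed integer seed.
#' @return data.frame in the [read_kinetics()] layout.
#' @export
make_kinetics_table <- function(truth, noise_sd = 0, seed = 1) {
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  kin <- truth$kinetics
  with_preserved_rng({
    set.seed(seed)
    kin$kcat_per_s <- kin$kcat_per_s * exp(stats::rnorm(nrow(kin), 0, noise_sd))
    kin$km_mM <- kin$km_mM * exp(stats::rnorm(nrow(kin), 0, noise_sd))
  })
  kin
}

#' Expression table (TPM per gene per condition) around the truth
#'
#' Baseline TPM is the planted truth times seeded log-normal noise, drawn
#' independently per condition; each condition additionally multiplies the
#' per-gene effects given for it (e.g. an sRNA-silenced condition with
#' multiplier 0.1223 on the ispA analogue emulates an 87.77% knockdown).
#'
#' @param truth ground-truth list from [make_toy_model()].
#' @param conditions named list: condition id -> named numeric vector of
#'   per-gene multipliers (or `NULL` for none).
#' @param noise_sd log-normal noise sd (`0` = exact).
#' @param seed integer seed.
#' @return data.frame in the [read_expression()] layout.
#' @export
make_expression_table <- function(truth,
                                  conditions = list(baseline = NULL),
                                  noise_sd = 0, seed = 1) {
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- names(truth$tpm)
  rows <- list()
  with_preserved_rng({
    set.seed(seed)
    for (cond in names(conditions)) {
      eff <- rep(1, length(genes)); names(eff) <- genes
      ce <- conditions[[cond]]
      if (!is.null(ce)) {
        if (any(ce <= 0)) stop("condition effects must be positive multipliers")
        eff[names(ce)] <- ce
      }
      tpm <- truth$tpm * eff * exp(stats::rnorm(length(genes), 0, noise_sd))
      rows[[cond]] <- data.frame(gene = genes, condition = cond,
                                 tpm = unname(tpm), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
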