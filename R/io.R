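# Readers and writers: community constraint-based JSON dialect, SBML Level 3
# with fbc flux bounds, and the tab-separated side tables (pathway extensions,
# gene maps, kinetics, expression).

#' Read a constraint-based model
#'
#' @param path file path.
#' @param format `"json"` (community constraint-based dialect) or `"sbml"`;
#'   guessed from the file extension when missing.
#' @return a `cb_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a constraint-based model
#'
#' The emitted file re-reads (with [read_model()]) to an equivalent model:
#' identical ids, stoichiometric coefficients, bounds and objective.
#'
#' @param model a `cb_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (k in c("metabolites", "reactions")) {
    if (is.null(j[[k]])) stop("JSON model lacks '", k, "'")
  }
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% sub("^.*_", "", m$id),
               formula = m$formula %||% NA_character_,
               charge = as.integer(m$charge %||% NA_integer_),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(j$reactions, function(r) {
    lb <- as.numeric(r$lower_bound %||% -1000)
    ub <- as.numeric(r$upper_bound %||% 1000)
    if (lb > ub) stop("reaction '", r$id, "': lower bound ", lb, " exceeds upper bound ", ub)
    gr <- r$gene_reaction_rule %||% ""
    data.frame(id = r$id, name = r$name %||% r$id, lb = lb, ub = ub,
               gene_rule = if (nzchar(gr)) gr else NA_character_,
               is_exchange = grepl("^(EX|DM|SK)_", r$id),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(j$reactions, function(r) {
    co <- unlist(r$metabolites)
    if (is.null(co) || !length(co)) stop("reaction '", r$id, "' has empty stoichiometry")
    co
  })
  names(stoich) <- rxns$id
  objective <- numeric()
  for (r in j$reactions) {
    w <- as.numeric(r$objective_coefficient %||% 0)
    if (w != 0) objective[r$id] <- w
  }
  cb_model(j$id %||% basename(path), mets, rxns, stoich, objective)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    co <- model$stoich[, r$id]; co <- co[co != 0]
    list(id = r$id, name = r$name, metabolites = as.list(co),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = if (is.na(r$gene_rule)) "" else r$gene_rule,
         objective_coefficient =
           if (r$id %in% names(model$objective)) model$objective[[r$id]] else 0)
  })
  genes <- lapply(model_genes(model), function(g) list(id = g, name = g))
  cpts <- unique(model$metabolites$compartment)
  obj <- list(id = model$id, version = "1",
              metabolites = mets, reactions = rxns, genes = genes,
              compartments = stats::setNames(as.list(cpts), cpts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id),
                             "fbc:strict" = "false")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", m$id),
      name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
  }
  # one parameter per distinct bound value, as fbc flux bounds
  vals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  pids <- stats::setNames(paste0("B_", seq_along(vals)), format_num(vals))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals) {
    xml2::xml_add_child(lp, "parameter", id = pids[[format_num(v)]],
                        value = format_num(v), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", r$id),
      name = r$name, reversible = if (r$lb < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rx, "fbc:lowerFluxBound", pids[[format_num(r$lb)]])
    xml2::xml_set_attr(rx, "fbc:upperFluxBound", pids[[format_num(r$ub)]])
    if (!is.na(r$gene_rule) && nzchar(r$gene_rule)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", r$gene_rule))
    }
    co <- model$stoich[, r$id]; co <- co[co != 0]
    subs <- co[co < 0]; prods <- co[co > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(lre, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format_num(-subs[[m]]), constant = "true")
      }
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(lpr, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format_num(prods[[m]]), constant = "true")
      }
    }
  }
  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = paste0("R_", rid),
                          "fbc:coefficient" = format_num(model$objective[[rid]]))
    }
  }
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("SBML parse failure: no <model> element")
  strip <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip(xml2::xml_attr(sp, "id"), "M"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns),
    charge = as.integer(xml2::xml_attr(sp, "fbc:charge", ns)),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) stop("SBML parse failure: no reactions")
  rxns <- NULL; stoich <- list()
  for (r in rx) {
    rid <- strip(xml2::xml_attr(r, "id"), "R")
    lbp <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns)
    ubp <- xml2::xml_attr(r, "fbc:upperFluxBound", ns)
    lb <- if (!is.na(lbp)) pvals[[lbp]] else if (isTRUE(xml2::xml_attr(r, "reversible") == "true")) -1000 else 0
    ub <- if (!is.na(ubp)) pvals[[ubp]] else 1000
    if (lb > ub) stop("reaction '", rid, "': lower bound ", lb, " exceeds upper bound ", ub)
    notes <- xml2::xml_text(xml2::xml_find_all(r, ".//s:notes//*", ns))
    ga <- grep("GENE_ASSOCIATION:", notes, value = TRUE)
    gr <- if (length(ga)) trimws(sub(".*GENE_ASSOCIATION:", "", ga[1])) else NA_character_
    if (!is.na(gr) && !nzchar(gr)) gr <- NA_character_
    co <- numeric()
    for (sr in xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)) {
      m <- strip(xml2::xml_attr(sr, "species"), "M")
      co[m] <- (if (is.na(co[m])) 0 else co[m]) - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)) {
      m <- strip(xml2::xml_attr(sr, "species"), "M")
      co[m] <- (if (is.na(co[m])) 0 else co[m]) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    if (!length(co)) stop("reaction '", rid, "' has empty stoichiometry")
    rxns <- rbind(rxns, data.frame(id = rid,
      name = ifelse(is.na(xml2::xml_attr(r, "name")), rid, xml2::xml_attr(r, "name")),
      lb = lb, ub = ub, gene_rule = gr,
      is_exchange = grepl("^(EX|DM|SK)_", rid), stringsAsFactors = FALSE))
    stoich[[rid]] <- co
  }
  objective <- numeric()
  for (fo in xml2::xml_find_all(mdl, ".//fbc:listOfFluxObjectives/fbc:fluxObjective", ns)) {
    rid <- strip(xml2::xml_attr(fo, "fbc:reaction", ns), "R")
    objective[rid] <- as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns))
  }
  mid <- xml2::xml_attr(mdl, "id")
  cb_model(if (is.na(mid)) basename(path) else mid, mets, rxns, stoich, objective)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
format_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pathway-extension table
#'
#' Tab-separated with a header; columns `reaction_id`, `name`, `equation`,
#' `lb`, `ub`, `gene_rule`, `replace`, `note` (the last three optional).
#' Equations use the `"2 a_c + b_c -> c_c"` / `"<=>"` grammar of
#' [parse_equation()].
#'
#' @param path TSV path.
#' @return data.frame suitable for [extend_model()].
#' @export
read_pathway_extension <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "equation", "lb", "ub")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("extension table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.null(x$replace)) x$replace <- as.logical(x$replace)
  x
}

#' Write a pathway-extension table
#' @param extension data.frame as accepted by [extend_model()].
#' @param path output TSV path.
#' @export
write_pathway_extension <- function(extension, path) {
  utils::write.table(extension, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene id map (template gene, target gene, match score)
#' @param path TSV with columns `template_id`, `target_id`, `match_score`.
#' @export
read_gene_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("template_id", "target_id", "match_score") %in% names(x)))
  x
}

#' Read an enzyme kinetics table
#' @param path TSV with columns `gene`, `reaction`, `kcat_per_s`, `km_mM` and
#'   optionally `source`.
#' @export
read_kinetics <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "reaction", "kcat_per_s", "km_mM") %in% names(x)))
  if (any(x$kcat_per_s <= 0) || any(x$km_mM <= 0)) {
    stop("kinetics table: kcat and Km must be positive")
  }
  x
}

#' Read a gene-expression table
#' @param path TSV with columns `gene`, `condition`, `tpm`.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "condition", "tpm") %in% names(x)))
  if (any(x$tpm < 0)) stop("expression table: TPM must be non-negative")
  x
}

#' Write a generic report table as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
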