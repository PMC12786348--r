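# Constraint-based model container and structural operations.
#
# The model is a light S3 object mirroring the community constraint-based
# JSON dialect: a metabolite table, a reaction table, a sparse stoichiometric
# matrix S (metabolites x reactions) and a named objective vector.
# Identifiers follow BiGG-style conventions (lowercase metabolite id with a
# compartment suffix, e.g. "dmapp_c"; reaction ids like "DMATT", "EX_glc__D_e").

#' Construct a constraint-based model
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `formula` (elemental formula string, `NA` allowed) and
#'   `charge` (integer, `NA` allowed).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   optionally `gene_rule` (boolean expression over gene ids, `NA` allowed)
#'   and `is_exchange`.
#' @param stoich stoichiometry, either a (sparse) matrix with one row per
#'   metabolite and one column per reaction, or a named list mapping reaction
#'   id to a named coefficient vector (negative = consumed).
#' @param objective named numeric vector of reaction weights.
#' @return an object of class `cb_model`.
#' @export
cb_model <- function(id, metabolites, reactions, stoich, objective = numeric()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- NA_character_
  if (is.null(reactions$is_exchange)) {
    reactions$is_exchange <- grepl("^(EX|DM|SK)_", reactions$id)
  }
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  if (any(!nzchar(metabolites$compartment) | is.na(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  bad <- reactions$lb > reactions$ub
  if (any(bad)) {
    stop("reaction bound lb > ub for: ", paste(reactions$id[bad], collapse = ", "))
  }
  if (is.list(stoich) && !is.matrix(stoich)) {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoich)) {
      co <- stoich[[rid]]
      miss <- setdiff(names(co), metabolites$id)
      if (length(miss)) stop("reaction ", rid, " references unknown metabolite: ",
                             paste(miss, collapse = ", "))
      S[names(co), rid] <- co
    }
    stoich <- S
  } else {
    stoich <- Matrix::Matrix(stoich, sparse = TRUE)
    if (is.null(dimnames(stoich)) || is.null(rownames(stoich))) {
      dimnames(stoich) <- list(metabolites$id, reactions$id)
    }
    stoich <- stoich[metabolites$id, reactions$id, drop = FALSE]
  }
  empty <- Matrix::colSums(stoich != 0) == 0
  if (any(empty)) {
    stop("reaction with empty stoichiometry: ",
         paste(reactions$id[empty], collapse = ", "))
  }
  miss <- setdiff(names(objective), reactions$id)
  if (length(miss)) stop("objective references unknown reaction: ",
                         paste(miss, collapse = ", "))
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 stoich = stoich, objective = objective),
            class = "cb_model")
}

#' @export
print.cb_model <- function(x, ...) {
  cat("<cb_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites), "\n",
      " reactions:  ", nrow(x$reactions), "\n",
      " objective:  ",
      if (length(x$objective)) paste(names(x$objective), collapse = " + ") else "(none)",
      "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#' @param model a `cb_model`.
#' @return sparse `Matrix` (metabolites x reactions).
#' @export
stoich_matrix <- function(model) model$stoich

#' Parse a reaction equation string
#'
#' Grammar: `"2 a_c + b_c -> c_c"` for irreversible, `"<=>"` for reversible
#' reactions; an empty side is allowed (exchange/sink/biomass pseudo
#' reactions), e.g. `"glc__D_e ->"` or `"-> x_c"`.
#'
#' @param eq equation string.
#' @return list with `coef` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  eq <- trimws(eq)
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, "<=>|-->|->", perl = TRUE)[[1]]
  if (length(sides) > 2) stop("malformed equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
    out <- numeric(0)
    for (tm in terms) {
      tm <- trimws(tm)
      mm <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]*(?:/[0-9]+)?)\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
      if (length(mm) == 0) stop("malformed term '", tm, "' in equation: ", eq)
      coef <- mm[2]
      coef <- if (!nzchar(coef)) 1 else if (grepl("/", coef)) {
        pq <- as.numeric(strsplit(coef, "/")[[1]]); pq[1] / pq[2]
      } else as.numeric(coef)
      out[mm[3]] <- (if (is.na(out[mm[3]])) 0 else out[mm[3]]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], +1) else numeric()
  coef <- lhs
  for (m in names(rhs)) coef[m] <- (if (is.na(coef[m])) 0 else coef[m]) + rhs[m]
  coef <- coef[coef != 0]
  if (length(coef) == 0) stop("equation cancels to nothing: ", eq)
  list(coef = coef, reversible = rev)
}

#' Render a reaction's stoichiometry as an equation string
#' @param model a `cb_model`.
#' @param rxn reaction id.
#' @return equation string in `"a A + b B -> c C"` / `"<=>"` form.
#' @export
format_equation <- function(model, rxn) {
  co <- model$stoich[, rxn]
  co <- co[co != 0]
  fmt <- function(v) {
    paste(vapply(names(v), function(m) {
      a <- abs(v[[m]])
      if (a == 1) m else paste(format(a, scientific = FALSE, trim = TRUE), m)
    }, character(1)), collapse = " + ")
  }
  arrow <- if (model$reactions$lb[match(rxn, model$reactions$id)] < 0) "<=>" else "->"
  paste(fmt(co[co < 0]), arrow, fmt(co[co > 0]))
}

#' Extend a model with heterologous pathway reactions
#'
#' Adds the rows of a pathway-extension table (e.g. a mevalonate pathway or a
#' chrysanthemate tail) to a model. New metabolites referenced by the
#' equations are created automatically, with compartment taken from the id
#' suffix (`"_c"`, `"_e"`, ...). The input model is not modified.
#'
#' @param model a `cb_model`.
#' @param extension data.frame with columns `reaction_id`, `name`, `equation`,
#'   `lb`, `ub` and optionally `gene_rule`, `replace` (logical), `note`;
#'   see [read_pathway_extension()].
#' @return the extended `cb_model`.
#' @export
extend_model <- function(model, extension) {
  extension <- as.data.frame(extension, stringsAsFactors = FALSE)
  need <- c("reaction_id", "equation", "lb", "ub")
  miss <- setdiff(need, names(extension))
  if (length(miss)) stop("extension table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(extension$name)) extension$name <- extension$reaction_id
  if (is.null(extension$gene_rule)) extension$gene_rule <- NA_character_
  if (is.null(extension$replace)) extension$replace <- FALSE
  extension$replace[is.na(extension$replace)] <- FALSE

  mets <- model$metabolites
  rxns <- model$reactions
  stoich <- lapply(rxns$id, function(r) { co <- model$stoich[, r]; co[co != 0] })
  names(stoich) <- rxns$id

  for (i in seq_len(nrow(extension))) {
    rid <- extension$reaction_id[i]
    parsed <- parse_equation(extension$equation[i])
    if (rid %in% rxns$id) {
      if (!isTRUE(extension$replace[i])) {
        stop("reaction id '", rid, "' already present; set replace=TRUE to overwrite")
      }
      rxns <- rxns[rxns$id != rid, , drop = FALSE]
      stoich[[rid]] <- NULL
    }
    new_mets <- setdiff(names(parsed$coef), mets$id)
    if (length(new_mets)) {
      cpt <- sub("^.*_([a-z][a-z0-9]?)$", "\\1", new_mets)
      bad <- cpt == new_mets
      if (any(bad)) stop("cannot infer compartment for new metabolite(s): ",
                         paste(new_mets[bad], collapse = ", "))
      mets <- rbind(mets, data.frame(id = new_mets, name = new_mets,
                                     compartment = cpt,
                                     formula = NA_character_, charge = NA_integer_,
                                     stringsAsFactors = FALSE))
    }
    rxns <- rbind(rxns, data.frame(id = rid, name = extension$name[i],
                                   lb = as.numeric(extension$lb[i]),
                                   ub = as.numeric(extension$ub[i]),
                                   gene_rule = extension$gene_rule[i],
                                   is_exchange = grepl("^(EX|DM|SK)_", rid),
                                   stringsAsFactors = FALSE))
    stoich[[rid]] <- parsed$coef
  }
  cb_model(model$id, mets, rxns, stoich[rxns$id], model$objective)
}

#' Rewrite gene ids in gene rules using a template-to-target map
#'
#' Applies an id-mapping table (typically derived upstream from sequence
#' matching) to the gene rules of a model. Rows whose `match_score` fails the
#' threshold are dropped before substitution; ids without a surviving mapping
#' are left untouched and listed in the attached report.
#'
#' @param model a `cb_model`.
#' @param map data.frame with columns `template_id`, `target_id`,
#'   `match_score` (E-value-like: smaller is better).
#' @param score_threshold keep rows with `match_score < score_threshold`
#'   (default `1e-5`).
#' @return the rewritten `cb_model`; attribute `"gene_map_report"` holds a
#'   list with `mapped` and `unmapped` gene id vectors.
#' @export
apply_gene_map <- function(model, map, score_threshold = 1e-5) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map)) {
    stopifnot(all(c("template_id", "target_id", "match_score") %in% names(map)))
    map <- map[as.numeric(map$match_score) < score_threshold, , drop = FALSE]
    map <- unique(map[c("template_id", "target_id")])
    dup <- duplicated(map$template_id)
    if (any(dup)) stop("gene map not injective for template id(s): ",
                       paste(unique(map$template_id[dup]), collapse = ", "))
  }
  lut <- if (nrow(map)) stats::setNames(map$target_id, map$template_id) else character()
  rules <- model$reactions$gene_rule
  seen <- character(); mapped <- character()
  out <- vapply(rules, function(r) {
    if (is.na(r) || !nzchar(r)) return(r)
    toks <- gene_rule_tokens(r)
    seen <<- union(seen, toks)
    for (g in intersect(toks, names(lut))) {
      mapped <<- union(mapped, g)
      r <- gsub(paste0("\\b", g, "\\b"), lut[[g]], r)
    }
    r
  }, character(1), USE.NAMES = FALSE)
  model$reactions$gene_rule <- out
  attr(model, "gene_map_report") <- list(mapped = mapped,
                                         unmapped = setdiff(seen, mapped))
  model
}

gene_rule_tokens <- function(rule) {
  toks <- regmatches(rule, gregexpr("[A-Za-z0-9_.-]+", rule))[[1]]
  setdiff(toks, c("and", "or", "AND", "OR", "And", "Or"))
}

#' List genes referenced by a model's gene rules
#' @param model a `cb_model`.
#' @return character vector of gene ids.
#' @export
model_genes <- function(model) {
  rules <- model$reactions$gene_rule
  sort(unique(unlist(lapply(rules[!is.na(rules) & nzchar(rules)], gene_rule_tokens))))
}

# "C6H12O6" -> c(C = 6, H = 12, O = 6)
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  if (!nzchar(paste(parts, collapse = "")) || paste(parts, collapse = "") != f) {
    stop("unparseable formula: ", f)
  }
  el <- sub("[0-9]*$", "", parts)
  nn <- as.numeric(sub("^[A-Za-z]+", "", parts))
  nn[is.na(nn)] <- 1
  tapply(nn, el, sum)
}

#' Check elemental mass balance of a model
#'
#' Every internal reaction (not an exchange/demand/sink, not a biomass pseudo
#' reaction) whose participating metabolites all carry elemental formulas is
#' checked for per-element balance. An empty result means the model passes.
#'
#' @param model a `cb_model`.
#' @param biomass_pattern regex identifying biomass pseudo-reactions by id.
#' @return data.frame with columns `reaction`, `element`, `net` (one row per
#'   imbalanced element); zero rows on a clean model. Attribute `"skipped"`
#'   lists reactions not checked (exchanges, biomass, incomplete formulas).
#' @export
validate_model <- function(model, biomass_pattern = "^BIOMASS") {
  out <- data.frame(reaction = character(), element = character(),
                    net = numeric(), stringsAsFactors = FALSE)
  skipped <- character()
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    if (model$reactions$is_exchange[i] || grepl(biomass_pattern, rid)) {
      skipped <- c(skipped, rid); next
    }
    co <- model$stoich[, rid]; co <- co[co != 0]
    fs <- formulas[names(co)]
    if (any(is.na(fs) | !nzchar(fs))) { skipped <- c(skipped, rid); next }
    net <- numeric()
    for (m in names(co)) {
      cnt <- parse_formula(fs[[m]])
      for (el in names(cnt)) {
        net[el] <- (if (is.na(net[el])) 0 else net[el]) + co[[m]] * cnt[[el]]
      }
    }
    bad <- abs(net) > 1e-9
    if (any(bad)) {
      out <- rbind(out, data.frame(reaction = rid, element = names(net)[bad],
                                   net = unname(net[bad]), stringsAsFactors = FALSE))
    }
  }
  attr(out, "skipped") <- skipped
  out
}
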