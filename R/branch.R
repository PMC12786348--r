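# Branch-point screening: which enzyme diverts a shared precursor?
#
# Two complementary views of the competition for a substrate (DMAPP in the
# motivating application):
#  * PRate — the Michaelis-Menten catalytic-rate share of each competing
#    enzyme at substrate concentration [s]:
#      PRate_i = (kcat_i / (Km_i + [s])) / sum_j (kcat_j / (Km_j + [s]))
#  * Vmax ranking — expression-scaled capacity kcat * 3600 * theta * TPM of
#    every consumer reaction, the quantity that identifies the dominant
#    branch (the ispA-type finding).

#' Michaelis-Menten catalytic-rate proportions of competing enzymes
#'
#' @param kcat turnover numbers (1/s), one per enzyme.
#' @param km Michaelis constants (mM), one per enzyme.
#' @param s substrate concentration (mM), `>= 0`.
#' @return vector of proportions summing to 1.
#' @export
prate <- function(kcat, km, s) {
  if (!length(kcat)) stop("no enzymes supplied")
  if (length(km) != length(kcat)) stop("kcat and km lengths differ")
  if (!is.numeric(s) || length(s) != 1 || s < 0) {
    stop("substrate concentration must be a single non-negative number")
  }
  if (any(kcat <= 0) || any(km <= 0)) stop("kcat and Km must be positive")
  rate <- kcat / (km + s)
  rate / sum(rate)
}

#' Rank the competing consumers of a precursor metabolite
#'
#' Finds every reaction consuming `substrate` in the model, attaches
#' expression-scaled Vmax values (see [vmax_bound()]) and catalytic-rate
#' shares over a grid of substrate concentrations, and ranks the consumers
#' by Vmax (rank 1 = largest; ties broken by lexicographic reaction id).
#' Multi-reaction enzymes are additionally aggregated per gene.
#'
#' @inheritParams vmax_constraints
#' @param substrate metabolite id (e.g. `"dmapp_c"`).
#' @param s_grid substrate concentrations (mM) for the PRate columns;
#'   default logarithmic, 1e-3 to 1e2, 6 points.
#' @param unknown consumer reaction ids explicitly marked as lacking
#'   kinetics; excluded from PRate normalization, listed separately.
#' @return a `branch_report`: list with `table` (per consumer reaction:
#'   gene, kcat, Km, TPM, Vmax, rank, one `prate_*` column per grid point),
#'   `by_gene` (summed Vmax), `top` (rank-1 reaction), `top_gene`,
#'   `substrate`, `s_grid`, `unknown`.
#' @export
rank_branches <- function(model, substrate, kinetics, expression, condition,
                          theta = 1e-5,
                          s_grid = 10^seq(-3, 2, length.out = 6),
                          unknown = character()) {
  cons <- consumers_of(model, substrate)
  if (!length(cons)) stop("no reactions consume '", substrate, "'")
  tab <- vmax_table(kinetics, expression, condition, theta)
  tab <- tab[tab$reaction %in% cons, , drop = FALSE]
  covered <- union(tab$reaction, unknown)
  not_covered <- setdiff(cons, covered)
  if (length(not_covered)) {
    stop("consumer reaction(s) without kinetics and not marked unknown: ",
         paste(not_covered, collapse = ", "))
  }
  tab <- tab[order(tab$reaction), , drop = FALSE]
  pr <- sapply(s_grid, function(s) prate(tab$kcat_per_s, tab$km_mM, s))
  pr <- matrix(pr, nrow = nrow(tab),
               dimnames = list(NULL, paste0("prate_", format(s_grid, trim = TRUE,
                                                             scientific = TRUE, digits = 3))))
  # rank by Vmax, deterministic lexicographic tie-break
  ord <- order(-tab$vmax, tab$reaction)
  rank <- integer(nrow(tab)); rank[ord] <- seq_len(nrow(tab))
  out <- cbind(tab[c("reaction", "gene", "kcat_per_s", "km_mM", "tpm", "vmax")],
               rank = rank, as.data.frame(pr))
  by_gene <- stats::aggregate(vmax ~ gene, tab, sum)
  by_gene <- by_gene[order(-by_gene$vmax, by_gene$gene), , drop = FALSE]
  structure(list(table = out[order(out$rank), , drop = FALSE],
                 by_gene = by_gene,
                 top = out$reaction[out$rank == 1],
                 top_gene = by_gene$gene[1],
                 substrate = substrate, s_grid = s_grid,
                 n = nrow(tab), unknown = unknown),
            class = "branch_report")
}

#' @export
print.branch_report <- function(x, ...) {
  cat("<branch_report> substrate", x$substrate, "-", x$n, "competing consumer(s)\n")
  cat(" top-ranked:", x$top, "(gene", paste0(x$top_gene, ")"), "\n")
  print(utils::head(x$table[c("reaction", "gene", "vmax", "rank")], 10))
  invisible(x)
}

#' Write a branch report (TSV table + JSON summary)
#' @param report a `branch_report`.
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @export
write_branch_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) write_report_tsv(report$table, path_tsv)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(substrate = report$substrate,
                              top_reaction = report$top,
                              top_gene = report$top_gene,
                              n_consumers = report$n,
                              s_grid = report$s_grid,
                              unknown = report$unknown),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
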