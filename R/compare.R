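# Comparative flux analytics between two constrained models:
# FVA-interval Jaccard sorting, sampling-based differential-flux volcano,
# and metabolite production flux-sums.

#' Jaccard index of FVA intervals, sorted most-changed first
#'
#' Per shared reaction,
#' `J = |[a1,a2] n [b1,b2]| / |[a1,a2] u [b1,b2]|` with interval length as
#' the measure. Degenerate cases follow measure-theoretic convention: two
#' identical single points give `J = 1`; a single point against any other
#' interval contributes intersection length 0, hence `J = 0`.
#'
#' @param fva_a,fva_b `fva_result` objects (or data.frames with `reaction`,
#'   `min`, `max`).
#' @param tol tolerance for the identical-point rule.
#' @return data.frame `reaction`, `jaccard`, sorted ascending; attribute
#'   `"only_in"` lists reactions present in only one input.
#' @export
fva_jaccard <- function(fva_a, fva_b, tol = 1e-9) {
  shared <- intersect(fva_a$reaction, fva_b$reaction)
  ia <- match(shared, fva_a$reaction); ib <- match(shared, fva_b$reaction)
  a1 <- fva_a$min[ia]; a2 <- fva_a$max[ia]
  b1 <- fva_b$min[ib]; b2 <- fva_b$max[ib]
  inter <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  un <- pmax(a2, b2) - pmin(a1, b1)
  j <- ifelse(un > tol, inter / un,
              # both degenerate: 1 if the same point, else 0
              as.numeric(abs(a1 - b1) <= tol & abs(a2 - b2) <= tol))
  # a point inside a positive-length interval: intersection has measure 0
  out <- data.frame(reaction = shared, jaccard = j, stringsAsFactors = FALSE)
  out <- out[order(out$jaccard, out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "only_in") <- list(
    a = setdiff(fva_a$reaction, shared),
    b = setdiff(fva_b$reaction, shared))
  out
}

#' Differential-flux volcano from two sampling ensembles
#'
#' Per shared reaction column: `log2FC = log2((|mean_B| + eps) / (|mean_A| +
#' eps))`, a two-sided rank-based (Mann-Whitney) p-value, and a significance
#' flag `p < p_threshold & |log2FC| > fc_threshold`. Reactions whose mean
#' flux changes sign between the ensembles are flagged `sign_flip` and
#' excluded from the significance gate (a ratio of signed means is not
#' interpretable). The defaults are the conventional strict thresholds:
#' `p < 1e-8`, `|log2FC| > 1`.
#'
#' @param ens_a,ens_b `sampling_ensemble` matrices sharing column names;
#'   at least 30 rows each.
#' @param p_threshold,fc_threshold significance thresholds.
#' @param eps pseudo-flux guarding the ratio.
#' @return data.frame `reaction`, `mean_a`, `mean_b`, `log2fc`, `p_value`,
#'   `sign_flip`, `significant`; attribute `"n"` records the sample sizes.
#' @export
sampling_volcano <- function(ens_a, ens_b, p_threshold = 1e-8,
                             fc_threshold = 1, eps = 1e-9) {
  shared <- intersect(colnames(ens_a), colnames(ens_b))
  if (!length(shared)) stop("ensembles share no reaction columns")
  if (nrow(ens_a) < 30 || nrow(ens_b) < 30) {
    stop("need at least 30 samples per ensemble")
  }
  res <- lapply(shared, function(r) {
    xa <- ens_a[, r]; xb <- ens_b[, r]
    ma <- mean(xa); mb <- mean(xb)
    flip <- ma * mb < 0 && abs(ma) > eps && abs(mb) > eps
    l2 <- log2((abs(mb) + eps) / (abs(ma) + eps))
    if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12) {
      p <- 1  # both columns constant: no evidence by convention
      flagged <- TRUE
    } else {
      p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
      if (is.na(p)) p <- 1
      flagged <- FALSE
    }
    data.frame(reaction = r, mean_a = ma, mean_b = mb, log2fc = l2,
               p_value = p, sign_flip = flip, zero_variance = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < p_threshold &
    abs(out$log2fc) > fc_threshold & !out$sign_flip
  attr(out, "n") <- c(a = nrow(ens_a), b = nrow(ens_b))
  attr(out, "thresholds") <- c(p = p_threshold, log2fc = fc_threshold)
  out
}

#' Production flux-sum of a metabolite
#'
#' `Phi = sum_j max(S[met, j] * v_j, 0)` — total production turnover. Given a
#' sampling ensemble, one value per sample; given a flux state, a scalar.
#' With `direction = "consumption"` the negative parts are summed instead
#' (at steady state the two agree).
#'
#' @param model a `cb_model`.
#' @param x a `flux_state` or a `sampling_ensemble`.
#' @param metabolite metabolite id.
#' @param direction `"production"` (default) or `"consumption"`.
#' @return scalar or numeric vector of flux-sums.
#' @export
flux_sum <- function(model, x, metabolite, direction = c("production", "consumption")) {
  direction <- match.arg(direction)
  if (!(metabolite %in% model$metabolites$id)) {
    stop("metabolite '", metabolite, "' not in model")
  }
  srow <- as.numeric(model$stoich[metabolite, ])
  names(srow) <- model$reactions$id
  if (all(srow <= 0) && direction == "production") {
    warning("metabolite '", metabolite, "' has no producing terms")
  }
  part <- function(v) {
    contrib <- srow[names(v)] * v
    if (direction == "production") sum(pmax(contrib, 0)) else -sum(pmin(contrib, 0))
  }
  if (inherits(x, "flux_state")) {
    stopifnot(x$status == "optimal")
    part(x$fluxes)
  } else {
    apply(x[, , drop = FALSE], 1, function(row) part(stats::setNames(row, colnames(x))))
  }
}

#' Comparison report between two constrained models
#'
#' Convenience wrapper producing the three comparative views at once:
#' FVA Jaccard table, sampling volcano, and flux-sum distributions for a set
#' of queried metabolites.
#'
#' @param model_a,model_b `cb_model`s.
#' @param constraints_a,constraints_b constraint sets (or `NULL`).
#' @param metabolites metabolite ids for the flux-sum comparison.
#' @param n_samples samples per ensemble.
#' @param seed sampler seed (model B uses `seed + 1`).
#' @param fraction FVA fraction-of-optimum.
#' @param ... passed to [sampling_volcano()].
#' @return a `comparison_report` list: `jaccard`, `volcano`, `flux_sums`
#'   (per metabolite: list of two numeric vectors).
#' @export
compare_models <- function(model_a, model_b, constraints_a = NULL,
                           constraints_b = NULL, metabolites = character(),
                           n_samples = 200, seed = 1, fraction = 1.0, ...) {
  fa <- fva(model_a, constraints_a, fraction = fraction)
  fb <- fva(model_b, constraints_b, fraction = fraction)
  ja <- fva_jaccard(fa, fb)
  ea <- sample_fluxes(model_a, constraints_a, n = n_samples, seed = seed)
  eb <- sample_fluxes(model_b, constraints_b, n = n_samples, seed = seed + 1)
  vol <- sampling_volcano(ea, eb, ...)
  fs <- lapply(stats::setNames(metabolites, metabolites), function(m) {
    list(a = if (m %in% model_a$metabolites$id) flux_sum(model_a, ea, m) else NULL,
         b = if (m %in% model_b$metabolites$id) flux_sum(model_b, eb, m) else NULL)
  })
  structure(list(jaccard = ja, volcano = vol, flux_sums = fs,
                 n_samples = n_samples, fraction = fraction, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", nrow(x$jaccard), "shared reactions;",
      sum(x$volcano$significant), "significant in volcano;",
      length(x$flux_sums), "flux-sum metabolite(s)\n")
  invisible(x)
}
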