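# Hit-and-run sampling of the steady-state flux polytope.
#
# The polytope {S v = 0 (+ pins/caps), lb <= v <= ub} is parameterized as
# v = v0 + N u with N an orthonormal null-space basis of the equality rows,
# so every proposal satisfies mass balance by construction. Moves are made
# along single null-space coordinates (coordinate hit-and-run in the reduced
# space); warmup points come from the FVA extreme solutions.

#' Sample flux distributions from the feasible region
#'
#' @inheritParams fba
#' @param n number of samples to keep.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param thinning keep one sample per `thinning` chain steps.
#' @param warmup number of discarded initial steps.
#' @return a `sampling_ensemble`: numeric matrix `n x n_reactions` with
#'   attributes `seed`, `thinning`, `warmup`.
#' @export
sample_fluxes <- function(model, constraints = NULL, n = 1000, seed = 1,
                          thinning = 100, warmup = 100) {
  lp <- assemble_lp(model, constraints)
  # inequalities become equalities with slack columns so that the whole
  # region is {A x = b, l <= x <= u}
  A <- lp$Aeq; b <- lp$beq; l <- lp$lb; u <- lp$ub
  if (nrow(lp$Ale) > 0) {
    ns <- nrow(lp$Ale)
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)), cbind(lp$Ale, diag(ns)))
    b <- c(b, lp$ble)
    l <- c(l, rep(0, ns)); u <- c(u, rep(Inf, ns))
  }
  # warmup points: FVA extremes over the same polytope (objective disabled)
  fv <- fva(model, constraints, fraction = 0, keep_solutions = TRUE)
  if (any(!is.finite(fv$min)) || any(!is.finite(fv$max))) {
    stop("feasible region is unbounded; tighten the reaction bounds before sampling")
  }
  sols <- attr(fv, "solutions")
  # FVA solutions live in lp space; append slack values for the full space
  xs <- do.call(rbind, lapply(sols, function(x) {
    if (nrow(lp$Ale) > 0) {
      c(x, lp$ble - as.numeric(lp$Ale %*% x))
    } else x
  }))
  x0 <- colMeans(xs)
  # orthonormal null-space basis of A
  sv <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(sv$d > max(dim(A)) * max(sv$d) * 1e-12)
  if (rank >= ncol(A)) {
    # fully determined: the polytope is a single point
    out <- matrix(rep(x0[seq_len(lp$n_rxn)], n), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, lp$vnames[seq_len(lp$n_rxn)]))
    return(structure(out, class = c("sampling_ensemble", class(out)),
                     seed = seed, thinning = thinning, warmup = warmup))
  }
  N <- sv$v[, (rank + 1L):ncol(A), drop = FALSE]
  q <- ncol(N)
  x <- x0
  keep <- matrix(NA_real_, n, lp$n_rxn,
                 dimnames = list(NULL, lp$vnames[seq_len(lp$n_rxn)]))
  total <- warmup + n * thinning
  with_preserved_rng({
    set.seed(seed)
    coords <- sample.int(q, total, replace = TRUE)
    tu <- stats::runif(total)
    kept <- 0L
    for (step in seq_len(total)) {
      d <- N[, coords[step]]
      nz <- which(abs(d) > 1e-12)
      lo_t <- (l[nz] - x[nz]) / d[nz]
      hi_t <- (u[nz] - x[nz]) / d[nz]
      tlo <- max(pmin(lo_t, hi_t))
      thi <- min(pmax(lo_t, hi_t))
      if (!is.finite(tlo) || !is.finite(thi)) {
        stop("feasible region is unbounded along a sampling direction; ",
             "tighten the reaction bounds")
      }
      if (thi > tlo) {
        x <- x + (tlo + tu[step] * (thi - tlo)) * d
      }
      if (step > warmup && (step - warmup) %% thinning == 0L) {
        kept <- kept + 1L
        keep[kept, ] <- x[seq_len(lp$n_rxn)]
        if (kept %% 100L == 0L) {
          # guard against drift off the affine subspace
          x <- x0 + as.numeric(N %*% crossprod(N, x - x0))
          x <- pmin(pmax(x, l), u)
        }
      }
    }
  })
  structure(keep, class = c("sampling_ensemble", class(keep)),
            seed = seed, thinning = thinning, warmup = warmup)
}

# run code with the global RNG state restored afterwards
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
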