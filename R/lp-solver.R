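# Bounded-variable primal simplex.
#
# Solves   max/min  c'x   s.t.  Aeq x = beq,  Ale x <= ble,  lb <= x <= ub
# with lb/ub possibly infinite (free variables rest at 0 while nonbasic).
# Two phases: phase 1 drives artificial variables out of the basis, phase 2
# optimizes the user objective. Bland's smallest-index rule throughout, so the
# solve is deterministic and cannot cycle; problem sizes in this package are
# tiny (tens of variables), so the O(m^3) per-iteration refactorization is a
# non-issue.

#' Solve a linear program
#'
#' Internal LP core used by [fba()], [fva()], [baseline_flux()] and the sweep
#' simulators. Exposed because the test-suite oracles exercise it directly.
#'
#' @param obj objective coefficient vector, length `n`.
#' @param Aeq,beq equality constraints `Aeq x = beq` (matrix may be `NULL`).
#' @param Ale,ble inequality constraints `Ale x <= ble` (may be `NULL`).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize maximize (`TRUE`, default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, length `n`) and `objective`.
#' @keywords internal
#' @export
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  A <- matrix(0, 0, n); b <- numeric(0)
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    A <- as.matrix(Aeq); b <- as.numeric(beq)
  }
  lbx <- as.numeric(lb); ubx <- as.numeric(ub); cx <- as.numeric(obj)
  nslack <- 0L
  if (!is.null(Ale) && nrow(Ale) > 0) {
    # slack variables turn Ale x <= ble into equalities
    nslack <- nrow(Ale)
    A <- rbind(cbind(A, matrix(0, nrow(A), nslack)),
               cbind(as.matrix(Ale), diag(nslack)))
    b <- c(b, as.numeric(ble))
    lbx <- c(lbx, rep(0, nslack))
    ubx <- c(ubx, rep(Inf, nslack))
    cx <- c(cx, rep(0, nslack))
  }
  res <- simplex_bounded(cx, A, b, lbx, ubx, maximize = maximize, tol = tol)
  if (res$status == "optimal") {
    list(status = "optimal", x = res$x[seq_len(n)],
         objective = sum(obj * res$x[seq_len(n)]))
  } else {
    list(status = res$status, x = rep(NA_real_, n), objective = NA_real_)
  }
}

# core: max/min c'x s.t. A x = b, lb <= x <= ub
simplex_bounded <- function(cc, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  if (!maximize) {
    out <- simplex_bounded(-cc, A, b, lb, ub, maximize = TRUE, tol = tol)
    if (out$status == "optimal") out$objective <- -out$objective
    return(out)
  }
  n <- length(cc); m <- nrow(A)
  if (m == 0L) {
    # box problem: each variable goes to its favourable bound
    x <- ifelse(cc > tol, ub, ifelse(cc < -tol, lb, ifelse(is.finite(lb), lb, pmin(ub, 0))))
    x[!is.finite(x) & cc == 0] <- 0
    if (any(!is.finite(x) & abs(cc) > tol)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    return(list(status = "optimal", x = x, objective = sum(cc * x)))
  }

  # start nonbasic at the finite bound of smaller magnitude; free vars at 0
  start_val <- function(j) {
    l <- lb[j]; u <- ub[j]
    if (is.finite(l) && is.finite(u)) { if (abs(l) <= abs(u)) l else u }
    else if (is.finite(l)) l else if (is.finite(u)) u else 0
  }
  x <- vapply(seq_len(n), start_val, numeric(1))
  r <- b - as.numeric(A %*% x)

  # artificials: one per row, signed so their start value |r_i| >= 0
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m, m))
  lbf <- c(lb, rep(0, m)); ubf <- c(ub, rep(Inf, m))
  nf <- n + m
  basis <- (n + 1L):nf
  # status of nonbasic vars: "lb", "ub", "free0"
  nb_status <- character(nf)
  for (j in seq_len(n)) {
    nb_status[j] <- if (is.finite(lb[j]) && x[j] == lb[j]) "lb"
      else if (is.finite(ub[j]) && x[j] == ub[j]) "ub" else "free0"
  }
  xf <- c(x, abs(r))

  run_phase <- function(cvec, basis, nb_status, xf, allow_basis_art = TRUE) {
    maxit <- 20000L
    for (it in seq_len(maxit)) {
      B <- Afull[, basis, drop = FALSE]
      qrB <- qr(B)
      if (qrB$rank < m) stop("simplex: singular basis (internal error)")
      nonbasic <- setdiff(seq_len(nf), basis)
      xN <- xf[nonbasic]
      xB <- qr.coef(qrB, b - as.numeric(Afull[, nonbasic, drop = FALSE] %*% xN))
      xf[basis] <- xB
      y <- qr.coef(qr(t(B)), cvec[basis])
      d <- cvec - as.numeric(crossprod(Afull, y))
      # entering variable, Bland: smallest index among eligible
      enter <- 0L; dirn <- 0
      for (j in nonbasic) {
        s <- nb_status[j]
        if (s == "lb" && d[j] > tol) { enter <- j; dirn <- 1; break }
        if (s == "ub" && d[j] < -tol) { enter <- j; dirn <- -1; break }
        if (s == "free0" && abs(d[j]) > tol) { enter <- j; dirn <- sign(d[j]); break }
      }
      if (enter == 0L) {
        return(list(status = "optimal", basis = basis, nb_status = nb_status, xf = xf))
      }
      w <- qr.coef(qrB, Afull[, enter])
      # ratio test: entering moves by t*dirn >= 0; collect every blocking
      # candidate (row index, step, bound hit), pick minimal step, break ties
      # by smallest variable index (Bland)
      cand_row <- integer(0); cand_t <- numeric(0); cand_bd <- character(0)
      for (i in seq_len(m)) {
        wi <- dirn * w[i]
        if (wi > tol && is.finite(lbf[basis[i]])) {
          cand_row <- c(cand_row, i)
          cand_t <- c(cand_t, max((xf[basis[i]] - lbf[basis[i]]) / wi, 0))
          cand_bd <- c(cand_bd, "lb")
        } else if (wi < -tol && is.finite(ubf[basis[i]])) {
          cand_row <- c(cand_row, i)
          cand_t <- c(cand_t, max((ubf[basis[i]] - xf[basis[i]]) / (-wi), 0))
          cand_bd <- c(cand_bd, "ub")
        }
      }
      tflip <- if (is.finite(ubf[enter]) && is.finite(lbf[enter])) {
        ubf[enter] - lbf[enter]
      } else Inf
      tbest <- min(c(cand_t, tflip))
      if (!is.finite(tbest)) {
        return(list(status = "unbounded", basis = basis, nb_status = nb_status, xf = xf))
      }
      near <- which(cand_t <= tbest + 1e-12)
      leave <- 0L
      if (length(near)) {
        pick <- near[which.min(basis[cand_row[near]])]
        # prefer a pivot unless the bound flip is strictly shorter
        if (tflip < tbest - 1e-12 ||
            (tflip <= tbest + 1e-12 && enter < basis[cand_row[pick]])) {
          leave <- 0L; tbest <- tflip
        } else {
          leave <- cand_row[pick]; tbest <- cand_t[pick]
        }
      }
      xf[basis] <- xf[basis] - dirn * tbest * w
      xf[enter] <- xf[enter] + dirn * tbest
      if (leave == 0L) {
        # bound-to-bound flip of the entering variable
        nb_status[enter] <- if (dirn > 0) "ub" else "lb"
        xf[enter] <- if (dirn > 0) ubf[enter] else lbf[enter]
      } else {
        lv <- basis[leave]
        hit <- cand_bd[pick]
        nb_status[lv] <- hit
        xf[lv] <- if (hit == "lb") lbf[lv] else ubf[lv]
        basis[leave] <- enter
        nb_status[enter] <- ""
      }
    }
    stop("simplex: iteration limit reached")
  }

  # phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, nb_status, xf)
  if (ph1$status != "optimal") stop("simplex: phase 1 unbounded (internal error)")
  art_sum <- sum(ph1$xf[(n + 1L):nf])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # pin artificials at zero for phase 2 (basic ones stay at value 0)
  ubf <- c(ub, rep(0, m)); lbf <- c(lb, rep(0, m))
  nb_status <- ph1$nb_status
  for (j in (n + 1L):nf) if (!(j %in% ph1$basis)) { nb_status[j] <- "lb"; ph1$xf[j] <- 0 }
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, nb_status, ph1$xf)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  x <- ph2$xf[seq_len(n)]
  # numerical clean-up against the box
  x <- pmin(pmax(x, ifelse(is.finite(lb), lb, -Inf)), ifelse(is.finite(ub), ub, Inf))
  list(status = "optimal", x = x, objective = sum(cc * x))
}
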