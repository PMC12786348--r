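# Fixtures built in code: tiny networks, random LP instances, and the
# independent brute-force vertex-enumeration oracle the LP tests compare
# against.

# build a small model from equation strings; metabolites are auto-derived
# (compartment from the id suffix), no formulas
make_net <- function(defs, objective = numeric(), id = "net") {
  ids <- vapply(defs, `[[`, character(1), "id")
  stoich <- lapply(defs, function(d) parse_equation(d$eq)$coef)
  names(stoich) <- ids
  mets <- sort(unique(unlist(lapply(stoich, names))))
  cb_model(id,
           data.frame(id = mets, name = mets,
                      compartment = sub("^.*_", "", mets),
                      stringsAsFactors = FALSE),
           data.frame(id = ids,
                      name = ids,
                      lb = vapply(defs, function(d) d$lb %||% 0, numeric(1)),
                      ub = vapply(defs, function(d) d$ub %||% 1000, numeric(1)),
                      stringsAsFactors = FALSE),
           stoich, objective)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# linear chain EX_A -(uptake)-> a -> b -> EX_B with the uptake bottleneck
chain_model <- function(uptake = 10) {
  make_net(list(
    list(id = "EX_A", eq = "a_c ->", lb = -uptake, ub = 0),
    list(id = "AB", eq = "a_c -> b_c"),
    list(id = "EX_B", eq = "b_c ->")),
    objective = c(EX_B = 1), id = "chain")
}

# demand metabolite reachable through two parallel equal-cost paths
two_path_model <- function(demand = 10, path_ub = 1000) {
  make_net(list(
    list(id = "EX_A", eq = "a_c ->", lb = -demand, ub = -demand),
    list(id = "P1", eq = "a_c -> b_c", ub = path_ub),
    list(id = "P2", eq = "a_c -> b_c", ub = path_ub),
    list(id = "EX_B", eq = "b_c ->")),
    objective = c(EX_B = 1), id = "twopath")
}

# brute-force LP oracle: enumerate vertices of {A x = b, lb <= x <= ub}
# (finite bounds), return the maximum of obj over feasible vertices
vertex_enum_lp <- function(obj, A, b, lb, ub, tol = 1e-8) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  m <- qr(A)$rank
  nfree <- n - m
  best <- -Inf; best_x <- NULL
  if (nfree <= 0) {
    x <- qr.solve(A, b)
    if (max(abs(A %*% x - b)) < tol && all(x >= lb - tol) && all(x <= ub + tol)) {
      best <- sum(obj * x); best_x <- x
    }
    return(list(objective = best, x = best_x))
  }
  combos <- utils::combn(n, nfree)
  for (ci in seq_len(ncol(combos))) {
    Fix <- combos[, ci]
    Bas <- setdiff(seq_len(n), Fix)
    AB <- A[, Bas, drop = FALSE]
    if (qr(AB)$rank < length(Bas)) next
    for (mask in 0:(2^nfree - 1)) {
      atub <- as.logical(bitwAnd(mask, 2^(seq_len(nfree) - 1)))
      xF <- ifelse(atub, ub[Fix], lb[Fix])
      rhs <- b - as.numeric(A[, Fix, drop = FALSE] %*% xF)
      xB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[Fix] <- xF; x[Bas] <- xB
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (val > best) { best <- val; best_x <- x }
    }
  }
  list(objective = best, x = best_x)
}

# random steady-state-style LP instance with 0 feasible (b = 0, lb <= 0 <= ub)
random_lp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  m <- sample(2:(n - 2), 1)
  A <- matrix(sample(c(-2, -1, 0, 1, 2), m * n, replace = TRUE,
                     prob = c(.1, .25, .3, .25, .1)), m, n)
  ub <- round(runif(n, 1, 10), 2)
  lb <- ifelse(runif(n) < 0.4, -round(runif(n, 1, 10), 2), 0)
  obj <- round(rnorm(n), 2)
  list(obj = obj, A = A, b = rep(0, m), lb = lb, ub = ub)
}

# the toy bundle, built once per test run
toy_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_model()
    cache
  }
})

toy_preset <- function(model, truth, ...) {
  cs5_preset(model, aliases = truth$aliases,
             dmapp_producers = truth$producers, delta = truth$delta, ...)
}
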