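# FBA engine behaviour: parsimonious baseline, FVA, multi-objective
# optimization, and the hit-and-run sampler.

test_that("fba reports infeasibility when biomass is fixed above its maximum", {
  m <- chain_model(uptake = 10)
  cs <- constraint_set(fixed = data.frame(reaction = "EX_B", value = 15))
  expect_equal(fba(m, cs)$status, "infeasible")
  cs_oob <- constraint_set(fixed = data.frame(reaction = "EX_B", value = 1500))
  expect_error(fba(m, cs_oob), "outside its declared bounds")
  # within declared bounds but above the achievable optimum
  m2 <- make_net(list(
    list(id = "EX_A", eq = "a_c ->", lb = -10, ub = 0),
    list(id = "AB", eq = "a_c -> b_c", ub = 4),
    list(id = "EX_B", eq = "b_c ->")),
    objective = c(EX_B = 1))
  cs2 <- constraint_set(fixed = data.frame(reaction = "EX_B", value = 8))
  expect_equal(fba(m2, cs2)$status, "infeasible")
})

test_that("baseline flux splits two redundant equal paths 5/5 and is deterministic", {
  m <- two_path_model(demand = 10)
  st <- baseline_flux(m)
  # demand is met either way; the L1-minimal point is any split summing to 10
  expect_equal(st$fluxes[["P1"]] + st$fluxes[["P2"]], 10, tolerance = 1e-9)
  expect_equal(st$objective_value, 10, tolerance = 1e-9)
  # total |v| equals the L1 oracle on the 2-path polytope: uptake 10 +
  # paths 10 + secretion 10
  expect_equal(sum(abs(st$fluxes)), 30, tolerance = 1e-9)
  st2 <- baseline_flux(m)
  expect_equal(st$fluxes, st2$fluxes, tolerance = 1e-12)
})

test_that("baseline flux equals fba on a single-path network", {
  m <- chain_model(uptake = 7)
  a <- fba(m); b <- baseline_flux(m)
  expect_equal(b$objective_value, a$objective_value, tolerance = 1e-9)
  expect_equal(as.numeric(b$fluxes), as.numeric(a$fluxes), tolerance = 1e-9)
})

test_that("parsimonious baseline removes futile cycles FBA may carry", {
  # reversible loop b <-> c that mass balance permits at any magnitude
  m <- make_net(list(
    list(id = "EX_A", eq = "a_c ->", lb = -10, ub = 0),
    list(id = "AB", eq = "a_c -> b_c"),
    list(id = "LOOP1", eq = "b_c <=> c_c", lb = -1000),
    list(id = "LOOP2", eq = "c_c <=> b_c", lb = -1000),
    list(id = "EX_B", eq = "b_c ->")),
    objective = c(EX_B = 1))
  st <- baseline_flux(m)
  expect_equal(st$objective_value, 10, tolerance = 1e-9)
  expect_equal(st$fluxes[["LOOP1"]], 0, tolerance = 1e-9)
  expect_equal(st$fluxes[["LOOP2"]], 0, tolerance = 1e-9)
})

test_that("FVA collapses to points at fraction 1 on a chain", {
  m <- chain_model(uptake = 10)
  fv <- fva(m, fraction = 1.0)
  expect_true(all(abs(fv$max - fv$min) < 1e-8))
})

test_that("FVA spans [0, demand] for two redundant paths", {
  m <- two_path_model(demand = 10)
  fv <- fva(m, fraction = 1.0)
  for (r in c("P1", "P2")) {
    expect_equal(fv$min[fv$reaction == r], 0, tolerance = 1e-8)
    expect_equal(fv$max[fv$reaction == r], 10, tolerance = 1e-8)
  }
})

test_that("FVA intervals match per-reaction LP solves and widen as fraction drops", {
  toy <- toy_bundle()
  m <- toy$model
  fv1 <- fva(m, fraction = 1.0)
  fv9 <- fva(m, fraction = 0.9)
  # brute force: direct LP per reaction with the objective row added manually
  lp_opt <- fba(m)$objective_value
  S <- as.matrix(stoich_matrix(m))
  objrow <- as.numeric(m$reactions$id == "BIOMASS_toy")
  for (r in sample(m$reactions$id, 8)) {
    e <- as.numeric(m$reactions$id == r)
    lo <- solve_lp(e, Aeq = S, beq = rep(0, nrow(S)),
                   Ale = matrix(-objrow, 1), ble = -1.0 * lp_opt,
                   lb = m$reactions$lb, ub = m$reactions$ub, maximize = FALSE)
    hi <- solve_lp(e, Aeq = S, beq = rep(0, nrow(S)),
                   Ale = matrix(-objrow, 1), ble = -1.0 * lp_opt,
                   lb = m$reactions$lb, ub = m$reactions$ub, maximize = TRUE)
    expect_equal(fv1$min[fv1$reaction == r], lo$objective, tolerance = 1e-8)
    expect_equal(fv1$max[fv1$reaction == r], hi$objective, tolerance = 1e-8)
  }
  w1 <- fv1$max - fv1$min
  w9 <- fv9$max - fv9$min
  expect_true(all(w9 >= w1 - 1e-8))
})

test_that("weighted multi-objective with weights (1, 0) degenerates to plain fba", {
  toy <- toy_bundle()
  spec <- objective_spec(c("BIOMASS_toy", "EX_CS_OH"), mode = "weighted",
                         weights = c(1, 0))
  st <- optimize_multi(toy$model, NULL, spec)
  expect_equal(st$fluxes[["BIOMASS_toy"]], fba(toy$model)$objective_value,
               tolerance = 1e-8)
})

test_that("lexicographic multi-objective equals FVA max of the product at the biomass optimum", {
  toy <- toy_bundle()
  spec <- objective_spec(c("BIOMASS_toy", "EX_CS_OH"), slack = 1.0)
  st <- optimize_multi(toy$model, NULL, spec)
  fv <- fva(toy$model, fraction = 1.0, reactions = "EX_CS_OH")
  expect_equal(st$fluxes[["EX_CS_OH"]], fv$max, tolerance = 1e-8)
})

test_that("weighted multi-objective matches a directly assembled LP oracle", {
  toy <- toy_bundle()
  m <- toy$model
  opts <- c(fba(m, objective = "BIOMASS_toy")$objective_value,
            fba(m, objective = "EX_CS_OH")$objective_value)
  spec <- objective_spec(c("BIOMASS_toy", "EX_CS_OH"), mode = "weighted")
  st <- optimize_multi(m, NULL, spec)
  S <- as.matrix(stoich_matrix(m))
  cc <- (m$reactions$id == "BIOMASS_toy") / opts[1] +
        (m$reactions$id == "EX_CS_OH") / opts[2]
  oracle <- solve_lp(cc, Aeq = S, beq = rep(0, nrow(S)),
                     lb = m$reactions$lb, ub = m$reactions$ub)
  expect_equal(st$objective_value, oracle$objective, tolerance = 1e-8)
})

test_that("sampling is seed-deterministic and respects the polytope", {
  toy <- toy_bundle()
  s1 <- sample_fluxes(toy$model, n = 60, seed = 4, thinning = 20)
  s2 <- sample_fluxes(toy$model, n = 60, seed = 4, thinning = 20)
  expect_identical(unclass(s1), unclass(s2))
  S <- as.matrix(stoich_matrix(toy$model))
  resid <- S %*% t(s1[, colnames(S)])
  expect_lt(max(abs(resid)), 1e-6)
  rx <- toy$model$reactions
  for (r in rx$id) {
    expect_true(all(s1[, r] >= rx$lb[match(r, rx$id)] - 1e-6))
    expect_true(all(s1[, r] <= rx$ub[match(r, rx$id)] + 1e-6))
  }
  # samples stay inside the pure-feasibility FVA intervals
  fv <- fva(toy$model, fraction = 0)
  for (r in fv$reaction) {
    expect_true(all(s1[, r] >= fv$min[fv$reaction == r] - 1e-6))
    expect_true(all(s1[, r] <= fv$max[fv$reaction == r] + 1e-6))
  }
  # sample mean of the objective never beats the optimum
  expect_lte(mean(s1[, "BIOMASS_toy"]), fba(toy$model)$objective_value + 1e-6)
})

test_that("sampling refuses an unbounded region", {
  m <- make_net(list(
    list(id = "EX_A", eq = "a_c ->", lb = -10, ub = 0),
    list(id = "AB", eq = "a_c -> b_c", ub = Inf),
    list(id = "EX_B", eq = "b_c ->", ub = Inf)),
    objective = c(EX_B = 1))
  m$reactions$ub[m$reactions$id == "AB"] <- Inf
  m$reactions$ub[m$reactions$id == "EX_B"] <- Inf
  m2 <- make_net(list(
    list(id = "F", eq = "a_c <=> b_c", lb = -1000, ub = Inf),
    list(id = "G", eq = "b_c <=> a_c", lb = -1000, ub = Inf)))
  expect_error(sample_fluxes(m2, n = 10, seed = 1), "unbounded")
})
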