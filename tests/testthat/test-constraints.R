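# Expression-scaled Vmax bounds, ratio pins, grouped consumption caps, and
# the production-strain preset.

test_that("Vmax follows kcat * 3600 * theta * TPM with the conversion applied once", {
  vb <- vmax_bound(kcat = 10, tpm = 100, theta = 1e-5)
  expect_equal(vb$etotal, 1e-3, tolerance = 1e-15)
  expect_equal(vb$vmax, 36, tolerance = 1e-12)  # 10 * 3600 * 1e-3
  expect_equal(vmax_bound(10, 0, 1e-5)$vmax, 0)
  # degree-1 homogeneity in theta and TPM separately
  expect_equal(vmax_bound(10, 100, 2e-5)$vmax, 2 * 36)
  expect_equal(vmax_bound(10, 200, 1e-5)$vmax, 2 * 36)
  expect_error(vmax_bound(10, 100, 0), "theta")
  expect_error(vmax_bound(10, 100, -1), "theta")
})

test_that("vmax_constraints joins tables, sums shared reactions, errors on missing TPM", {
  toy <- toy_bundle()
  kin <- make_kinetics_table(toy$truth)
  expr <- make_expression_table(toy$truth)
  cs <- vmax_constraints(toy$model, kin, expr, "baseline",
                         theta = toy$truth$theta)
  tab <- attr(cs, "vmax")
  expect_equal(cs$bounds$ub[cs$bounds$reaction == "ADH2"], 0.2, tolerance = 1e-12)
  expect_equal(cs$bounds$ub[cs$bounds$reaction == "ALDH1"], 0.002, tolerance = 1e-12)
  kin2 <- rbind(kin, data.frame(gene = "ghost_t", reaction = "GLCt",
                                kcat_per_s = 1, km_mM = 1, source = "synthetic"))
  expect_error(vmax_constraints(toy$model, kin2, expr, "baseline"),
               "TPM missing for gene")
  expect_error(vmax_constraints(toy$model, kin, expr, "nope"), "no expression rows")
})

test_that("theta calibration makes the reference reaction's Vmax hit the target", {
  toy <- toy_bundle()
  kin <- make_kinetics_table(toy$truth)
  expr <- make_expression_table(toy$truth)
  th <- calibrate_theta(kin, expr, "baseline", "DMATT", reference_flux = 5)
  tab <- debranch:::vmax_table(kin, expr, "baseline", th)
  expect_equal(sum(tab$vmax[tab$reaction == "DMATT"]), 5, tolerance = 1e-10)
})

test_that("a 1:1 ratio pin equalizes two parallel routes", {
  m <- two_path_model(demand = 10)
  st <- fba(m, ratio_pin("P1", "P2", 1, 1))
  expect_equal(st$fluxes[["P1"]], st$fluxes[["P2"]], tolerance = 1e-8)
  expect_equal(st$fluxes[["P1"]], 5, tolerance = 1e-8)
  expect_error(ratio_pin("P1", "P2", -1, 1), "positive")
})

test_that("the 6461:1 route ratio is satisfied by the solved fluxes", {
  toy <- toy_bundle()
  st <- fba(toy$model, ratio_pin("DPMVD", "CDPMEK", 6461, 1))
  expect_equal(st$status, "optimal")
  expect_equal(st$fluxes[["DPMVD"]] / st$fluxes[["CDPMEK"]], 6461,
               tolerance = 1e-6)
})

test_that("a ratio pin is vacuously satisfied when both fluxes are forced to 0", {
  m <- two_path_model(demand = 0)
  cs <- merge_constraints(
    ratio_pin("P1", "P2", 3, 1),
    constraint_set(bounds = data.frame(reaction = c("P1", "P2"), lb = 0, ub = 0)))
  st <- fba(m, cs)
  expect_equal(st$status, "optimal")
  expect_equal(st$fluxes[["P1"]], 0, tolerance = 1e-9)
})

test_that("group caps bound consumption by delta times production", {
  # one producer (uptake 10 fixed), two consumers
  m <- make_net(list(
    list(id = "IN", eq = "-> x_c", lb = 10, ub = 10),
    list(id = "C1", eq = "x_c -> y_c"),
    list(id = "C2", eq = "x_c -> z_c"),
    list(id = "EX_Y", eq = "y_c ->"),
    list(id = "EX_Z", eq = "z_c ->")),
    objective = c(EX_Y = 1))
  st1 <- fba(m, group_cap(c("C1", "C2"), "IN", delta = 1, metabolite = "x_c"))
  expect_equal(st1$status, "optimal")
  expect_lte(st1$fluxes[["C1"]] + st1$fluxes[["C2"]], 10 + 1e-9)
  # delta = 0.4 with the producer pinned at 10: consumption caps at 4, but
  # steady state then forces infeasibility unless the pool can drain; give it
  # an overflow valve and check the cap maximum is reached exactly
  m2 <- make_net(list(
    list(id = "IN", eq = "-> x_c", lb = 10, ub = 10),
    list(id = "C1", eq = "x_c -> y_c"),
    list(id = "OVF", eq = "x_c ->"),
    list(id = "EX_Y", eq = "y_c ->")),
    objective = c(EX_Y = 1))
  st2 <- fba(m2, group_cap("C1", "IN", delta = 0.4, metabolite = "x_c"))
  expect_equal(st2$fluxes[["C1"]], 4, tolerance = 1e-8)
  expect_error(group_cap("C1", "IN", delta = 0), "delta")
  expect_error(group_cap("C1", "IN", delta = 1.2), "delta")
  expect_error(group_cap("C1", "C1", delta = 0.5), "disjoint")
  expect_error(group_cap(character(), "IN", 0.5), "non-empty")
})

test_that("a complete-set cap at delta = 1 is redundant under steady state", {
  toy <- toy_bundle()
  m <- toy$model
  cap <- group_cap(consumers_of(m, "gpp_c"), producers_of(m, "gpp_c"),
                   delta = 1, metabolite = "gpp_c")
  expect_equal(fba(m, cap)$objective_value, fba(m)$objective_value,
               tolerance = 1e-8)
})

test_that("adding constraints never increases the optimum", {
  toy <- toy_bundle()
  m <- toy$model
  base <- fba(m)$objective_value
  set.seed(7)
  for (i in 1:12) {
    r <- sample(m$reactions$id[m$reactions$lb >= 0], 1)
    ub0 <- m$reactions$ub[m$reactions$id == r]
    cs <- constraint_set(bounds = data.frame(reaction = r, lb = 0,
                                             ub = runif(1, 0, ub0)))
    st <- fba(m, cs)
    if (st$status == "optimal") expect_lte(st$objective_value, base + 1e-8)
  }
})

test_that("the production-strain preset carries the preset values and solves to them", {
  toy <- toy_bundle()
  ps <- toy_preset(toy$model, toy$truth)
  expect_equal(ps$fixed$value[ps$fixed$reaction == "BIOMASS_toy"], 1.706)
  expect_equal(ps$bounds$lb[ps$bounds$reaction == "EX_glc__D_e"], -20)
  expect_equal(ps$bounds$lb[ps$bounds$reaction == "EX_CS_OH"], 0.0023)
  expect_equal(ps$ratios$a, 6461); expect_equal(ps$ratios$b, 1)
  expect_equal(ps$group_caps[[1]]$delta, 0.4)
  st <- fba(toy$model, ps)
  expect_equal(st$fluxes[["BIOMASS_toy"]], 1.706, tolerance = 1e-6)
  expect_gte(st$fluxes[["EX_CS_OH"]], 0.0023 - 1e-9)
  expect_lte(abs(st$fluxes[["EX_glc__D_e"]]), 20 + 1e-9)
  # renamed ids through the alias map give identical content
  m2 <- toy$model
  m2$reactions$id[m2$reactions$id == "DPMVD"] <- "MVD_alt"
  colnames(m2$stoich)[colnames(m2$stoich) == "DPMVD"] <- "MVD_alt"
  ps2 <- cs5_preset(m2, aliases = c(biomass = "BIOMASS_toy",
                                    mva_ratio_rxn = "MVD_alt"),
                    dmapp_producers = c("MEPL", "MVD_alt"))
  expect_equal(ps2$ratios$rxn_a, "MVD_alt")
  expect_equal(sort(names(ps2)), sort(names(ps)))
  # missing ids without aliases are a configuration error listing candidates
  expect_error(cs5_preset(toy$core, dmapp_producers = "MEPL"),
               "provide aliases")
})

test_that("constraint sets round-trip through YAML", {
  toy <- toy_bundle()
  ps <- toy_preset(toy$model, toy$truth)
  f <- tempfile(fileext = ".yaml")
  write_constraints_yaml(ps, f)
  back <- read_constraints_yaml(f)
  expect_equal(back$fixed$value, ps$fixed$value)
  expect_equal(back$ratios$a, ps$ratios$a)
  expect_equal(back$group_caps[[1]]$delta, ps$group_caps[[1]]$delta)
  expect_equal(back$group_caps[[1]]$rhs_value, ps$group_caps[[1]]$rhs_value)
  expect_setequal(back$group_caps[[1]]$consumers, ps$group_caps[[1]]$consumers)
  st_a <- fba(toy$model, ps); st_b <- fba(toy$model, back)
  expect_equal(st_a$objective_value, st_b$objective_value, tolerance = 1e-9)
  unlink(f)
})
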