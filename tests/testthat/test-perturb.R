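# Knockdown and overexpression simulators.

kd_setup <- function() {
  toy <- toy_bundle()
  cs <- toy_preset(toy$model, toy$truth, fix_biomass = FALSE)
  list(toy = toy, cs = cs)
}

test_that("knockdown: factor-1 fold-change is exactly 1 and the sweep is monotone", {
  s <- kd_setup()
  kd <- simulate_knockdown(s$toy$model, s$cs,
                           targets = s$toy$truth$knockdown_targets,
                           product = "EX_CS_OH", factors = 2^(0:8))
  expect_identical(kd$fold_change[kd$factor == 1], 1)
  ok <- kd$status == "optimal"
  expect_true(all(ok))
  # debranching: freeing the precursor cannot hurt the product
  expect_true(all(diff(kd$flux_cs[ok][order(kd$factor[ok])]) >= -1e-8))
  # growth declines as the essential branch tightens but stays positive
  expect_true(all(kd$biomass[ok] > 0))
  expect_true(all(diff(kd$biomass[ok][order(kd$factor[ok])]) <= 1e-8))
})

test_that("knockdown rows equal an independent per-factor LP solve", {
  s <- kd_setup()
  base <- baseline_flux(s$toy$model, s$cs, "BIOMASS_toy")
  kd <- simulate_knockdown(s$toy$model, s$cs,
                           targets = c("DMATT", "GRTT"),
                           product = "EX_CS_OH", factors = c(1, 4, 16))
  for (k in c(4, 16)) {
    bnds <- data.frame(reaction = c("DMATT", "GRTT"), lb = 0,
                       ub = abs(base$fluxes[c("DMATT", "GRTT")]) / k)
    cs_k <- merge_constraints(s$cs, constraint_set(bounds = bnds))
    # oracle: two sequential LP solves (biomass, then product at 0.999)
    b1 <- fba(s$toy$model, cs_k, "BIOMASS_toy")
    cs_fix <- merge_constraints(cs_k, constraint_set(bounds = data.frame(
      reaction = "BIOMASS_toy", lb = 0.999 * b1$objective_value, ub = Inf)))
    b2 <- fba(s$toy$model, cs_fix, "EX_CS_OH")
    expect_equal(kd$flux_cs[kd$factor == k], b2$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("full knockout of the essential branch abolishes growth", {
  s <- kd_setup()
  ko <- merge_constraints(s$cs, constraint_set(bounds = data.frame(
    reaction = c("DMATT", "GRTT"), lb = 0, ub = 0)))
  st <- fba(s$toy$model, ko)
  expect_true(st$status != "optimal" || st$objective_value < 1e-9)
})

test_that("degenerate knockdown (zero baseline target flux) warns", {
  s <- kd_setup()
  expect_warning(
    simulate_knockdown(s$toy$model, s$cs, targets = "NUDX2",
                       product = "EX_CS_OH", factors = c(1, 2)),
    "degenerate")
})

test_that("yield improvement ratios follow the arithmetic", {
  s <- kd_setup()
  kd <- simulate_knockdown(s$toy$model, s$cs,
                           targets = c("DMATT", "GRTT"),
                           product = "EX_CS_OH", factors = c(1, 2, 4))
  yi <- yield_improvement(kd)
  expect_equal(yi$ratio, kd$flux_cs / kd$flux_cs[kd$factor == 1],
               tolerance = 1e-12)
  expect_equal(attr(yi, "max_ratio"), max(yi$ratio))
  # 0.0023 -> 0.0060 is a 2.609-fold improvement
  fake <- kd[1:2, ]; fake$factor <- c(1, 16)
  fake$flux_cs <- c(0.0023, 0.0060)
  class(fake) <- class(kd)
  expect_equal(yield_improvement(fake)$ratio[2], 0.0060 / 0.0023,
               tolerance = 1e-12)
  expect_equal(round(yield_improvement(fake)$ratio[2], 3), 2.609)
  # zero baseline: sentinel, no division
  fake$flux_cs <- c(0, 0.005)
  expect_warning(yi0 <- yield_improvement(fake), "undefined")
  expect_true(all(is.na(yi0$ratio)))
})

test_that("RVmax follows kcat and expression with the stated edge cases", {
  expect_equal(rvmax_ratio(3, 3, 10, 10), 1)
  expect_equal(rvmax_ratio(4, 2, 3, 6), 1)
  expect_equal(rvmax_ratio(4, 2, 0, 6), 0)
  expect_error(rvmax_ratio(4, 2, 3, 0), "positive")
})

test_that("overexpression sweep: identity at n = 1, monotone, f1 flat, f2 limiting", {
  toy <- toy_bundle()
  cs <- toy_preset(toy$model, toy$truth)
  tr <- toy$truth
  oe <- sweep_overexpression(toy$model, cs, tr$f1, tr$f2,
                             f1_base = tr$f1_base, f2_base = tr$f2_base,
                             product = tr$product_acid)
  # baseline cell reproduces the baseline product flux
  st <- optimize_multi(toy$model,
    merge_constraints(cs, constraint_set(bounds = data.frame(
      reaction = c(tr$f1, tr$f2), lb = 0, ub = c(tr$f1_base, tr$f2_base)))),
    objective_spec(c("BIOMASS_toy", tr$product_acid)))
  expect_equal(oe$grid[1, 1], st$fluxes[[tr$product_acid]], tolerance = 1e-8)
  # monotone non-decreasing in each axis
  expect_true(all(apply(oe$grid, 1, function(r) all(diff(r) >= -1e-8))))
  expect_true(all(apply(oe$grid, 2, function(r) all(diff(r) >= -1e-8))))
  # the alcohol-dehydrogenase step alone changes nothing (f2 binds) ...
  expect_true(all(abs(oe$f1_curve - oe$f1_curve[1]) < 1e-8))
  # ... while the aldehyde step increases the yield until the upstream
  # bottleneck binds, strictly at first
  expect_gt(oe$f2_curve[2], oe$f2_curve[1] + 1e-8)
  expect_gt(oe$f2_curve[3], oe$f2_curve[2] + 1e-8)
  expect_lt(oe$f2_curve[length(oe$f2_curve)] - oe$f2_curve[length(oe$f2_curve) - 1], 1e-6)
  # joint relaxation dominates the single-axis relaxations
  for (i in seq_along(oe$n_grid)) {
    expect_gte(oe$joint_curve[i], max(oe$f1_curve[i], oe$f2_curve[i]) - 1e-8)
  }
  expect_equal(oe$rvmax, tr$f1_base / tr$f2_base)
})

test_that("sweeps are deterministic across repeated runs", {
  toy <- toy_bundle()
  cs <- toy_preset(toy$model, toy$truth, fix_biomass = FALSE)
  kd1 <- simulate_knockdown(toy$model, cs, product = "EX_CS_OH",
                            factors = c(1, 2, 4))
  kd2 <- simulate_knockdown(toy$model, cs, product = "EX_CS_OH",
                            factors = c(1, 2, 4))
  expect_equal(as.data.frame(kd1), as.data.frame(kd2), tolerance = 1e-12)
})
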