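# Comparative analytics: FVA-interval Jaccard, sampling volcano, flux-sums.

test_that("interval Jaccard handles the analytic cases exactly", {
  a <- data.frame(reaction = c("R1", "R2", "R3", "R4", "R5"),
                  min = c(0, 0, 0, 1, 1), max = c(2, 2, 2, 1, 1))
  b <- data.frame(reaction = c("R1", "R2", "R3", "R4", "R5"),
                  min = c(0, 5, 1, 1, 2), max = c(2, 7, 3, 1, 2))
  j <- fva_jaccard(a, b)
  expect_equal(j$jaccard[j$reaction == "R1"], 1)    # identical intervals
  expect_equal(j$jaccard[j$reaction == "R2"], 0)    # disjoint
  expect_equal(j$jaccard[j$reaction == "R3"], 1 / 3)  # [0,2] vs [1,3]
  expect_equal(j$jaccard[j$reaction == "R4"], 1)    # identical single points
  expect_equal(j$jaccard[j$reaction == "R5"], 0)    # distinct single points
  # a point inside a positive-length interval has measure-zero intersection
  a2 <- data.frame(reaction = "R", min = 1, max = 1)
  b2 <- data.frame(reaction = "R", min = 0, max = 2)
  expect_equal(fva_jaccard(a2, b2)$jaccard, 0)
  # sorted ascending, most-changed first
  expect_equal(j$jaccard, sort(j$jaccard))
})

test_that("Jaccard is symmetric, bounded, and restricted to the shared set", {
  set.seed(3)
  a <- data.frame(reaction = paste0("R", 1:20),
                  min = rnorm(20), max = NA)
  a$max <- a$min + runif(20, 0, 3)
  b <- data.frame(reaction = paste0("R", 5:24),
                  min = rnorm(20), max = NA)
  b$max <- b$min + runif(20, 0, 3)
  jab <- fva_jaccard(a, b); jba <- fva_jaccard(b, a)
  expect_equal(jab$jaccard[order(jab$reaction)],
               jba$jaccard[order(jba$reaction)])
  expect_true(all(jab$jaccard >= 0 & jab$jaccard <= 1))
  expect_setequal(jab$reaction, paste0("R", 5:20))
  expect_setequal(attr(jab, "only_in")$a, paste0("R", 1:4))
})

test_that("volcano of an ensemble against itself finds nothing", {
  toy <- toy_bundle()
  e <- sample_fluxes(toy$model, n = 60, seed = 9, thinning = 10)
  v <- sampling_volcano(e, e)
  expect_true(all(abs(v$log2fc) < 1e-12))
  expect_false(any(v$significant))
})

test_that("a constructed 4x shift is called at log2FC = 2 and significant", {
  set.seed(11)
  base <- matrix(abs(rnorm(1000 * 3, mean = 5)), 1000, 3,
                 dimnames = list(NULL, c("R1", "R2", "R3")))
  shifted <- base
  shifted[, "R2"] <- 4 * base[, "R2"]
  v <- sampling_volcano(base, shifted)
  expect_equal(v$log2fc[v$reaction == "R2"], 2, tolerance = 1e-3)
  expect_true(v$significant[v$reaction == "R2"])
  expect_false(any(v$significant[v$reaction != "R2"]))
  # the defaults are the strict gate thresholds
  expect_equal(unname(attr(v, "thresholds")), c(1e-8, 1))
  expect_equal(unname(formals(sampling_volcano)$p_threshold), 1e-8)
  expect_equal(unname(formals(sampling_volcano)$fc_threshold), 1)
})

test_that("sign flips are flagged and excluded; constant columns get p = 1", {
  set.seed(12)
  a <- cbind(R1 = rnorm(50, 2), R2 = rep(1, 50))
  b <- cbind(R1 = rnorm(50, -2), R2 = rep(1, 50))
  v <- sampling_volcano(a, b)
  expect_true(v$sign_flip[v$reaction == "R1"])
  expect_false(v$significant[v$reaction == "R1"])
  expect_equal(v$p_value[v$reaction == "R2"], 1)
  expect_true(v$zero_variance[v$reaction == "R2"])
  expect_error(sampling_volcano(a[1:10, ], b), "at least 30")
})

test_that("flux-sums add producer contributions with positive parts only", {
  toy <- toy_bundle()
  m <- toy$model
  st <- fba(m)
  # single producer: geraniol made only by GPPH
  expect_equal(flux_sum(m, st, "ger_c"), max(st$fluxes[["GPPH"]], 0),
               tolerance = 1e-9)
  # two producers of ipp_c: MEPL and DPMVD
  expect_equal(flux_sum(m, st, "ipp_c"),
               max(st$fluxes[["MEPL"]], 0) + max(st$fluxes[["DPMVD"]], 0),
               tolerance = 1e-9)
  # a reversible reaction flowing away from the metabolite contributes 0
  mm <- make_net(list(
    list(id = "IN", eq = "-> a_c", lb = 5, ub = 5),
    list(id = "REV", eq = "b_c <=> a_c", lb = -1000),
    list(id = "EX_B", eq = "b_c ->")),
    objective = c(EX_B = 1))
  stm <- fba(mm)
  expect_lt(stm$fluxes[["REV"]], 0)  # runs a -> b here
  expect_equal(flux_sum(mm, stm, "a_c"), 5, tolerance = 1e-9)  # only IN produces
  expect_warning(flux_sum(mm, stm, "a_c", direction = "production"), NA)
})

test_that("production and consumption flux-sums balance for every sample", {
  toy <- toy_bundle()
  e <- sample_fluxes(toy$model, n = 40, seed = 2, thinning = 10)
  for (met in c("dmapp_c", "ipp_c", "gpp_c")) {
    prod <- flux_sum(toy$model, e, met, "production")
    cons <- flux_sum(toy$model, e, met, "consumption")
    expect_equal(prod, cons, tolerance = 1e-6)
  }
})

test_that("compare_models bundles the three views", {
  toy <- toy_bundle()
  cmp <- compare_models(toy$core, toy$model, metabolites = c("ger_c", "far_c"),
                        n_samples = 40, seed = 5)
  expect_s3_class(cmp, "comparison_report")
  expect_true(all(cmp$jaccard$jaccard >= 0 & cmp$jaccard$jaccard <= 1))
  expect_setequal(cmp$jaccard$reaction,
                  intersect(toy$core$reactions$id, toy$model$reactions$id))
  expect_equal(length(cmp$flux_sums$ger_c$a), 40)
})
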