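test_that("a fixed seed reproduces the simulated screen exactly", {
  cfg <- simConfig(n_genes = 30, n_safe_harbor = 10, n_non_targeting = 10,
                   depth = 100, seed = 77)
  se1 <- simulateScreen(cfg)
  se2 <- simulateScreen(cfg)
  expect_identical(counts(se1), counts(se2))
  expect_identical(rowData(se1)$fitness, rowData(se2)$fitness)
})

test_that("control guides are always neutral and a neutral pool centres at zero", {
  cfg <- simConfig(n_genes = 50, n_safe_harbor = 20, n_non_targeting = 20,
                   depth = 2000, dispersion = 0.01,
                   effect_model = data.frame(class = "neutral", fitness = 0,
                                             fraction = 1),
                   seed = 5)
  se <- simulateScreen(cfg)
  expect_true(all(rowData(se)$fitness[guideClass(se) != "targeting"] == 0))
  res <- diffSel(se, reference = paste0("2D_Day0_r", 1:3),
                 comparison = paste0("2D_Day20_r", 1:2))
  expect_lt(mean(abs(res$lfc), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(res$lfc, na.rm = TRUE)), 0.1)
})

test_that("estimated fold change recovers the closed-form d*f of a planted guide", {
  # one strongly depleting gene among neutrals; d = 7 doublings
  cfg <- simConfig(n_genes = 200, n_safe_harbor = 50, n_non_targeting = 50,
                   subsets = "SET1", depth = 1000, dispersion = 0.01,
                   effect_model = data.frame(
                     class = c("neutral", "disadvantage"),
                     fitness = c(0, -0.5), fraction = c(0.995, 0.005)),
                   samples = chemicalLayout(n_control = 3, n_treated = 3),
                   seed = 12)
  se <- simulateScreen(cfg)
  planted <- which(rowData(se)$fitness == -0.5)
  expect_gt(length(planted), 0L)
  res <- diffSel(se, reference = paste0("2D_Cont_r", 1:3),
                 comparison = paste0("2D_Doxo_r", 1:3))
  for (i in planted) {
    ci <- res$lfc[i] + c(-1.96, 1.96) * res$se[i]
    expect_gt(-3.5, ci[1])
    expect_lt(-3.5, ci[2])
  }
})

test_that("tighter bottlenecks inflate replicate-to-replicate variance", {
  lfc_var <- function(coverage, seed) {
    cfg <- simConfig(n_genes = 40, n_safe_harbor = 15, n_non_targeting = 15,
                     subsets = "SET1", coverage = coverage, depth = 400,
                     dispersion = 0.01,
                     effect_model = data.frame(class = "neutral",
                                               fitness = 0, fraction = 1),
                     seed = seed)
    se <- simulateScreen(cfg)
    k <- sweep(counts(se), 2L, controlSizeFactors(se), "/")
    base <- rowMeans(k[, 1:3])
    keep <- base > 0
    lfc <- log2((k[keep, 4:5] + 0.5) / (base[keep] + 0.5))
    mean(apply(lfc, 1L, var))
  }
  seeds <- 1:20
  tight <- vapply(seeds, function(s) lfc_var(5, s), 0)
  loose <- vapply(seeds, function(s) lfc_var(500, s + 1000L), 0)
  # rank comparison over >= 20 replicate simulations
  expect_gt(mean(tight), mean(loose))
  expect_gt(mean(outer(tight, loose, ">")), 0.8)
})

test_that("misconfigured simulations are rejected", {
  expect_error(simConfig(effect_model = data.frame(
    class = c("neutral", "disadvantage"), fitness = c(0, -0.5),
    fraction = c(0.8, 0.1))), "sum to 1")
  expect_error(simConfig(coverage = 0), "coverage")
  expect_error(simConfig(dispersion = -1), "dispersion")
  lib <- tiny_library()
  expect_error(simulateFastq(lib, c(1, 0, 0, 0), n_reads = 10,
                             read_length = 15), "read_length")
  expect_error(simulateFastq(lib, c(2, 0, 0, 0), n_reads = 10),
               "summing to 1")
})

test_that("expected fold changes are d*f for selected arms and 0 elsewhere", {
  cfg <- simConfig(n_genes = 10, n_safe_harbor = 5, n_non_targeting = 5,
                   depth = 50, seed = 2)
  se <- simulateScreen(cfg)
  el <- expectedLfc(se)
  expect_equal(dim(el), dim(se))
  expect_true(all(el[, colData(se)$arm == "baseline"] == 0))
  d30 <- which(colData(se)$day == 30)[1]
  expect_equal(el[, d30], rowData(se)$fitness * 15)
})
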