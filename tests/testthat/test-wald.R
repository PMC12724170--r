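test_that("identical groups give zero fold change and p near 1", {
  k <- matrix(rep(c(50L, 120L), each = 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  res <- waldTestGuides(k, rep(1, 4), 0.05, reference = c("s1", "s2"),
                        comparison = c("s3", "s4"))
  expect_equal(res$lfc, c(0, 0), tolerance = 1e-10)
  expect_equal(res$p, c(1, 1), tolerance = 1e-8)
})

test_that("a 4x count ratio with equal size factors gives lfc exactly 2", {
  k <- matrix(c(25L, 25L, 100L, 100L), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  res <- waldTestGuides(k, rep(1, 4), 0.1, reference = c("s1", "s2"),
                        comparison = c("s3", "s4"))
  expect_equal(res$lfc, 2, tolerance = 1e-8)
})

test_that("IRLS estimates match a brute-force likelihood oracle to 1e-6", {
  set.seed(31)
  sf <- c(0.8, 1.1, 0.9, 1.3)
  x <- c(0, 0, 1, 1)
  alphas <- c(0.02, 0.1, 0.5)
  k <- nb_two_group(9, mu_a = 150, mu_b = 40, n_a = 2, n_b = 2,
                    alpha = 0.1, sf = sf, seed = 31)
  for (a in alphas) {
    res <- waldTestGuides(k, sf, a, reference = c("A1", "A2"),
                          comparison = c("B1", "B2"))
    for (i in seq_len(nrow(k))) {
      orc <- oracle_nb_fit(k[i, ], sf, x, a)
      expect_equal(res$lfc[i], orc$b1 / log(2), tolerance = 1e-6)
      expect_equal(res$se[i], orc$se1 / log(2), tolerance = 1e-4)
    }
  }
})

test_that("a group of all zeros is fitted with a flagged pseudocount, all-zero guides are untested", {
  k <- matrix(c(80L, 120L, 0L, 0L,
                0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gdead", "gnone"), sprintf("s%d", 1:4)))
  res <- waldTestGuides(k, rep(1, 4), 0.05, reference = c("s1", "s2"),
                        comparison = c("s3", "s4"))
  expect_true(res["gdead", "zeroGroup"])
  expect_true(is.finite(res["gdead", "lfc"]))
  expect_lt(res["gdead", "lfc"], -5)
  expect_false(res["gnone", "tested"])
  expect_true(is.na(res["gnone", "lfc"]))
})

test_that("BH adjustment follows the hand-computed step-up rule", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.037), 0.037)
  expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
  # missing values propagate and are excluded from the test count
  p <- c(0.01, NA, 0.02)
  expect_equal(adjustBH(p), c(0.02, NA, 0.02))
})

test_that("p-values are calibrated under the global null with known dispersion", {
  # fraction with p < 0.05 within 3 binomial SDs of 0.05
  n <- 800
  k <- nb_two_group(n, mu_a = 500, mu_b = 500, n_a = 3, n_b = 3,
                    alpha = 0.05, seed = 33)
  res <- waldTestGuides(k, rep(1, 6), 0.05,
                        reference = c("A1", "A2", "A3"),
                        comparison = c("B1", "B2", "B3"))
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("BH discoveries under the global null are essentially absent across seeds", {
  hits <- vapply(1:20, function(s) {
    k <- nb_two_group(200, mu_a = 300, mu_b = 300, n_a = 2, n_b = 2,
                      alpha = 0.05, seed = 100 + s)
    res <- waldTestGuides(k, rep(1, 4), 0.05,
                          reference = c("A1", "A2"),
                          comparison = c("B1", "B2"))
    sum(res$padj < 0.05, na.rm = TRUE)
  }, 0)
  expect_lte(sum(hits), 0.01 * 20 * 200)
})

test_that("fold-change estimates track the truth across a simulated screen", {
  cfg <- simConfig(n_genes = 300, n_safe_harbor = 50, n_non_targeting = 50,
                   subsets = "SET1", depth = 500, dispersion = 0.05,
                   samples = chemicalLayout(n_control = 2, n_treated = 2),
                   seed = 44)
  se <- simulateScreen(cfg)
  res <- diffSel(se, reference = c("2D_Cont_r1", "2D_Cont_r2"),
                 comparison = c("2D_Doxo_r1", "2D_Doxo_r2"))
  truth <- rowData(se)$fitness * 7
  ok <- res$tested
  slope <- coef(lm(res$lfc[ok] ~ truth[ok]))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("malformed contrasts are rejected", {
  k <- nb_two_group(5, 100, 100, seed = 1)
  expect_error(waldTestGuides(k, rep(1, 4), 0.1, c("A1", "B1"), c("B1", "B2")),
               "disjoint")
  expect_error(waldTestGuides(k, rep(1, 4), 0.1, character(0), c("B1")),
               "non-empty|disjoint")
  expect_error(adjustBH(c(0.2, 1.7)), "0, 1")
})
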