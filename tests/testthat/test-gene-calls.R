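guide_calls <- function(ids, sig, dir) {
  S4Vectors::DataFrame(sgrna_id = ids, significant = sig, direction = dir)
}

test_that("one significant guide out of two suffices to call the gene", {
  lib <- tiny_library()
  gc <- guide_calls(guideIds(lib),
                    sig = c(TRUE, FALSE, FALSE, FALSE),
                    dir = c("depleted", "none", "none", "none"))
  genes <- callGenes(gc, lib, label = "d20")
  expect_equal(nrow(genes), 1L)  # controls excluded
  expect_true(genes$significant[1])
  expect_equal(genes$direction[1], "depleted")
  expect_equal(genes$n_sig_guides[1], 1L)
  expect_equal(genes$supporting[1], "geneA_SET1")
})

test_that("genes with no significant guide are not called", {
  lib <- tiny_library()
  gc <- guide_calls(guideIds(lib), sig = rep(FALSE, 4), dir = rep("none", 4))
  genes <- callGenes(gc, lib)
  expect_false(genes$significant[1])
  expect_equal(genes$direction[1], "none")
})

test_that("opposing significant guides yield an ambiguous gene, never a vote", {
  lib <- tiny_library()
  gc <- guide_calls(guideIds(lib),
                    sig = c(TRUE, TRUE, FALSE, FALSE),
                    dir = c("depleted", "enriched", "none", "none"))
  genes <- callGenes(gc, lib)
  expect_true(genes$significant[1])
  expect_equal(genes$direction[1], "ambiguous")
  expect_equal(genes$n_sig_guides[1], 2L)
})

test_that("unknown guide ids are a reference error and calls cite real guides", {
  lib <- tiny_library()
  gc <- guide_calls(c("phantom", guideIds(lib)[-1]),
                    sig = c(TRUE, FALSE, FALSE, FALSE),
                    dir = c("depleted", "none", "none", "none"))
  expect_error(callGenes(gc, lib), "phantom")

  # soundness: every significant gene cites >= 1 significant input guide
  set.seed(81)
  n <- 40
  ids <- sprintf("g%02d_%s", rep(1:(n / 2), 2), rep(c("SET1", "SET2"), each = n / 2))
  lib2 <- GuideLibrary(ids, rand_spacers(n),
                       gene = rep(sprintf("gene%02d", 1:(n / 2)), 2),
                       class = "targeting",
                       subset = rep(c("SET1", "SET2"), each = n / 2))
  sig <- runif(n) < 0.3
  dir <- ifelse(sig, sample(c("depleted", "enriched"), n, TRUE), "none")
  genes <- callGenes(guide_calls(ids, sig, dir), lib2)
  for (i in which(genes$significant)) {
    cited <- strsplit(genes$supporting[i], ",")[[1]]
    expect_gte(length(cited), 1L)
    expect_true(all(sig[match(cited, ids)]))
  }
  expect_equal(sum(genes$significant),
               length(unique(rep(sprintf("gene%02d", 1:(n / 2)), 2)[sig])))
})

test_that("time-course labels follow consistent monotone selection", {
  # printed worked examples: consistent depletion, tie-enrichment, flat, non-monotone
  expect_equal(classifyTimeCourse(-2.86, -3.15, TRUE, TRUE), "disadvantage")
  expect_equal(classifyTimeCourse(1.08, 1.08, TRUE, TRUE), "advantage")
  expect_equal(classifyTimeCourse(0, 0, TRUE, TRUE), "none")
  expect_equal(classifyTimeCourse(-2.0, -1.5, TRUE, TRUE), "none")
  # significance gating
  expect_equal(classifyTimeCourse(-2.86, -3.15, TRUE, FALSE, TRUE), "none")
  expect_equal(classifyTimeCourse(-2.86, -3.15, TRUE, FALSE, FALSE),
               "disadvantage")
})

test_that("sign-flipping all fold changes swaps disadvantage and advantage", {
  set.seed(82)
  l20 <- rnorm(200); l30 <- l20 + rnorm(200, sd = 0.5)
  lab <- classifyTimeCourse(l20, l30, TRUE, TRUE)
  flipped <- classifyTimeCourse(-l20, -l30, TRUE, TRUE)
  expect_identical(flipped[lab == "disadvantage"],
                   rep("advantage", sum(lab == "disadvantage")))
  expect_identical(flipped[lab == "advantage"],
                   rep("disadvantage", sum(lab == "advantage")))
  expect_identical(lab == "none", flipped == "none")
})

test_that("chemical phenotypes map depletion to sensitive and enrichment to resistant", {
  gcalls <- S4Vectors::DataFrame(
    gene = c("gS", "gR", "gN", "gA"),
    significant = c(TRUE, TRUE, FALSE, TRUE),
    direction = c("depleted", "enriched", "none", "ambiguous"))
  chem <- classifyChemical(gcalls)
  expect_equal(as.character(chem$phenotype),
               c("sensitive", "resistant", "none", "none"))
})

test_that("condition overlaps count shared and concordant genes", {
  mk <- function(genes, dirs) S4Vectors::DataFrame(
    gene = genes, significant = TRUE, direction = dirs)
  # disjoint sets
  ov <- compareConditions(mk("g1", "depleted"), mk("g2", "depleted"))
  expect_equal(ov$shared, 0L)
  # identical sets
  ov <- compareConditions(mk(c("g1", "g2"), c("depleted", "enriched")),
                          mk(c("g1", "g2"), c("depleted", "enriched")))
  expect_equal(ov$shared, 2L)
  expect_equal(ov$a_only + ov$b_only, 0L)
  expect_equal(ov$concordant, 2L)
  # hand-enumerable mixed case
  ov <- compareConditions(mk(c("g1", "g2"), c("depleted", "enriched")),
                          mk(c("g2", "g3"), c("enriched", "enriched")))
  expect_equal(ov$a_only, 1L)
  expect_equal(ov$b_only, 1L)
  expect_equal(ov$shared, 1L)
  expect_equal(ov$concordant, 1L)
  expect_equal(ov$concordant_genes, "g2")
})

test_that("annotation joins preserve calls and mark absent genes as No data", {
  gcalls <- data.frame(gene = c("A", "B", "C"), significant = TRUE,
                       direction = "depleted")
  ann <- data.frame(gene = c("A", "C"), status = c("Essential", "Hit"),
                    score = c(-1.2, 0.4))
  out <- annotateCalls(gcalls, ann)
  expect_equal(nrow(out), 3L)
  expect_equal(out$status, c("Essential", "No data", "Hit"))
  expect_true(is.na(out$score[2]))

  # empty annotation: everything No data
  empty <- data.frame(gene = character(0), status = character(0))
  out2 <- annotateCalls(gcalls, empty)
  expect_equal(out2$status, rep("No data", 3))

  # duplicate keys refused, missing key column named
  dup <- data.frame(gene = c("A", "A"), status = c("x", "y"))
  expect_error(annotateCalls(gcalls, dup), "duplicate.*A")
  expect_error(annotateCalls(gcalls, data.frame(symbol = "A")), "gene")
})
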