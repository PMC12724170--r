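test_that("an empty FASTQ yields zero counts and zero unassigned", {
  lib <- tiny_library()
  path <- tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  res <- countSpacerReads(path, lib)
  expect_equal(unname(res$counts), rep(0L, 4))
  expect_equal(res$unassigned, 0L)
  expect_equal(res$total, 0L)
})

test_that("reads embedding one spacer at a fixed offset are all assigned to it", {
  lib <- tiny_library()
  sp <- as.character(as.data.frame(lib)$spacer)
  path <- tempfile(fileext = ".fastq")
  reads <- paste0("ACGTACGTAC", sp[1], "TTTT")  # spacer 1 at offset 10
  writeLines(as.vector(rbind(sprintf("@r%d", 1:5), rep(reads, 5), "+",
                             strrep("I", nchar(reads)))), path)
  res <- countSpacerReads(path, lib)
  expect_equal(unname(res$counts), c(5L, 0L, 0L, 0L))
  expect_equal(res$unassigned, 0L)
})

test_that("a single substitution is unassigned exactly, assigned at 1 mismatch", {
  lib <- tiny_library()
  sp <- as.character(as.data.frame(lib)$spacer)
  mut <- sp[2]
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  path <- tempfile(fileext = ".fastq")
  read <- paste0("GGGGG", mut, "CCCCC")
  writeLines(c("@r1", read, "+", strrep("I", nchar(read))), path)

  exact <- countSpacerReads(path, lib, max_mismatch = 0L)
  expect_equal(sum(exact$counts), 0L)
  expect_equal(exact$unassigned, 1L)

  fuzzy <- countSpacerReads(path, lib, max_mismatch = 1L)
  expect_equal(unname(fuzzy$counts), c(0L, 1L, 0L, 0L))
  expect_equal(fuzzy$unassigned, 0L)
})

test_that("a read matching two distinct spacers is discarded as ambiguous", {
  lib <- tiny_library()
  sp <- as.character(as.data.frame(lib)$spacer)
  path <- tempfile(fileext = ".fastq")
  read <- paste0("AA", sp[1], "TT", sp[3], "AA")
  writeLines(c("@r1", read, "+", strrep("I", nchar(read))), path)
  res <- countSpacerReads(path, lib)
  expect_equal(sum(res$counts), 0L)
  expect_equal(res$unassigned, 1L)
})

test_that("counting conserves reads and is deterministic on simulated FASTQ", {
  lib <- tiny_library()
  path <- simulateFastq(lib, c(0.4, 0.3, 0.2, 0.1), n_reads = 400,
                        read_length = 44, seed = 9)
  r1 <- countSpacerReads(path, lib)
  r2 <- countSpacerReads(path, lib)
  expect_identical(r1, r2)
  expect_equal(sum(r1$counts) + r1$unassigned, r1$total)
  expect_equal(r1$total, 400L)
  # exact matching on clean reads: allocation is recovered exactly
  expect_equal(r1$counts, attr(path, "allocation"))
})

test_that("simulated read fractions follow the multinomial expectation", {
  lib0 <- tiny_library()
  lib <- GuideLibrary(sgrna_id = guideIds(lib0)[1:2],
                      spacer = as.data.frame(lib0)$spacer[1:2],
                      gene = c("geneA", "geneA"),
                      class = "targeting", subset = c("SET1", "SET2"))
  n <- 1e5L
  path <- simulateFastq(lib, c(0.8, 0.2), n_reads = n, read_length = 40,
                        seed = 5)
  res <- countSpacerReads(path, lib)
  sd1 <- sqrt(n * 0.8 * 0.2)
  expect_lt(abs(res$counts[[1]] - n * 0.8), 3 * sd1)
  expect_lt(abs(res$counts[[2]] - n * 0.2), 3 * sd1)
})

test_that("reverse-complement orientation finds flipped reads", {
  lib <- tiny_library()
  sp <- as.character(as.data.frame(lib)$spacer)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0("AAAA", sp[1], "GGGG"))))
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", rc, "+", strrep("I", nchar(rc))), path)
  expect_equal(sum(countSpacerReads(path, lib, "forward")$counts), 0L)
  expect_equal(
    unname(countSpacerReads(path, lib, "reverse_complement")$counts),
    c(1L, 0L, 0L, 0L))
  expect_equal(
    unname(countSpacerReads(path, lib, "both")$counts),
    c(1L, 0L, 0L, 0L))
})

test_that("malformed FASTQ records are reported with their index", {
  lib <- tiny_library()
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-no-at", "ACGT", "+", "IIII"),
             path)
  expect_error(countSpacerReads(path, lib), "record at index 2")
  writeLines(c("@r1", "ACGT", "+"), path)
  expect_error(countSpacerReads(path, lib), "truncated")
  empty_lib <- GuideLibrary(character(0), character(0), gene = character(0),
                            class = character(0), subset = character(0))
  expect_error(countSpacerReads(path, empty_lib), "empty")
})
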