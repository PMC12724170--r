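#' Quantify sgRNA abundance from FASTQ reads by spacer matching
#'
#' Each read is scanned for library spacer sequences at any offset
#' (substring search). A read is assigned to a guide when it matches
#' exactly one distinct spacer; reads matching none, or matching two or
#' more distinct spacers, are counted as unassigned, so that
#' \code{sum(counts) + unassigned == total}.
#'
#' @param fastq path to a FASTQ file (4-line records; \code{.gz} accepted).
#' @param library a [GuideLibrary-class]; must be non-empty.
#' @param orientation scan the read as-is (\code{"forward"}), its
#'   reverse complement (\code{"reverse_complement"}), or both.
#' @param max_mismatch 0 (exact, default) or 1 (Hamming-1 tolerance).
#' @return a list with \code{counts} (named integer vector over guides),
#'   \code{unassigned} and \code{total}.
#' @examples
#' lib <- GuideLibrary("g1", "ACGTACGTACGTACGTACGT")
#' fq <- tempfile(fileext = ".fastq")
#' simulateFastq(lib, 1, n_reads = 5, read_length = 40, seed = 1, path = fq)
#' countSpacerReads(fq, lib)$counts
#' @export
countSpacerReads <- function(fastq, library,
                             orientation = c("forward", "reverse_complement",
                                             "both"),
                             max_mismatch = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(is(library, "GuideLibrary"))
  if (nrow(library) == 0L)
    .stop2("configError", "guide library is empty")
  if (!max_mismatch %in% c(0L, 1L))
    .stop2("configError", "max_mismatch must be 0 or 1")
  reads <- .read_fastq(fastq)
  ids <- guideIds(library)
  out <- integer(length(ids))
  names(out) <- ids
  total <- length(reads)
  if (total == 0L)
    return(list(counts = out, unassigned = 0L, total = 0L))

  sp <- spacers(library)
  subjects <- switch(orientation,
    forward = list(reads),
    reverse_complement = list(Biostrings::reverseComplement(reads)),
    both = list(reads, Biostrings::reverseComplement(reads)))

  # per-read set of matching guide indices, pooled over orientations
  nmatch <- matrix(0L, nrow = total, ncol = length(ids))
  for (subj in subjects) {
    if (max_mismatch == 0L) {
      hits <- Biostrings::vwhichPDict(Biostrings::PDict(sp), subj)
      for (r in seq_len(total)) {
        h <- hits[[r]]
        if (length(h)) nmatch[r, h] <- 1L
      }
    } else {
      for (g in seq_along(sp)) {
        n <- Biostrings::vcountPattern(sp[[g]], subj,
                                       max.mismatch = max_mismatch)
        nmatch[n > 0L, g] <- 1L
      }
    }
  }
  nhit <- rowSums(nmatch)
  assigned <- which(nhit == 1L)
  if (length(assigned)) {
    g <- max.col(nmatch[assigned, , drop = FALSE])
    tab <- tabulate(g, nbins = length(ids))
    out[] <- tab
  }
  list(counts = out,
       unassigned = total - length(assigned),
       total = total)
}

# strict 4-line FASTQ reader; reports the index of a malformed record
.read_fastq <- function(path) {
  if (!file.exists(path))
    .stop2("fileError", "file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    .stop2("parseError",
           "truncated FASTQ: %d lines is not a multiple of 4 (record %d incomplete)",
           length(lines), length(lines) %/% 4L + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L) return(Biostrings::DNAStringSet())
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    .stop2("parseError", "malformed FASTQ record at index %d", bad[1L])
  Biostrings::DNAStringSet(toupper(seq))
}

#' Simulate a FASTQ file embedding library spacers
#'
#' Reads are allocated to guides by a multinomial draw over
#' \code{abundance}; each read carries its guide's spacer at a fixed
#' offset (\code{flank5} random bases precede it) padded with random
#' bases to \code{read_length}. Quality is constant ("I").
#'
#' @param library a [GuideLibrary-class].
#' @param abundance numeric vector over guides, summing to 1.
#' @param n_reads total number of reads.
#' @param read_length read length; must cover \code{flank5} + spacer.
#' @param seed integer RNG seed.
#' @param path output path (\code{.gz} supported); a tempfile by default.
#' @param flank5 number of random bases before the spacer (default 10).
#' @return the path, invisibly, with the per-guide read allocation in
#'   \code{attr(, "allocation")}.
#' @export
simulateFastq <- function(library, abundance, n_reads, read_length = 50L,
                          seed = 1L, path = tempfile(fileext = ".fastq"),
                          flank5 = 10L) {
  stopifnot(is(library, "GuideLibrary"))
  abundance <- as.numeric(abundance)
  if (length(abundance) != nrow(library) || any(abundance < 0) ||
      abs(sum(abundance) - 1) > 1e-8)
    .stop2("configError",
           "abundance must be a non-negative vector over guides summing to 1")
  spl <- nchar(as.character(library$spacer))
  if (read_length < flank5 + max(spl))
    .stop2("configError",
           "read_length %d is shorter than flank5 + spacer length (%d)",
           read_length, flank5 + max(spl))
  set.seed(seed)
  alloc <- as.integer(stats::rmultinom(1L, n_reads, abundance))
  names(alloc) <- guideIds(library)
  guide_of <- rep(seq_len(nrow(library)), alloc)
  if (length(guide_of)) guide_of <- sample(guide_of)  # shuffle read order
  bases <- c("A", "C", "G", "T")
  recs <- character(0L)
  if (length(guide_of)) {
    pre <- vapply(seq_along(guide_of), function(i)
      paste(sample(bases, flank5, replace = TRUE), collapse = ""), "")
    spacer <- as.character(library$spacer)[guide_of]
    padlen <- read_length - flank5 - nchar(spacer)
    post <- vapply(padlen, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    seqs <- paste0(pre, spacer, post)
    recs <- as.vector(rbind(sprintf("@read%d guide=%s", seq_along(seqs),
                                    guideIds(library)[guide_of]),
                            seqs, "+",
                            strrep("I", nchar(seqs))))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(recs, con)
  close(con)
  invisible(structure(path, allocation = alloc))
}
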