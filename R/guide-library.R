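#' Construct a GuideLibrary
#'
#' @param sgrna_id character, unique guide identifiers.
#' @param spacer character, 18-22 nt spacer sequences (A/C/G/T).
#' @param gene character, target gene symbol; \code{NA} for control guides.
#' @param class character, one of \code{"targeting"}, \code{"safe_harbor"},
#'   \code{"non_targeting"}.
#' @param subset character, sub-library membership (e.g. \code{"SET1"},
#'   \code{"SET2"}, \code{"control"}).
#' @return a [GuideLibrary-class] object.
#' @examples
#' GuideLibrary(
#'   sgrna_id = c("g1", "sh1"),
#'   spacer   = c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT"),
#'   gene     = c("TP53", NA),
#'   class    = c("targeting", "safe_harbor"),
#'   subset   = c("SET1", "control"))
#' @export
GuideLibrary <- function(sgrna_id, spacer, gene = NA_character_,
                         class = "targeting", subset = "SET1") {
  df <- DataFrame(sgrna_id = as.character(sgrna_id),
                  spacer = toupper(as.character(spacer)),
                  gene = as.character(gene),
                  class = as.character(class),
                  subset = as.character(subset))
  rownames(df) <- df$sgrna_id
  new("GuideLibrary", df)
}

#' Read a guide library from a delimited file
#'
#' Expects a header with columns \code{sgrna_id}, \code{spacer},
#' \code{gene}, \code{class}, \code{subset}. Empty \code{gene} fields are
#' treated as missing (control guides).
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return a [GuideLibrary-class].
#' @export
readGuideLibrary <- function(path, sep = "\t") {
  df <- utils::read.delim(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  .require_cols(df, .GUIDE_COLS, "guide library file")
  gene <- df$gene
  gene[gene == ""] <- NA_character_
  lib <- DataFrame(sgrna_id = df$sgrna_id, spacer = toupper(df$spacer),
                   gene = gene, class = df$class, subset = df$subset)
  rownames(lib) <- NULL
  out <- try(new("GuideLibrary", lib), silent = TRUE)
  if (inherits(out, "try-error"))
    .stop2("validationError", "invalid guide library in %s: %s",
           path, attr(out, "condition")$message)
  rownames(out) <- out$sgrna_id
  out
}

#' Write a guide library to TSV
#' @param x a [GuideLibrary-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGuideLibrary <- function(x, path) {
  stopifnot(is(x, "GuideLibrary"))
  df <- as.data.frame(x)[, .GUIDE_COLS]
  df$gene[is.na(df$gene)] <- ""
  .write_tsv(df, path)
}
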