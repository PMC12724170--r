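#' @import SummarizedExperiment
#' @importFrom BiocGenerics counts
NULL

#' Guide ids of a library or experiment
#' @param x a GuideLibrary or ScreenExperiment.
#' @return character vector of sgRNA ids.
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' Spacer sequences
#' @param x a GuideLibrary.
#' @return a [Biostrings::DNAStringSet] named by sgRNA id.
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' Control class of each guide
#' @param x a GuideLibrary or ScreenExperiment.
#' @return character vector: "targeting", "safe_harbor" or "non_targeting".
#' @export
setGeneric("guideClass", function(x) standardGeneric("guideClass"))

#' Target gene of each guide (NA for controls)
#' @param x a GuideLibrary or ScreenExperiment.
#' @return character vector of gene symbols.
#' @export
setGeneric("guideGene", function(x) standardGeneric("guideGene"))

#' Lower/upper empirical cutoffs of a null distribution
#' @param x an EmpiricalNull.
#' @return named numeric of length 2, \code{c(lo, hi)}.
#' @export
setGeneric("nullCutoffs", function(x) standardGeneric("nullCutoffs"))

#' @describeIn GuideLibrary guide ids.
#' @param x a GuideLibrary.
#' @export
setMethod("guideIds", "GuideLibrary", function(x) as.character(x$sgrna_id))

#' @describeIn GuideLibrary spacer sequences as a DNAStringSet.
#' @export
setMethod("spacers", "GuideLibrary", function(x) {
  s <- Biostrings::DNAStringSet(toupper(as.character(x$spacer)))
  names(s) <- guideIds(x)
  s
})

#' @describeIn GuideLibrary control class per guide.
#' @export
setMethod("guideClass", "GuideLibrary", function(x) as.character(x$class))

#' @describeIn GuideLibrary target gene per guide (NA for controls).
#' @export
setMethod("guideGene", "GuideLibrary", function(x) {
  g <- as.character(x$gene)
  g[!is.na(g) & g == ""] <- NA_character_
  g
})

#' @describeIn ScreenExperiment guide ids (row names).
#' @param x a ScreenExperiment.
#' @export
setMethod("guideIds", "ScreenExperiment", function(x) rownames(x))

#' @describeIn ScreenExperiment control class per guide.
#' @export
setMethod("guideClass", "ScreenExperiment",
          function(x) as.character(rowData(x)$class))

#' @describeIn ScreenExperiment target gene per guide.
#' @export
setMethod("guideGene", "ScreenExperiment",
          function(x) as.character(rowData(x)$gene))

#' @describeIn ScreenExperiment the integer count matrix.
#' @param object a ScreenExperiment.
#' @export
setMethod("counts", "ScreenExperiment",
          function(object) assay(object, "counts"))

#' @describeIn EmpiricalNull the lower/upper cutoffs.
#' @export
setMethod("nullCutoffs", "EmpiricalNull",
          function(x) c(lo = x@loCut, hi = x@hiCut))

setMethod("show", "EmpiricalNull", function(object) {
  cat("EmpiricalNull from", object@nControls, "negative-control effect sizes\n")
  cat(sprintf("  bandwidth: %.4g\n", object@bandwidth))
  cat(sprintf("  empirical cutoffs (2.5%% / 97.5%%): %.4g / %.4g\n",
              object@loCut, object@hiCut))
})

setMethod("show", "FourPLFit", function(object) {
  cat("Four-parameter logistic dose-response fit",
      if (object@constrained) "(top/bottom fixed at 100/0)" else "", "\n")
  cat(sprintf("  top: %.4g  bottom: %.4g  ic50: %.4g  hill: %.4g\n",
              object@top, object@bottom, object@ic50, object@hill))
  cat(sprintf("  residual SS: %.4g\n", object@residualSS))
})

setMethod("show", "GuideLibrary", function(object) {
  tab <- table(factor(object$class, levels = .GUIDE_CLASSES))
  cat(sprintf("GuideLibrary with %d guides (%d targeting, %d safe-harbor, %d non-targeting)\n",
              nrow(object), tab[["targeting"]], tab[["safe_harbor"]],
              tab[["non_targeting"]]))
  cat(sprintf("  %d distinct target genes across sub-libraries: %s\n",
              length(unique(stats::na.omit(guideGene(object)))),
              paste(unique(object$subset), collapse = ", ")))
})
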