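#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
NULL

#' GuideLibrary: the sgRNA catalogue of a pooled screen
#'
#' A \linkS4class{DFrame} holding one row per sgRNA with the columns
#' \code{sgrna_id}, \code{spacer}, \code{gene}, \code{class} and
#' \code{subset}. Guides are either gene-targeting, safe-harbor controls
#' (cutting at a phenotypically neutral locus) or non-targeting controls.
#' The design assumes at most one sgRNA per gene per sub-library
#' (e.g. SET1/SET2), so a gene is covered by up to two independent guides.
#'
#' Validity enforces: unique \code{sgrna_id}; spacers are 18-22 nt over
#' A/C/G/T; every targeting guide names a gene; a gene occurs at most once
#' within a sub-library.
#'
#' @seealso [readGuideLibrary()], [ScreenExperiment()]
#' @export
setClass("GuideLibrary", contains = "DFrame")

.GUIDE_CLASSES <- c("targeting", "safe_harbor", "non_targeting")
.GUIDE_COLS <- c("sgrna_id", "spacer", "gene", "class", "subset")

setValidity("GuideLibrary", function(object) {
  msg <- character()
  missing_cols <- setdiff(.GUIDE_COLS, colnames(object))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  id <- object$sgrna_id
  if (anyDuplicated(id))
    msg <- c(msg, sprintf("duplicated sgrna_id: %s",
                          paste(unique(id[duplicated(id)]), collapse = ", ")))
  sp <- toupper(as.character(object$spacer))
  bad <- which(!grepl("^[ACGT]+$", sp) | nchar(sp) < 18L | nchar(sp) > 22L)
  if (length(bad))
    msg <- c(msg, sprintf(
      "spacer must be 18-22 nt over A/C/G/T; offending row(s): %s",
      paste(head(bad, 10L), collapse = ", ")))
  cls <- as.character(object$class)
  if (!all(cls %in% .GUIDE_CLASSES))
    msg <- c(msg, sprintf("class must be one of %s",
                          paste(.GUIDE_CLASSES, collapse = "/")))
  targeting <- cls == "targeting"
  if (any(targeting & (is.na(object$gene) | object$gene == "")))
    msg <- c(msg, "every targeting guide must have a non-missing gene")
  key <- paste(object$gene[targeting], object$subset[targeting])
  if (anyDuplicated(key))
    msg <- c(msg, sprintf(
      "gene present more than once in a sub-library: %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ScreenExperiment: sgRNA counts with guide and sample annotation
#'
#' Extends \linkS4class{SummarizedExperiment}: a \code{counts} assay of
#' non-negative integer sgRNA x sample read counts, guide annotation
#' (gene, control class, sub-library and -- for simulated screens -- the
#' true fitness) in \code{rowData}, and sample annotation (\code{system},
#' \code{arm}, \code{day}) in \code{colData}.
#'
#' @seealso [ScreenExperiment()], [simulateScreen()], [diffSel()]
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  k <- assay(object, "counts")
  if (is.null(rownames(k)))
    return("counts must have sgRNA row names")
  bad <- which(is.na(k) | k < 0 | k != round(k), arr.ind = TRUE)
  if (nrow(bad))
    return(sprintf(
      "counts must be non-negative integers; first offending entry at [%d, %d]",
      bad[1L, 1L], bad[1L, 2L]))
  TRUE
})

#' EmpiricalNull: a KDE-based null distribution of control effect sizes
#'
#' Holds the Gaussian-kernel density estimate of negative-control log2
#' fold changes evaluated on a uniform grid, the cumulative distribution
#' obtained by trapezoidal integration, and the 2.5%/97.5% quantile
#' cutoffs used to gate sgRNA calls.
#'
#' @slot grid numeric, ordered evaluation points.
#' @slot density numeric, KDE values on the grid.
#' @slot cdf numeric, normalized cumulative distribution on the grid.
#' @slot loCut,hiCut numeric(1), effect sizes at CDF = 0.025 and 0.975.
#' @slot bandwidth numeric(1), the KDE bandwidth used.
#' @slot nControls integer(1), number of control effect sizes used.
#'
#' @seealso [fitEmpiricalNull()], [callGuides()]
#' @export
setClass("EmpiricalNull",
  representation(grid = "numeric", density = "numeric", cdf = "numeric",
                 loCut = "numeric", hiCut = "numeric",
                 bandwidth = "numeric", nControls = "integer"))

setValidity("EmpiricalNull", function(object) {
  msg <- character()
  if (is.unsorted(object@grid)) msg <- c(msg, "grid must be ordered")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (is.unsorted(object@cdf)) msg <- c(msg, "cdf must be non-decreasing")
  if (abs(object@cdf[1L]) > 1e-6 ||
      abs(object@cdf[length(object@cdf)] - 1) > 1e-6)
    msg <- c(msg, "cdf must run from ~0 to ~1")
  if (!(object@loCut < object@hiCut)) msg <- c(msg, "loCut must be < hiCut")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DiffSelResult: per-sgRNA differential-selection statistics
#'
#' A \linkS4class{DFrame} with one row per sgRNA and columns
#' \code{baseMean}, \code{lfc} (log2 fold change, comparison vs
#' reference), \code{se}, \code{wald}, \code{p}, \code{padj} (BH),
#' \code{dispersion}, \code{tested} and \code{zeroGroup}. The contrast
#' label and size factors travel in \code{metadata()}.
#'
#' @export
setClass("DiffSelResult", contains = "DFrame")

#' FourPLFit: a fitted four-parameter logistic dose-response curve
#'
#' The model is \eqn{v(c) = bottom + (top - bottom) / (1 + (c/ic50)^{hill})}
#' with viability in percent and concentration in the input units.
#'
#' @slot top,bottom numeric(1), upper/lower viability asymptotes (%).
#' @slot ic50 numeric(1), concentration of half-maximal response.
#' @slot hill numeric(1), slope factor.
#' @slot residualSS numeric(1), residual sum of squares of the fit.
#' @slot constrained logical(1), whether top/bottom were fixed at 100/0.
#'
#' @seealso [fit4PL()], [inhibitoryConc()]
#' @export
setClass("FourPLFit",
  representation(top = "numeric", bottom = "numeric", ic50 = "numeric",
                 hill = "numeric", residualSS = "numeric",
                 constrained = "logical"))

setValidity("FourPLFit", function(object) {
  msg <- character()
  if (!(object@top > object@bottom)) msg <- c(msg, "top must exceed bottom")
  if (!(object@ic50 > 0)) msg <- c(msg, "ic50 must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
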