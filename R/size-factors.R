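#' Control-anchored median-of-ratios size factors
#'
#' Per-sample normalization factors computed from a designated set of
#' control guides only (typically the safe-harbor controls), so that
#' depletion or enrichment of targeting guides cannot distort the
#' normalization. For each sample \eqn{j},
#' \deqn{s_j = \mathrm{median}_{i \in C^+} \; k_{ij} / \left(\prod_j k_{ij}\right)^{1/m}}
#' where \eqn{C^+} is the set of control guides with strictly positive
#' counts in every sample. Size factors are identified up to a common
#' scale (only their ratios enter fold changes): multiplying one
#' sample's counts by \eqn{c > 0} multiplies its size factor
#' \emph{relative to every other sample} by exactly \eqn{c}.
#'
#' @param counts integer matrix (guides x samples) or a
#'   [ScreenExperiment-class].
#' @param controls character vector of control guide ids; for a
#'   \code{ScreenExperiment} the default is its safe-harbor guides.
#' @return positive numeric vector of per-sample size factors, named by
#'   sample; the control ids actually used are in
#'   \code{attr(, "controls")}.
#' @examples
#' k <- rbind(c(10, 20), c(40, 80))
#' rownames(k) <- c("sh1", "sh2"); colnames(k) <- c("s1", "s2")
#' controlSizeFactors(k, c("sh1", "sh2"))  # c(1/sqrt(2), sqrt(2))
#' @export
controlSizeFactors <- function(counts, controls = NULL) {
  if (is(counts, "ScreenExperiment")) {
    if (is.null(controls))
      controls <- guideIds(counts)[guideClass(counts) == "safe_harbor"]
    counts <- counts(counts)
  }
  if (is.null(controls) || !length(controls))
    .stop2("configError", "a non-empty set of control guide ids is required")
  missing_ids <- setdiff(controls, rownames(counts))
  if (length(missing_ids))
    .stop2("referenceError", "control ids absent from counts: %s",
           paste(head(missing_ids, 10L), collapse = ", "))
  k <- counts[controls, , drop = FALSE]
  pos <- rowSums(k == 0) == 0L
  if (!any(pos))
    .stop2("degenerateInputError",
           paste("no control guide has positive counts in every sample;",
                 "add a pseudocount or widen the control set"))
  k <- k[pos, , drop = FALSE]
  logk <- log(k)
  loggeo <- rowMeans(logk)
  # median taken on the log scale (geometric interpolation at even counts)
  s <- exp(apply(logk - loggeo, 2L, stats::median))
  structure(s, controls = rownames(k))
}
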