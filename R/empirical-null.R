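#' Fit an empirical null from negative-control effect sizes
#'
#' Builds the null distribution of log2 fold changes expected in the
#' absence of selection from the negative-control guides (non-targeting
#' and safe-harbor, pooled). A Gaussian-kernel density estimate is
#' computed on a uniform 512-point grid spanning
#' \eqn{[\min - 3h, \max + 3h]} (the \code{stats::density} convention),
#' converted to a CDF by trapezoidal integration and renormalized; the
#' effect sizes at CDF = 0.025 and 0.975 become the lower/upper
#' empirical cutoffs used to gate calls.
#'
#' @param lfcs numeric vector of negative-control log2 fold changes.
#' @param bandwidth \code{"silverman"} (the \code{bw.nrd0} rule of
#'   thumb, default) or a positive number.
#' @param n_grid number of grid points (default 512).
#' @param minControls minimum number of control effect sizes required
#'   (default 20).
#' @return an [EmpiricalNull-class].
#' @examples
#' null <- fitEmpiricalNull(rnorm(500, sd = 0.4))
#' nullCutoffs(null)
#' @export
fitEmpiricalNull <- function(lfcs, bandwidth = "silverman",
                             n_grid = 512L, minControls = 20L) {
  lfcs <- lfcs[is.finite(lfcs)]
  if (length(lfcs) < minControls)
    .stop2("calibrationError",
           "only %d finite control effect sizes (< %d); pool non-targeting and safe-harbor controls or lower the floor",
           length(lfcs), minControls)
  if (stats::sd(lfcs) == 0)
    .stop2("degenerateNullError",
           "control effect sizes have zero variance; cannot calibrate a null")
  h <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(lfcs)
       else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0)
    .stop2("configError", "bandwidth must be positive")
  d <- stats::density(lfcs, bw = h, kernel = "gaussian", n = n_grid,
                      from = min(lfcs) - 3 * h, to = max(lfcs) + 3 * h)
  dx <- diff(d$x)
  cdf <- c(0, cumsum((d$y[-1L] + d$y[-n_grid]) / 2 * dx))
  cdf <- cdf / cdf[n_grid]
  lo <- .cdf_quantile(d$x, cdf, 0.025)
  hi <- .cdf_quantile(d$x, cdf, 0.975)
  new("EmpiricalNull", grid = d$x, density = d$y, cdf = cdf,
      loCut = lo, hiCut = hi, bandwidth = h,
      nControls = length(lfcs))
}

# linear interpolation of the inverse CDF; flat stretches resolved to the
# first grid point attaining the level
.cdf_quantile <- function(grid, cdf, p) {
  i <- findInterval(p, cdf, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(grid) - 1L)
  c0 <- cdf[i]; c1 <- cdf[i + 1L]
  if (c1 == c0) return(grid[i])
  grid[i] + (p - c0) / (c1 - c0) * (grid[i + 1L] - grid[i])
}

#' Call significantly selected sgRNAs
#'
#' Combines the FDR threshold with the empirical null band. Under the
#' default \code{rule = "conjunction"} a guide is significant iff
#' \code{padj < alpha} AND its log2 fold change falls outside
#' \code{[loCut, hiCut]}; direction is set by which cutoff is exceeded.
#' Under \code{rule = "fdr-only"} significance is \code{padj < alpha}
#' alone and the band only labels direction (inside-band effects keep
#' the sign of their lfc).
#'
#' @param res a [DiffSelResult-class].
#' @param null an [EmpiricalNull-class] from the same contrast.
#' @param alpha FDR level (default 0.05).
#' @param rule \code{"conjunction"} (default) or \code{"fdr-only"}.
#' @return a DataFrame with \code{sgrna_id}, \code{lfc}, \code{padj},
#'   \code{significant}, \code{direction} (\code{depleted},
#'   \code{enriched} or \code{none}) and \code{tested}. Untested guides
#'   are never significant and carry direction \code{none}.
#' @export
callGuides <- function(res, null, alpha = 0.05,
                       rule = c("conjunction", "fdr-only")) {
  rule <- match.arg(rule)
  stopifnot(is(res, "DiffSelResult"), is(null, "EmpiricalNull"))
  lfc <- res$lfc
  padj <- res$padj
  tested <- res$tested
  outside <- ifelse(lfc < null@loCut, "depleted",
                    ifelse(lfc > null@hiCut, "enriched", "none"))
  outside[!tested | is.na(lfc)] <- "none"
  fdr_ok <- !is.na(padj) & padj < alpha & tested
  if (rule == "conjunction") {
    significant <- fdr_ok & outside != "none"
    direction <- ifelse(significant, outside, "none")
  } else {
    significant <- fdr_ok
    direction <- ifelse(significant,
                        ifelse(outside != "none", outside,
                               ifelse(lfc < 0, "depleted", "enriched")),
                        "none")
  }
  DataFrame(sgrna_id = rownames(res), lfc = lfc, padj = padj,
            significant = significant, direction = direction,
            tested = tested, row.names = rownames(res))
}

#' Fraction of control effect sizes outside the empirical band
#'
#' Diagnostic: by construction approximately 5% of the control effect
#' sizes used to fit the null should fall outside
#' \code{[loCut, hiCut]} (KDE smoothing permits a small deviation).
#'
#' @param null an [EmpiricalNull-class].
#' @param lfcs the control effect sizes.
#' @return the outside fraction, a number in [0, 1].
#' @export
nullExceedance <- function(null, lfcs) {
  lfcs <- lfcs[is.finite(lfcs)]
  mean(lfcs < null@loCut | lfcs > null@hiCut)
}

#' Serialize an empirical null summary to JSON
#' @param null an [EmpiricalNull-class].
#' @param path output path.
#' @export
writeNullSummary <- function(null, path) {
  jsonlite::write_json(
    list(lo_cut = null@loCut, hi_cut = null@hiCut,
         bandwidth = null@bandwidth, n_controls = null@nControls),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
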