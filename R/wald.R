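#' Benjamini-Hochberg adjustment with NaN propagation
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}: missing
#' p-values are propagated as missing and excluded from the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return vector of BH-adjusted p-values, same length and order.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustBH <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok[which(ok)] & (p[ok] < 0 | p[ok] > 1)))
    .stop2("validationError", "p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-guide negative binomial Wald test between two sample groups
#'
#' Fits, for every guide, the two-group NB generalized linear model
#' \deqn{K_{ij} \sim NB(\mu_{ij}, \alpha_i), \quad
#'       \mu_{ij} = s_j \exp(\beta_0 + \beta_1 x_j)}
#' with \eqn{x_j = 1} for comparison-group samples and the log size
#' factors as offset, by iteratively reweighted least squares vectorized
#' across guides. Reported effect sizes are \eqn{\beta_1/\log 2} (log2
#' fold change, comparison vs reference), with Wald statistic
#' \eqn{\beta_1/SE(\beta_1)} and two-sided normal p-value. For balanced
#' groups with equal size factors the estimate equals the log2 ratio of
#' group mean counts exactly.
#'
#' Guides with zero counts in all samples of one group get a 0.5
#' pseudocount on every sample before fitting (flagged in
#' \code{zeroGroup}); guides with zero counts everywhere are excluded
#' (\code{tested = FALSE}, statistics NA). BH adjustment is applied over
#' the tested guides of this contrast.
#'
#' @param counts integer matrix, guides x samples.
#' @param sizeFactors positive per-sample size factors.
#' @param dispersions per-guide NB dispersion alpha (recycled if
#'   length 1), e.g. from [estimateGuideDispersions()].
#' @param reference,comparison column names (or indices) of the two
#'   groups; must be disjoint and non-empty.
#' @param label contrast label stored in the result metadata.
#' @return a [DiffSelResult-class] with columns \code{baseMean},
#'   \code{lfc}, \code{se}, \code{wald}, \code{p}, \code{padj},
#'   \code{dispersion}, \code{tested}, \code{zeroGroup}.
#' @export
waldTestGuides <- function(counts, sizeFactors, dispersions,
                           reference, comparison, label = "B_vs_A") {
  counts <- as.matrix(counts)
  if (is.character(reference))
    reference <- match(reference, colnames(counts))
  if (is.character(comparison))
    comparison <- match(comparison, colnames(counts))
  if (anyNA(reference) || anyNA(comparison) ||
      !length(reference) || !length(comparison) ||
      length(intersect(reference, comparison)))
    .stop2("configError",
           "reference and comparison must be disjoint, non-empty sample sets present in counts")
  cols <- c(reference, comparison)
  y <- counts[, cols, drop = FALSE]
  sf <- sizeFactors[cols]
  stopifnot(all(sf > 0))
  x <- rep(c(0, 1), c(length(reference), length(comparison)))
  n <- nrow(y)
  alpha <- rep_len(as.numeric(dispersions), n)

  base_mean <- rowMeans(sweep(y, 2L, sf, "/"))
  tested <- rowSums(y) > 0L
  zeroA <- rowSums(y[, x == 0, drop = FALSE]) == 0L
  zeroB <- rowSums(y[, x == 1, drop = FALSE]) == 0L
  zero_group <- tested & (zeroA | zeroB)

  yfit <- y
  yfit[zero_group, ] <- yfit[zero_group, , drop = FALSE] + 0.5

  fit <- .nb_irls_2group(yfit[tested, , drop = FALSE], sf, x,
                         alpha[tested])

  lfc <- se <- wald <- p <- rep(NA_real_, n)
  lfc[tested] <- fit$b1 / log(2)
  se[tested] <- fit$se1 / log(2)
  wald[tested] <- fit$b1 / fit$se1
  p[tested] <- 2 * stats::pnorm(-abs(wald[tested]))

  res <- DataFrame(baseMean = base_mean, lfc = lfc, se = se, wald = wald,
                   p = p, padj = adjustBH(p), dispersion = alpha,
                   tested = tested, zeroGroup = zero_group,
                   row.names = rownames(counts))
  res <- new("DiffSelResult", res)
  metadata(res) <- list(contrast = label,
                        reference = colnames(counts)[reference],
                        comparison = colnames(counts)[comparison],
                        sizeFactors = stats::setNames(sf, colnames(y)))
  res
}

# vectorized IRLS for the 2-parameter model eta = b0 + b1*x + log(sf)
.nb_irls_2group <- function(y, sf, x, alpha, maxit = 50L, tol = 1e-12) {
  n <- nrow(y)
  if (n == 0L)
    return(list(b0 = numeric(0), b1 = numeric(0), se1 = numeric(0)))
  o <- matrix(log(sf), n, length(sf), byrow = TRUE)
  xr <- matrix(x, n, length(x), byrow = TRUE)
  # initial values from pseudocounted group means
  qa <- (rowSums(y[, x == 0, drop = FALSE]) + 0.5) / sum(sf[x == 0])
  qb <- (rowSums(y[, x == 1, drop = FALSE]) + 0.5) / sum(sf[x == 1])
  b0 <- log(qa)
  b1 <- log(qb) - log(qa)
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * xr + o
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - o) + (y - mu) / mu
    Sw <- rowSums(w); Swx <- rowSums(w * xr)
    Swz <- rowSums(w * z); Swxz <- rowSums(w * xr * z)
    det <- Sw * Swx - Swx^2          # x binary: sum w x^2 == sum w x
    det <- pmax(det, 1e-300)
    b0_new <- (Swx * Swz - Swx * Swxz) / det
    b1_new <- (Sw * Swxz - Swx * Swz) / det
    delta <- max(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new; b1 <- b1_new
    if (delta < tol) break
  }
  eta <- b0 + b1 * xr + o
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  Sw <- rowSums(w); Swx <- rowSums(w * xr)
  det <- pmax(Sw * Swx - Swx^2, 1e-300)
  list(b0 = b0, b1 = b1, se1 = sqrt(Sw / det))
}

#' Differential selection analysis of one contrast
#'
#' Convenience wrapper tying the engine together for a
#' [ScreenExperiment-class]: control-anchored size factors from the
#' safe-harbor guides, dispersion estimation over the contrast's
#' samples, and the per-guide NB Wald test with BH adjustment.
#'
#' @param se a [ScreenExperiment-class].
#' @param reference,comparison sample ids of the two groups.
#' @param label contrast label.
#' @param sizeFactors optional precomputed size factors for the full
#'   experiment (named by sample); computed from safe-harbor guides when
#'   missing.
#' @param dispersions optional per-guide dispersions; estimated when
#'   missing.
#' @return a [DiffSelResult-class].
#' @examples
#' se <- simulateScreen(simConfig(n_genes = 40, n_safe_harbor = 25,
#'                                n_non_targeting = 25, depth = 200,
#'                                seed = 3))
#' res <- diffSel(se, reference = c("2D_Day0_r1", "2D_Day0_r2", "2D_Day0_r3"),
#'                comparison = c("2D_Day30_r1", "2D_Day30_r2"),
#'                label = "2D_Day30_vs_Day0")
#' head(res)
#' @export
diffSel <- function(se, reference, comparison, label = "B_vs_A",
                    sizeFactors = NULL, dispersions = NULL) {
  stopifnot(is(se, "ScreenExperiment"))
  bad <- setdiff(c(reference, comparison), colnames(se))
  if (length(bad))
    .stop2("referenceError", "unknown sample id(s): %s",
           paste(bad, collapse = ", "))
  if (is.null(sizeFactors)) sizeFactors <- controlSizeFactors(se)
  k <- counts(se)
  cols <- c(reference, comparison)
  if (is.null(dispersions)) {
    grp <- rep(c("A", "B"), c(length(reference), length(comparison)))
    dispersions <- estimateGuideDispersions(k[, cols, drop = FALSE],
                                            sizeFactors[cols], grp)
  }
  waldTestGuides(k, sizeFactors, dispersions, reference, comparison,
                 label = label)
}

#' Write a differential-selection table to TSV
#' @param res a [DiffSelResult-class].
#' @param path output path.
#' @export
writeDiffSel <- function(res, path) {
  df <- data.frame(sgrna_id = rownames(res), as.data.frame(res))
  .write_tsv(df, path)
}
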