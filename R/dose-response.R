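#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{v(c) = bottom + \frac{top - bottom}{1 + (c/ic50)^{hill}}}
#' to viability (%) versus concentration, via Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}). Initialization is deterministic: top and
#' bottom from the data extremes, ic50 from the dose whose viability is
#' nearest the half-span, hill = 1. With \code{constrain = TRUE} the
#' asymptotes are fixed at 100/0 and only ic50 and hill are fitted.
#'
#' @param conc positive concentrations (>= 4 distinct values).
#' @param viability viability in percent of control, finite.
#' @param constrain fix top = 100, bottom = 0 (default FALSE).
#' @return a [FourPLFit-class].
#' @examples
#' conc <- 10^seq(-1, 2, length.out = 8)
#' v <- 100 / (1 + conc / 10)
#' fit4PL(conc, v)
#' @export
fit4PL <- function(conc, viability, constrain = FALSE) {
  conc <- as.numeric(conc); viability <- as.numeric(viability)
  if (length(conc) != length(viability) || !all(is.finite(viability)))
    .stop2("validationError",
           "conc and viability must be equal-length finite vectors")
  if (any(conc <= 0))
    .stop2("validationError", "concentrations must be positive")
  if (length(unique(conc)) < 4L)
    .stop2("validationError", "need >= 4 distinct concentrations")

  df <- data.frame(conc = conc, v = viability)
  top0 <- max(viability); bot0 <- min(viability)
  half <- (top0 + bot0) / 2
  ic50_0 <- conc[which.min(abs(viability - half))]
  fit <- if (constrain) {
    try(minpack.lm::nlsLM(
      v ~ 100 / (1 + (conc / ic50)^hill), data = df,
      start = list(ic50 = ic50_0, hill = 1),
      lower = c(ic50 = 1e-12, hill = -50),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill), data = df,
      start = list(top = top0, bottom = bot0, ic50 = ic50_0, hill = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12, hill = -50),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error"))
    .stop2("fitError",
           "4PL fit failed (%s); data may lack sigmoid structure [range of viability: %.3g..%.3g over %d doses]",
           trimws(attr(fit, "condition")$message), bot0, top0,
           length(unique(conc)))
  cf <- stats::coef(fit)
  top <- if (constrain) 100 else cf[["top"]]
  bottom <- if (constrain) 0 else cf[["bottom"]]
  rss <- sum(stats::resid(fit)^2)
  if (!(top > bottom) || !(cf[["ic50"]] > 0))
    .stop2("fitError",
           "4PL fit degenerate (top=%.4g, bottom=%.4g, ic50=%.4g, hill=%.4g, RSS=%.4g); no usable sigmoid structure",
           top, bottom, cf[["ic50"]], cf[["hill"]], rss)
  new("FourPLFit", top = top, bottom = bottom, ic50 = cf[["ic50"]],
      hill = cf[["hill"]], residualSS = rss,
      constrained = isTRUE(constrain))
}

#' Invert a 4PL fit for the x% inhibitory concentration
#'
#' Analytic inversion of the fitted curve. Under the default
#' span-relative definition the target viability for x% inhibition is
#' \eqn{v = top - (x/100)(top - bottom)}; with
#' \code{mode = "absolute"} the target is \eqn{v = 100 - x} percent
#' regardless of the fitted asymptotes. The returned concentration is
#' \deqn{c = ic50 \left(\frac{top - bottom}{v - bottom} - 1\right)^{1/hill}.}
#'
#' @param fit a [FourPLFit-class].
#' @param x percent inhibition in (0, 100); e.g. \code{x = 25} gives the
#'   IC25.
#' @param mode \code{"span"} (default) or \code{"absolute"}.
#' @return the concentration, in the units of the fitted data.
#' @examples
#' f <- new("FourPLFit", top = 100, bottom = 0, ic50 = 10, hill = 1,
#'          residualSS = 0, constrained = FALSE)
#' inhibitoryConc(f, 50)   # 10
#' inhibitoryConc(f, 25)   # 10/3
#' @export
inhibitoryConc <- function(fit, x, mode = c("span", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is(fit, "FourPLFit"))
  if (!(x > 0 && x < 100))
    .stop2("domainError", "x must lie strictly between 0 and 100")
  v_target <- if (mode == "span") fit@top - x / 100 * (fit@top - fit@bottom)
              else 100 - x
  if (!(v_target > fit@bottom && v_target < fit@top))
    .stop2("domainError",
           "target viability %.4g%% is outside the fitted range (%.4g, %.4g)",
           v_target, fit@bottom, fit@top)
  fit@ic50 * ((fit@top - fit@bottom) / (v_target - fit@bottom) - 1)^(1 / fit@hill)
}

#' Evaluate a fitted 4PL curve
#' @param fit a [FourPLFit-class].
#' @param conc concentrations at which to evaluate.
#' @return predicted viability (%).
#' @export
predict4PL <- function(fit, conc) {
  fit@bottom + (fit@top - fit@bottom) / (1 + (conc / fit@ic50)^fit@hill)
}

#' Read a dose-response viability table
#' @param path TSV with columns \code{concentration},
#'   \code{viability_pct} and optionally \code{replicate}.
#' @return a data.frame.
#' @export
readDoseResponse <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("concentration", "viability_pct"),
                "dose-response file")
  df
}
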