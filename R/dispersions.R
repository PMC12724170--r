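#' Per-guide negative-binomial dispersion estimation with shrinkage
#'
#' Three-step scheme suited to screens with 2-4 samples per group:
#' \enumerate{
#'   \item gene-wise maximum-likelihood dispersion per guide, with group
#'     means fitted under the two-group model (offsets = log size
#'     factors);
#'   \item a mean-dispersion trend \eqn{\alpha_{tr}(\mu) = a_0 + a_1/\mu}
#'     fitted across guides by iterated gamma-family regression;
#'   \item empirical-Bayes shrinkage of log-dispersions toward the
#'     trend: each guide's final \eqn{\alpha} maximizes its likelihood
#'     plus a normal prior on \eqn{\log\alpha} centred at the trend,
#'     prior variance estimated from the spread of gene-wise estimates
#'     around the trend minus the expected sampling variance.
#' }
#' Guides with no residual degrees of freedom (or instances too small to
#' fit a trend) fall back to the documented prior dispersion
#' \code{fallback}. All-zero guides are flagged and assigned
#' \code{fallback}.
#'
#' @param counts integer matrix, guides x samples (both groups).
#' @param sizeFactors positive per-sample size factors.
#' @param group factor/vector of length ncol with two levels (reference
#'   first).
#' @param minDisp,maxDisp bounds on the dispersion estimate.
#' @param fallback dispersion used when no information is available
#'   (default 0.1, typical for pooled screens).
#' @return numeric vector of shrunken dispersions with attributes
#'   \code{genewise}, \code{trend} (function of mu), \code{trendCoef},
#'   \code{priorVar} and \code{allZero}.
#' @export
estimateGuideDispersions <- function(counts, sizeFactors, group,
                                     minDisp = 1e-8, maxDisp = 20,
                                     fallback = 0.1) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  stopifnot(length(sizeFactors) == m, all(sizeFactors > 0))
  group <- as.integer(factor(group))
  if (length(unique(group)) != 2L)
    .stop2("configError", "group must have exactly two levels")
  n <- nrow(counts)
  all_zero <- rowSums(counts) == 0L
  df_resid <- m - 2L

  base_mean <- rowMeans(sweep(counts, 2L, sizeFactors, "/"))
  genewise <- rep(NA_real_, n)
  if (df_resid > 0L) {
    for (i in which(!all_zero)) {
      genewise[i] <- .ml_dispersion(counts[i, ], sizeFactors, group,
                                    minDisp, maxDisp)
    }
  }

  usable <- !is.na(genewise) & genewise > minDisp * 10 & base_mean > 0
  if (sum(usable) >= 10L) {
    tc <- .fit_disp_trend(base_mean[usable], genewise[usable], minDisp)
  } else {
    mid <- if (any(usable)) stats::median(genewise[usable]) else fallback
    tc <- c(a0 = max(mid, minDisp), a1 = 0)
  }
  trend <- function(mu) pmax(tc[["a0"]] + tc[["a1"]] / mu, minDisp)

  # prior variance of log-dispersion about the trend
  if (sum(usable) >= 10L) {
    lres <- log(genewise[usable]) - log(trend(base_mean[usable]))
    samp_var <- trigamma(df_resid / 2)          # approx sampling variance
    prior_var <- max(stats::var(lres) - samp_var, 0.25)
  } else {
    prior_var <- 0.25
  }

  out <- rep(fallback, n)
  for (i in seq_len(n)) {
    if (all_zero[i]) next
    a_tr <- trend(max(base_mean[i], 1e-8))
    if (df_resid <= 0L || is.na(genewise[i])) {
      out[i] <- if (sum(usable) >= 10L) a_tr else fallback
      next
    }
    out[i] <- .map_dispersion(counts[i, ], sizeFactors, group,
                              log(a_tr), prior_var, minDisp, maxDisp)
  }
  structure(out, genewise = genewise, trend = trend, trendCoef = tc,
            priorVar = prior_var, allZero = all_zero)
}

# two-group NB mean fit for a fixed dispersion: weighted means per group
.group_mu <- function(y, sf, group, alpha = 0) {
  mu <- numeric(length(y))
  for (g in 1:2) {
    idx <- group == g
    # MLE of the group abundance under NB with mu = s_j * q: solved by
    # one-dim Newton; exact q = sum(y)/sum(s) under Poisson, used as start
    q <- sum(y[idx]) / sum(sf[idx])
    if (alpha > 0 && q > 0) {
      for (it in 1:10) {
        mug <- sf[idx] * q
        w <- 1 / (1 + alpha * mug)
        score <- sum((y[idx] - mug) * w) / q
        info <- sum(mug * w) / q^2
        step <- score / info
        q_new <- q + step
        if (!is.finite(q_new) || q_new <= 0) q_new <- q / 2
        if (abs(q_new - q) < 1e-10 * (q + 1e-10)) { q <- q_new; break }
        q <- q_new
      }
    }
    mu[idx] <- sf[idx] * q
  }
  mu
}

.nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 0) return(sum(stats::dpois(y, lambda = pmax(mu, 1e-12),
                                          log = TRUE)))
  sum(stats::dnbinom(y, mu = pmax(mu, 1e-12), size = 1 / alpha, log = TRUE))
}

.ml_dispersion <- function(y, sf, group, minDisp, maxDisp) {
  obj <- function(la) {
    a <- exp(la)
    mu <- .group_mu(y, sf, group, a)
    -.nb_loglik(y, mu, a)
  }
  opt <- stats::optimize(obj, interval = log(c(minDisp, maxDisp)),
                         tol = 1e-4)
  exp(opt$minimum)
}

.map_dispersion <- function(y, sf, group, log_prior_mean, prior_var,
                            minDisp, maxDisp) {
  obj <- function(la) {
    a <- exp(la)
    mu <- .group_mu(y, sf, group, a)
    -.nb_loglik(y, mu, a) + (la - log_prior_mean)^2 / (2 * prior_var)
  }
  opt <- stats::optimize(obj, interval = log(c(minDisp, maxDisp)),
                         tol = 1e-4)
  exp(opt$minimum)
}

# robust parametric trend alpha(mu) = a0 + a1/mu, gamma-family IRLS with
# iterative exclusion of extreme ratios (DESeq2-style outlier trimming)
.fit_disp_trend <- function(mu, disp, minDisp) {
  keep <- rep(TRUE, length(mu))
  coefs <- c(a0 = stats::median(disp), a1 = 0)
  for (it in 1:10) {
    fit <- try(suppressWarnings(
      stats::glm(disp[keep] ~ I(1 / mu[keep]),
                 family = stats::Gamma(link = "identity"),
                 start = pmax(coefs, minDisp))), silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(stats::coef(fit))))
      break
    new_coefs <- stats::coef(fit)
    names(new_coefs) <- c("a0", "a1")
    pred <- new_coefs[["a0"]] + new_coefs[["a1"]] / mu
    ratio <- disp / pmax(pred, minDisp)
    keep_new <- ratio > 1e-4 & ratio < 15
    conv <- sum(abs(new_coefs - coefs)) < 1e-6 * sum(abs(coefs) + 1e-6)
    coefs <- new_coefs
    if (conv || all(keep_new == keep)) break
    keep <- keep_new
  }
  c(a0 = max(coefs[["a0"]], minDisp), a1 = max(coefs[["a1"]], 0))
}
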