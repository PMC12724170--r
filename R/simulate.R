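#' Simulation configuration for a pooled CRISPR screen
#'
#' Assembles and validates the parameters of [simulateScreen()]. The
#' defaults emulate a two-sub-library loss-of-function screen: one guide
#' per gene in each of SET1/SET2, safe-harbor and non-targeting
#' controls, 500x cell coverage at every bottleneck, and
#' negative-binomial sequencing noise.
#'
#' The growth model: a mutant with relative fitness \eqn{f} changes cell
#' abundance over \eqn{d} population doublings as
#' \eqn{x(d) = x(0) \cdot 2^{d(1+f)}}, so its expected log2 fold change
#' relative to the neutral (f = 0) control population is exactly
#' \eqn{d \cdot f}. Selection acts only in samples whose layout row has
#' \code{selected = TRUE}; baseline and no-drug control arms stay at the
#' initial composition up to bottleneck and sequencing noise.
#'
#' @param n_genes number of targeted genes (each gets one guide per
#'   sub-library in \code{subsets}).
#' @param n_safe_harbor,n_non_targeting numbers of control guides.
#' @param subsets sub-library names for targeting guides.
#' @param coverage cells maintained per guide at each bottleneck.
#' @param depth expected reads per guide per sample.
#' @param dispersion negative-binomial overdispersion alpha of the
#'   sequencing counts (0 = Poisson).
#' @param baseline_lognormal_sigma log-scale SD of the initial guide
#'   abundance distribution.
#' @param effect_model data.frame with columns \code{class},
#'   \code{fitness}, \code{fraction}; fractions must sum to 1. Gene-level:
#'   both guides of a gene share its fitness. Controls are always neutral.
#' @param samples sample layout data.frame with columns
#'   \code{sample_id}, \code{system}, \code{arm}, \code{day},
#'   \code{doublings}, \code{selected}; see [timecourseLayout()] and
#'   [chemicalLayout()]. Defaults to a 2D time-course layout.
#' @param bottlenecks number of sequential multinomial bottlenecks per
#'   sample (a dissociation/reassembly passage adds one).
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return a validated list of class \code{simConfig}.
#' @export
simConfig <- function(n_genes = 2000L, n_safe_harbor = 100L,
                      n_non_targeting = 100L, subsets = c("SET1", "SET2"),
                      coverage = 500, depth = 500, dispersion = 0.05,
                      baseline_lognormal_sigma = 0.3,
                      effect_model = data.frame(
                        class = c("neutral", "disadvantage", "advantage"),
                        fitness = c(0, -0.5, 0.5),
                        fraction = c(0.90, 0.05, 0.05)),
                      samples = timecourseLayout(),
                      bottlenecks = 1L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_safe_harbor = as.integer(n_safe_harbor),
              n_non_targeting = as.integer(n_non_targeting),
              subsets = subsets, coverage = coverage, depth = depth,
              dispersion = dispersion,
              baseline_lognormal_sigma = baseline_lognormal_sigma,
              effect_model = effect_model, samples = samples,
              bottlenecks = as.integer(bottlenecks),
              seed = as.integer(seed))
  if (cfg$n_genes < 0 || cfg$n_safe_harbor < 0 || cfg$n_non_targeting < 0)
    .stop2("configError", "guide counts must be non-negative")
  if (cfg$coverage < 1) .stop2("configError", "coverage must be >= 1")
  if (cfg$dispersion < 0) .stop2("configError", "dispersion must be >= 0")
  .require_cols(effect_model, c("class", "fitness", "fraction"),
                "effect_model")
  if (abs(sum(effect_model$fraction) - 1) > 1e-8)
    .stop2("configError", "effect_model fractions must sum to 1 (got %g)",
           sum(effect_model$fraction))
  .require_cols(samples,
                c("sample_id", "system", "arm", "day", "doublings",
                  "selected"), "sample layout")
  class(cfg) <- "simConfig"
  cfg
}

#' Sample layouts for simulated screens
#'
#' \code{timecourseLayout()} mirrors a time-course design: 3 baseline
#' (Day 0) samples and 2 replicates at each later timepoint, with
#' doubling counts derived from a 2-day doubling time (Day 20 = 10,
#' Day 30 = 15 doublings). \code{chemicalLayout()} mirrors a drug arm:
#' untreated control and treated samples harvested after 7 doublings
#' (Day 14), selection acting only under treatment.
#'
#' @param system "2D" or "3D".
#' @param n_baseline,n_timepoint,n_control,n_treated replicate counts.
#' @param days,doublings timepoints and their doubling counts.
#' @return a data.frame sample layout for [simConfig()].
#' @export
timecourseLayout <- function(system = "2D", n_baseline = 3L,
                             n_timepoint = 2L, days = c(20L, 30L),
                             doublings = c(10, 15)) {
  stopifnot(length(days) == length(doublings))
  base <- data.frame(
    sample_id = sprintf("%s_Day0_r%d", system, seq_len(n_baseline)),
    system = system, arm = "baseline", day = 0L, doublings = 0,
    selected = FALSE)
  tps <- do.call(rbind, lapply(seq_along(days), function(i) data.frame(
    sample_id = sprintf("%s_Day%d_r%d", system, days[i],
                        seq_len(n_timepoint)),
    system = system, arm = "timecourse", day = days[i],
    doublings = doublings[i], selected = TRUE)))
  rbind(base, tps)
}

#' @rdname timecourseLayout
#' @param day harvest day of the chemical arm.
#' @export
chemicalLayout <- function(system = "2D", n_control = 2L, n_treated = 2L,
                           day = 14L, doublings = 7) {
  rbind(
    data.frame(
      sample_id = sprintf("%s_Cont_r%d", system, seq_len(n_control)),
      system = system, arm = "control", day = day, doublings = doublings,
      selected = FALSE),
    data.frame(
      sample_id = sprintf("%s_Doxo_r%d", system, seq_len(n_treated)),
      system = system, arm = "treated", day = day, doublings = doublings,
      selected = TRUE))
}

#' Simulate a pooled CRISPR screen with known ground truth
#'
#' Generates a guide library (one guide per gene per sub-library plus
#' safe-harbor and non-targeting controls), assigns each gene a fitness
#' from the configured effect model, and produces sequencing counts per
#' sample: growth by \eqn{2^{d(1+f)}} over the sample's doublings,
#' one or more multinomial bottlenecks at \code{coverage} cells per
#' guide, then negative-binomial read sampling at the configured depth
#' and dispersion.
#'
#' @param config a [simConfig()].
#' @return a [ScreenExperiment-class]; \code{rowData} carries the truth
#'   (\code{fitness}, \code{effect_class}), \code{colData} the layout
#'   (including \code{doublings} and \code{selected}), and
#'   \code{metadata()$config} the configuration.
#' @examples
#' cfg <- simConfig(n_genes = 50, n_safe_harbor = 10, n_non_targeting = 10,
#'                  depth = 100, seed = 7)
#' se <- simulateScreen(cfg)
#' table(rowData(se)$effect_class)
#' @export
simulateScreen <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  lib <- .sim_library(config)
  n <- nrow(lib)
  genes <- unique(stats::na.omit(guideGene(lib)))

  em <- config$effect_model
  gene_class <- sample(rep(seq_len(nrow(em)),
                           .round_fractions(em$fraction, length(genes))))
  fit_of_gene <- stats::setNames(em$fitness[gene_class], genes)
  cls_of_gene <- stats::setNames(as.character(em$class[gene_class]), genes)
  fitness <- ifelse(is.na(guideGene(lib)), 0, fit_of_gene[guideGene(lib)])
  effect_class <- ifelse(is.na(guideGene(lib)), "control",
                         cls_of_gene[guideGene(lib)])

  x0 <- stats::rlnorm(n, meanlog = 0,
                      sdlog = config$baseline_lognormal_sigma)
  layout <- config$samples
  counts <- matrix(0L, nrow = n, ncol = nrow(layout),
                   dimnames = list(guideIds(lib), layout$sample_id))
  n_cells <- round(config$coverage * n)
  total_reads <- config$depth * n
  for (j in seq_len(nrow(layout))) {
    d <- layout$doublings[j] * as.numeric(layout$selected[j])
    w <- x0 * 2^(d * fitness)
    for (b in seq_len(config$bottlenecks))
      w <- as.numeric(stats::rmultinom(1L, n_cells, w))
    mu <- total_reads * w / sum(w)
    counts[, j] <- if (config$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(n, mu)
  }
  se <- ScreenExperiment(counts, lib, layout[, .SAMPLE_COLS])
  rowData(se)$fitness <- fitness
  rowData(se)$effect_class <- effect_class
  colData(se)$doublings <- layout$doublings
  colData(se)$selected <- layout$selected
  metadata(se)$config <- config
  se
}

#' Expected log2 fold changes of a simulated screen
#'
#' For every guide and sample, the closed-form expected normalized
#' log2 fold change relative to the unselected baseline composition:
#' \eqn{d_j f_i} where selection acted, 0 elsewhere.
#'
#' @param se a simulated [ScreenExperiment-class].
#' @return numeric matrix, guides x samples.
#' @export
expectedLfc <- function(se) {
  stopifnot(is(se, "ScreenExperiment"),
            !is.null(rowData(se)$fitness))
  outer(rowData(se)$fitness,
        colData(se)$doublings * as.numeric(colData(se)$selected))
}

#' Write the ground-truth table of a simulated screen
#'
#' TSV with columns \code{sgrna_id class fitness} plus one
#' \code{expected_lfc_<day>} column per selected timepoint.
#'
#' @param se a simulated [ScreenExperiment-class].
#' @param path output path.
#' @export
writeSimTruth <- function(se, path) {
  df <- data.frame(sgrna_id = guideIds(se),
                   class = rowData(se)$effect_class,
                   fitness = rowData(se)$fitness)
  sel <- unique(colData(se)$doublings[colData(se)$selected])
  days <- unique(colData(se)$day[colData(se)$selected])
  for (i in seq_along(sel))
    df[[sprintf("expected_lfc_d%s", days[i])]] <-
      rowData(se)$fitness * sel[i]
  .write_tsv(df, path)
}

# deterministic integer allocation of class sizes (largest remainder)
.round_fractions <- function(frac, n) {
  k <- floor(frac * n)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(frac * n - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  k
}

.sim_library <- function(config) {
  n_t <- config$n_genes * length(config$subsets)
  n <- n_t + config$n_safe_harbor + config$n_non_targeting
  sp <- .random_spacers(n, 20L)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  id_t <- character(0); gene_t <- character(0); sub_t <- character(0)
  for (s in config$subsets) {
    id_t <- c(id_t, sprintf("%s_%s", genes, s))
    gene_t <- c(gene_t, genes)
    sub_t <- c(sub_t, rep(s, config$n_genes))
  }
  GuideLibrary(
    sgrna_id = c(id_t, sprintf("SH_%03d", seq_len(config$n_safe_harbor)),
                 sprintf("NT_%03d", seq_len(config$n_non_targeting))),
    spacer = sp,
    gene = c(gene_t, rep(NA_character_,
                         config$n_safe_harbor + config$n_non_targeting)),
    class = c(rep("targeting", n_t),
              rep("safe_harbor", config$n_safe_harbor),
              rep("non_targeting", config$n_non_targeting)),
    subset = c(sub_t, rep("control",
                          config$n_safe_harbor + config$n_non_targeting)))
}

.random_spacers <- function(n, len) {
  out <- character(0L)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}
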