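#' Validate a pipeline configuration
#'
#' Exhaustively checks a run configuration (R list or YAML path) and
#' returns findings as data rather than throwing: one row per finding
#' with \code{level} (\code{"error"}/\code{"warning"}) and
#' \code{message}. [runPipeline()] refuses to start if any error-level
#' finding exists.
#'
#' Checked: presence of either a \code{simulate} block or an
#' \code{input} block with existing files; contrast well-formedness
#' (label, non-empty disjoint groups, known sample ids); FDR level in
#' (0, 1); fewer than 20 negative controls (warning: below the
#' empirical-null calibration floor); 1-vs-1 contrasts (warning: the
#' dispersion estimate then rests entirely on the shrinkage prior).
#'
#' @param config list or path to a YAML file.
#' @return data.frame with columns \code{level}, \code{message};
#'   zero rows if the configuration is clean.
#' @export
validateScreenConfig <- function(config) {
  config <- .load_config(config)
  f <- list()
  add <- function(level, msg) f[[length(f) + 1L]] <<- c(level, msg)

  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (!has_sim && !has_input)
    add("error", "config needs a 'simulate' or an 'input' block")
  if (has_sim && has_input)
    add("error", "config must not have both 'simulate' and 'input' blocks")

  sample_ids <- character(0)
  n_negctrl <- NA_integer_
  if (has_input) {
    for (p in c("library", "counts", "metadata")) {
      if (is.null(config$input[[p]]))
        add("error", sprintf("input block is missing '%s'", p))
      else if (!file.exists(config$input[[p]]))
        add("error", sprintf("input %s file not found: %s", p,
                             config$input[[p]]))
    }
    if (!is.null(config$input$metadata) &&
        file.exists(config$input$metadata)) {
      meta <- try(readSampleMeta(config$input$metadata), silent = TRUE)
      if (inherits(meta, "try-error"))
        add("error", sprintf("invalid sample metadata: %s",
                             attr(meta, "condition")$message))
      else sample_ids <- meta$sample_id
    }
    if (!is.null(config$input$library) &&
        file.exists(config$input$library)) {
      lib <- try(readGuideLibrary(config$input$library), silent = TRUE)
      if (inherits(lib, "try-error"))
        add("error", sprintf("invalid guide library: %s",
                             attr(lib, "condition")$message))
      else n_negctrl <- sum(guideClass(lib) != "targeting")
    }
  }
  if (has_sim && !has_input) {
    sc <- try(.sim_config_from_block(config$simulate,
                                     config$seed %||% 1L), silent = TRUE)
    if (inherits(sc, "try-error"))
      add("error", sprintf("invalid simulate block: %s",
                           attr(sc, "condition")$message))
    else {
      sample_ids <- sc$samples$sample_id
      n_negctrl <- sc$n_safe_harbor + sc$n_non_targeting
    }
  }

  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    add("error", "alpha must lie strictly between 0 and 1")

  if (is.null(config$contrasts) || !length(config$contrasts))
    add("error", "at least one contrast is required")
  for (ct in config$contrasts) {
    lab <- ct$label %||% "<unlabelled>"
    ref <- unlist(ct$reference); cmp <- unlist(ct$comparison)
    if (is.null(ct$label))
      add("error", "every contrast needs a label")
    if (!length(ref) || !length(cmp))
      add("error", sprintf("contrast %s: both groups must be non-empty", lab))
    if (length(intersect(ref, cmp)))
      add("error", sprintf("contrast %s: groups overlap (%s)", lab,
                           paste(intersect(ref, cmp), collapse = ", ")))
    if (length(sample_ids)) {
      unknown <- setdiff(c(ref, cmp), sample_ids)
      if (length(unknown))
        add("error", sprintf("contrast %s: unknown sample id(s): %s", lab,
                             paste(unknown, collapse = ", ")))
    }
    if (length(ref) == 1L && length(cmp) == 1L)
      add("warning", sprintf(
        "contrast %s is 1-vs-1: dispersion rests entirely on the shrinkage prior",
        lab))
  }
  if (!is.na(n_negctrl) && n_negctrl < 20L)
    add("warning", sprintf(
      "only %d negative-control guides: below the empirical-null calibration floor of 20",
      n_negctrl))

  if (length(f))
    data.frame(level = vapply(f, `[`, "", 1L),
               message = vapply(f, `[`, "", 2L))
  else data.frame(level = character(0), message = character(0))
}

#' Run the full screen analysis pipeline
#'
#' Orchestrates: load or simulate the screen; per contrast, compute
#' safe-harbor size factors, dispersions and NB Wald tests; fit the
#' empirical null from negative-control effect sizes; call guides and
#' genes; classify time-course and chemical phenotypes where the config
#' maps contrasts to them; optionally annotate gene calls; write all
#' tables plus a machine-readable \code{report.json} and a
#' \code{MANIFEST} to the output directory. Identical config + seed
#' gives identical outputs.
#'
#' Configuration blocks (YAML or list): \code{simulate} or \code{input}
#' (\code{library}/\code{counts}/\code{metadata} paths);
#' \code{contrasts} (list of \code{label}/\code{reference}/
#' \code{comparison}); \code{alpha}; \code{null} (\code{bandwidth},
#' \code{rule}); \code{classify} (\code{require_both_sig});
#' \code{timecourse} (list of \code{system}/\code{d20}/\code{d30}
#' contrast labels); \code{chemical} (contrast labels);
#' \code{annotation} (\code{path}, \code{key}); \code{seed};
#' \code{outdir}.
#'
#' @param config list or YAML path.
#' @param outdir output directory (default from config).
#' @return the run report, invisibly.
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- .load_config(config)
  findings <- validateScreenConfig(config)
  if (any(findings$level == "error"))
    .stop2("validationError", "invalid configuration:\n%s",
           paste("-", findings$message[findings$level == "error"],
                 collapse = "\n"))
  for (w in findings$message[findings$level == "warning"])
    warning(w, call. = FALSE)

  outdir <- outdir %||% config$outdir %||% "screen_results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  rule <- config$null$rule %||% "conjunction"
  bandwidth <- config$null$bandwidth %||% "silverman"
  require_both_sig <- config$classify$require_both_sig %||% TRUE
  set.seed(seed)

  written <- character(0)
  stage <- "load"
  report <- list(seed = seed, alpha = alpha, rule = rule,
                 package = as.character(utils::packageVersion("crisprDiffSel")),
                 config_hash = .config_hash(config), contrasts = list())
  emit <- function(path) { written <<- c(written, path); path }

  on_fail <- function(e) {
    writeLines(c(sprintf("INCOMPLETE at stage: %s", stage), written),
               file.path(outdir, "MANIFEST"))
    .stop2("stageError", "pipeline failed at stage '%s': %s", stage,
           conditionMessage(e))
  }
  tryCatch({
    if (!is.null(config$simulate)) {
      se <- simulateScreen(.sim_config_from_block(config$simulate, seed))
      lib <- guideLibraryOf(se)
      writeCounts(se, emit(file.path(outdir, "counts.tsv")))
      writeSampleMeta(se, emit(file.path(outdir, "samples.tsv")))
      writeSimTruth(se, emit(file.path(outdir, "sim_truth.tsv")))
    } else {
      lib <- readGuideLibrary(config$input$library)
      k <- readCounts(config$input$counts)
      meta <- readSampleMeta(config$input$metadata)
      se <- ScreenExperiment(k, lib, meta)
    }

    stage <- "normalize"
    sf <- controlSizeFactors(se)
    neg_ids <- guideIds(se)[guideClass(se) %in%
                              c("safe_harbor", "non_targeting")]

    stage <- "test"
    gene_calls <- list()
    for (ct in config$contrasts) {
      lab <- ct$label
      res <- diffSel(se, unlist(ct$reference), unlist(ct$comparison),
                     label = lab, sizeFactors = sf)
      writeDiffSel(res, emit(file.path(outdir,
                                       sprintf("diffsel_%s.tsv", lab))))
      stage <- "calibrate"
      null <- fitEmpiricalNull(res[neg_ids, "lfc"][res[neg_ids, "tested"]],
                               bandwidth = bandwidth)
      writeNullSummary(null, emit(file.path(outdir,
                                            sprintf("null_%s.json", lab))))
      stage <- "call"
      gcalls <- callGuides(res, null, alpha = alpha, rule = rule)
      .write_tsv(as.data.frame(gcalls),
                 emit(file.path(outdir, sprintf("guide_calls_%s.tsv", lab))))
      genes <- callGenes(gcalls, lib, label = lab)
      .write_tsv(as.data.frame(genes),
                 emit(file.path(outdir, sprintf("gene_calls_%s.tsv", lab))))
      gene_calls[[lab]] <- genes
      report$contrasts[[lab]] <- list(
        n_guides_tested = sum(res$tested),
        n_sig_guides = sum(gcalls$significant),
        n_guides_depleted = sum(gcalls$direction == "depleted"),
        n_guides_enriched = sum(gcalls$direction == "enriched"),
        null = list(lo_cut = null@loCut, hi_cut = null@hiCut,
                    bandwidth = null@bandwidth,
                    n_controls = null@nControls),
        n_genes = nrow(genes),
        n_sig_genes = sum(genes$significant),
        n_genes_depleted = sum(genes$direction == "depleted"),
        n_genes_enriched = sum(genes$direction == "enriched"),
        n_genes_ambiguous = sum(genes$direction == "ambiguous"))
      stage <- "test"
    }

    stage <- "classify"
    for (tc in config$timecourse) {
      g20 <- gene_calls[[tc$d20]]; g30 <- gene_calls[[tc$d30]]
      r20 <- .gene_lfc(file.path(outdir,
                                 sprintf("diffsel_%s.tsv", tc$d20)), lib)
      r30 <- .gene_lfc(file.path(outdir,
                                 sprintf("diffsel_%s.tsv", tc$d30)), lib)
      genes <- intersect(intersect(g20$gene, g30$gene),
                         intersect(names(r20), names(r30)))
      lab <- classifyTimeCourse(r20[genes], r30[genes],
                                g20$significant[match(genes, g20$gene)],
                                g30$significant[match(genes, g30$gene)],
                                require_both_sig = require_both_sig)
      tcdf <- data.frame(gene = genes, lfc_d20 = r20[genes],
                         lfc_d30 = r30[genes], label = lab)
      .write_tsv(tcdf, emit(file.path(
        outdir, sprintf("timecourse_%s.tsv", tc$system))))
      report$timecourse[[tc$system]] <-
        as.list(table(factor(lab, c("disadvantage", "advantage", "none"))))
    }
    for (lab in unlist(config$chemical)) {
      chem <- classifyChemical(gene_calls[[lab]])
      .write_tsv(as.data.frame(chem),
                 emit(file.path(outdir, sprintf("chemical_%s.tsv", lab))))
      report$chemical[[lab]] <-
        as.list(table(factor(chem$phenotype,
                             c("sensitive", "resistant", "none"))))
    }

    if (!is.null(config$annotation)) {
      stage <- "annotate"
      for (lab in names(gene_calls)) {
        ann <- annotateCalls(gene_calls[[lab]], config$annotation$path,
                             key = config$annotation$key %||% "gene")
        .write_tsv(ann, emit(file.path(
          outdir, sprintf("gene_calls_annotated_%s.tsv", lab))))
      }
    }

    stage <- "report"
    # internal consistency: reported gene counts match written tables
    for (lab in names(gene_calls)) {
      tab <- .read_tsv(file.path(outdir,
                                 sprintf("gene_calls_%s.tsv", lab)))
      stopifnot(nrow(tab) == report$contrasts[[lab]]$n_genes,
                sum(tab$significant) ==
                  report$contrasts[[lab]]$n_sig_genes)
    }
    jsonlite::write_json(report,
                         emit(file.path(outdir, "report.json")),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c("COMPLETE", written), file.path(outdir, "MANIFEST"))
  }, error = function(e) {
    if (inherits(e, "stageError")) stop(e)
    on_fail(e)
  })
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      .stop2("fileError", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

.sim_config_from_block <- function(block, seed) {
  if (!is.null(block$layout)) {
    lay <- block$layout
    type <- lay$type %||% "timecourse"
    fun <- switch(type, timecourse = timecourseLayout,
                  chemical = chemicalLayout,
                  .stop2("configError", "unknown layout type '%s'", type))
    args <- lapply(lay[setdiff(names(lay), "type")], unlist)
    block$samples <- do.call(fun, args)
    block$layout <- NULL
  }
  if (!is.null(block$effect_model) && !is.data.frame(block$effect_model))
    block$effect_model <- do.call(rbind, lapply(block$effect_model,
                                                as.data.frame))
  if (is.null(block$seed)) block$seed <- seed
  do.call(simConfig, block)
}

# mean per-gene lfc across a gene's tested guides, from a written
# diffsel table; named numeric by gene
.gene_lfc <- function(diffsel_path, lib) {
  tab <- .read_tsv(diffsel_path)
  gene <- guideGene(lib)[match(tab$sgrna_id, guideIds(lib))]
  ok <- !is.na(gene) & tab$tested
  v <- tapply(tab$lfc[ok], gene[ok], mean)
  stats::setNames(as.numeric(v), names(v))
}
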