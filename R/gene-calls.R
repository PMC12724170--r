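#' Aggregate sgRNA calls to gene-level calls
#'
#' With one guide per gene per sub-library, a gene is deemed significant
#' if at least one of its guides is significantly differentially
#' selected. The gene direction is the shared direction of its
#' significant guides; genes with significant guides in both directions
#' are reported as \code{ambiguous} rather than dropped.
#'
#' @param guideCalls DataFrame from [callGuides()] (columns
#'   \code{sgrna_id}, \code{significant}, \code{direction}).
#' @param library a [GuideLibrary-class] resolving guides to genes;
#'   control guides are excluded from gene calls.
#' @param label contrast label carried into the output.
#' @return a DataFrame with one row per targeted gene: \code{gene},
#'   \code{significant}, \code{direction} (\code{depleted},
#'   \code{enriched}, \code{ambiguous}, \code{none}),
#'   \code{n_sig_guides}, \code{supporting} (comma-separated significant
#'   guide ids) and \code{contrast}.
#' @export
callGenes <- function(guideCalls, library, label = NA_character_) {
  stopifnot(is(library, "GuideLibrary"))
  ids <- as.character(guideCalls$sgrna_id)
  idx <- match(ids, guideIds(library))
  if (anyNA(idx))
    .stop2("referenceError", "sgRNA id(s) absent from library: %s",
           paste(head(ids[is.na(idx)], 10L), collapse = ", "))
  gene <- guideGene(library)[idx]
  targeting <- guideClass(library)[idx] == "targeting"
  keep <- targeting & !is.na(gene)
  gene <- gene[keep]
  sig <- as.logical(guideCalls$significant)[keep]
  dir <- as.character(guideCalls$direction)[keep]
  id <- ids[keep]

  genes <- sort(unique(gene))
  out <- lapply(genes, function(g) {
    i <- which(gene == g)
    si <- i[sig[i]]
    dirs <- unique(dir[si])
    d <- if (!length(si)) "none"
         else if (length(dirs) == 1L) dirs
         else "ambiguous"
    list(gene = g, significant = length(si) > 0L, direction = d,
         n_sig_guides = length(si),
         supporting = paste(id[si], collapse = ","))
  })
  DataFrame(gene = genes,
            significant = vapply(out, `[[`, TRUE, "significant"),
            direction = vapply(out, `[[`, "", "direction"),
            n_sig_guides = vapply(out, `[[`, 1L, "n_sig_guides"),
            supporting = vapply(out, `[[`, "", "supporting"),
            contrast = label)
}

#' Classify time-course growth phenotypes
#'
#' Labels each gene by the pattern of its log2 fold changes at the two
#' harvest timepoints versus baseline: \code{disadvantage} for
#' significant, consistently increasing depletion
#' (\eqn{lfc_{d30} \le lfc_{d20} < 0}), \code{advantage} for significant,
#' consistently non-decreasing enrichment
#' (\eqn{lfc_{d30} \ge lfc_{d20} > 0}), otherwise \code{none}.
#' Inequalities are non-strict, so an exact tie between timepoints
#' still counts as consistent.
#'
#' @param lfc_d20,lfc_d30 numeric, log2 fold changes vs baseline at the
#'   earlier/later timepoint (vectorized).
#' @param sig_d20,sig_d30 logical significance flags per timepoint.
#' @param require_both_sig require significance at both timepoints
#'   (default) or at either one.
#' @return character vector of labels: \code{"disadvantage"},
#'   \code{"advantage"} or \code{"none"}.
#' @examples
#' classifyTimeCourse(-2.86, -3.15, TRUE, TRUE)  # disadvantage
#' classifyTimeCourse(1.08, 1.08, TRUE, TRUE)    # advantage (tie allowed)
#' classifyTimeCourse(-2.0, -1.5, TRUE, TRUE)    # none (not monotone)
#' @export
classifyTimeCourse <- function(lfc_d20, lfc_d30, sig_d20, sig_d30,
                               require_both_sig = TRUE) {
  stopifnot(is.finite(lfc_d20), is.finite(lfc_d30))
  sig_ok <- if (require_both_sig) sig_d20 & sig_d30 else sig_d20 | sig_d30
  ifelse(sig_ok & lfc_d30 <= lfc_d20 & lfc_d20 < 0, "disadvantage",
         ifelse(sig_ok & lfc_d30 >= lfc_d20 & lfc_d20 > 0, "advantage",
                "none"))
}

#' Classify chemical-screen phenotypes from gene calls
#'
#' In a treated-vs-control contrast, depletion of a gene's guides under
#' drug marks the gene \code{sensitive} (its disruption sensitizes cells
#' to the compound); enrichment marks it \code{resistant}. Ambiguous or
#' non-significant genes are \code{none}.
#'
#' @param geneCalls DataFrame from [callGenes()] on a treated-vs-control
#'   contrast.
#' @return DataFrame with \code{gene} and \code{phenotype}
#'   (\code{sensitive}, \code{resistant}, \code{none}).
#' @export
classifyChemical <- function(geneCalls) {
  phen <- ifelse(geneCalls$direction == "depleted", "sensitive",
                 ifelse(geneCalls$direction == "enriched", "resistant",
                        "none"))
  DataFrame(gene = geneCalls$gene, phenotype = phen)
}

#' Overlap of gene calls between two conditions
#'
#' Compares the significant gene sets of two screens over the same gene
#' universe (e.g. 2D vs 3D), partitioning the shared genes by direction
#' concordance.
#'
#' @param callsA,callsB DataFrames with columns \code{gene},
#'   \code{significant}, \code{direction} ([callGenes()] output).
#' @return a list: \code{a_only}, \code{b_only}, \code{shared} (counts),
#'   \code{shared_genes}, \code{concordant} (count),
#'   \code{concordant_genes}, \code{direction_shared} (named directions
#'   of concordant genes).
#' @export
compareConditions <- function(callsA, callsB) {
  sa <- as.character(callsA$gene[as.logical(callsA$significant)])
  sb <- as.character(callsB$gene[as.logical(callsB$significant)])
  shared <- intersect(sa, sb)
  da <- stats::setNames(as.character(callsA$direction),
                        as.character(callsA$gene))[shared]
  db <- stats::setNames(as.character(callsB$direction),
                        as.character(callsB$gene))[shared]
  conc <- shared[da == db]
  list(a_only = length(setdiff(sa, shared)),
       b_only = length(setdiff(sb, shared)),
       shared = length(shared), shared_genes = shared,
       concordant = length(conc), concordant_genes = conc,
       direction_shared = da[match(conc, shared)])
}

#' Annotate gene calls with an external keyed table
#'
#' Left join preserving every gene call; character annotation columns of
#' unmatched genes are filled with \code{"No data"} (numeric columns
#' with NA). Duplicate keys in the annotation table are rejected.
#'
#' @param geneCalls DataFrame/data.frame of gene calls with a
#'   \code{gene} column.
#' @param annotation data.frame (or TSV path) carrying the annotation.
#' @param key name of the key column in \code{annotation} matched
#'   against \code{gene} (default \code{"gene"}).
#' @return a data.frame: the gene calls plus the annotation columns.
#' @export
annotateCalls <- function(geneCalls, annotation, key = "gene") {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- .read_tsv(annotation)
  annotation <- as.data.frame(annotation)
  .require_cols(annotation, key, "annotation table")
  kv <- as.character(annotation[[key]])
  if (anyDuplicated(kv))
    .stop2("validationError", "duplicate annotation key(s): %s",
           paste(unique(kv[duplicated(kv)]), collapse = ", "))
  gc <- as.data.frame(geneCalls)
  idx <- match(as.character(gc$gene), kv)
  ann <- annotation[idx, setdiff(colnames(annotation), key), drop = FALSE]
  for (col in colnames(ann)) {
    if (is.character(ann[[col]]) || is.factor(ann[[col]])) {
      ann[[col]] <- as.character(ann[[col]])
      ann[[col]][is.na(idx)] <- "No data"
    }
  }
  rownames(ann) <- NULL
  cbind(gc, ann)
}
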