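#' @title Response labeling
#' @description Converts per-TF differential-expression tables into binary
#'   responsive labels and defines per-TF bound-gene sets used by the SHAP
#'   bin analyses. All thresholds are strict inequalities.
#' @name labels
NULL

#' Responsive call from a replicated DE table
#'
#' A gene is responsive iff adjusted p < `padj_max` and |log2 fold-change|
#' > `lfc_min` (both strict).
#'
#' @param de DE data.frame with `gene_id`, `log2fc`, `padj`.
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 0.5).
#' @return named integer vector (0/1) per gene.
#' @export
call_responsive_de <- function(de, padj_max = 0.05, lfc_min = 0.5) {
  if (is.null(de$padj) || all(is.na(de$padj))) {
    stop("padj absent: use call_responsive_fc_only() for no-replicate data")
  }
  resp <- as.integer(!is.na(de$padj) & de$padj < padj_max &
                     abs(de$log2fc) > lfc_min)
  stats::setNames(resp, de$gene_id)
}

#' Responsive call from fold-change only (no-replicate datasets)
#' @inheritParams call_responsive_de
#' @return named integer vector (0/1) per gene.
#' @export
call_responsive_fc_only <- function(de, lfc_min = 0.5) {
  stats::setNames(as.integer(abs(de$log2fc) > lfc_min), de$gene_id)
}

#' Responsive call from shrunken fold-changes
#'
#' For tables whose fold-changes were already shrunken toward zero, any
#' gene with a nonzero shrunken value is responsive.
#'
#' @param de DE data.frame with `gene_id`, `shrunken_lfc`.
#' @return named integer vector (0/1) per gene.
#' @export
call_responsive_nonzero <- function(de) {
  if (is.null(de$shrunken_lfc)) stop("shrunken_lfc column absent")
  stats::setNames(as.integer(de$shrunken_lfc != 0), de$gene_id)
}

#' Build response labels for a set of TFs
#'
#' Applies a labeling rule to each TF's DE table over a fixed gene
#' universe. Genes absent from a TF's table are labeled nonresponsive.
#' Also records each TF's response fraction and, when the TF's own gene is
#' in its table, the perturbation efficacy |log2FC| of that gene.
#'
#' @param de_tables named list (per TF) of DE data.frames.
#' @param genes character vector: the gene universe.
#' @param rule `"de"`, `"fc_only"`, or `"nonzero"`.
#' @param tf_genes optional named character vector mapping tf_id to the
#'   gene encoding that TF (for efficacy).
#' @param padj_max,lfc_min thresholds for the chosen rule.
#' @return object of class `response_labels`: `tab` (tf_id, gene_id,
#'   responsive), `fractions`, `efficacy`.
#' @export
build_response_labels <- function(de_tables, genes,
                                  rule = c("de", "fc_only", "nonzero"),
                                  tf_genes = NULL,
                                  padj_max = 0.05, lfc_min = 0.5) {
  rule <- match.arg(rule)
  tfs <- names(de_tables)
  tab_list <- lapply(tfs, function(tf) {
    de <- de_tables[[tf]]
    called <- switch(rule,
      de = call_responsive_de(de, padj_max, lfc_min),
      fc_only = call_responsive_fc_only(de, lfc_min),
      nonzero = call_responsive_nonzero(de))
    resp <- stats::setNames(integer(length(genes)), genes)
    common <- intersect(genes, names(called))
    resp[common] <- called[common]
    data.frame(tf_id = tf, gene_id = genes, responsive = unname(resp),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab_list)
  fractions <- vapply(tfs, function(tf) {
    mean(tab$responsive[tab$tf_id == tf])
  }, numeric(1))
  efficacy <- stats::setNames(rep(NA_real_, length(tfs)), tfs)
  if (!is.null(tf_genes)) {
    for (tf in tfs) {
      g <- tf_genes[tf]
      de <- de_tables[[tf]]
      if (!is.na(g) && g %in% de$gene_id) {
        efficacy[tf] <- abs(de$log2fc[match(g, de$gene_id)])
      }
    }
  }
  structure(list(tab = tab, fractions = fractions, efficacy = efficacy),
            class = "response_labels")
}

#' @export
print.response_labels <- function(x, ...) {
  cat(sprintf("response_labels: %d TFs x %d genes; median response fraction %.3f\n",
              length(x$fractions), nrow(x$tab) / length(x$fractions),
              stats::median(x$fractions)))
  invisible(x)
}

#' Label vector aligned to the instances of a feature matrix
#' @param labels a `response_labels`.
#' @param fm a `feature_matrix`.
#' @return integer vector of 0/1 labels, one per instance row.
#' @export
labels_for_instances <- function(labels, fm) {
  key <- paste(labels$tab$tf_id, labels$tab$gene_id)
  idx <- match(paste(fm$instances$tf_id, fm$instances$gene_id), key)
  if (anyNA(idx)) stop("labels missing for some (TF, gene) instances")
  labels$tab$responsive[idx]
}

#' Per-TF bound-gene sets
#'
#' A gene is bound by a TF iff at least one of that TF's peaks with signal
#' >= `min_signal` is anchored (summit, else midpoint) within the gene's
#' promoter window.
#'
#' @param peaks_by_tf named list (per TF) of peak data.frames.
#' @param regions_list named list (per gene) of [build_regions()] results.
#' @param min_signal minimum peak signal.
#' @return named list (per TF) of bound gene_id character vectors.
#' @export
bound_gene_set <- function(peaks_by_tf, regions_list, min_signal = 0) {
  lapply(peaks_by_tf, function(pk) {
    if (is.null(pk) || nrow(pk) == 0L) return(character())
    pk <- pk[pk$signal >= min_signal, , drop = FALSE]
    if (nrow(pk) == 0L) return(character())
    anchor <- ifelse(is.na(pk$summit),
                     floor((pk$start + pk$end) / 2),
                     pk$start + pk$summit)
    bound <- vapply(regions_list, function(rg) {
      pi <- rg$promoter_interval
      any(pk$chrom == rg$chrom & anchor >= pi[1L] & anchor < pi[2L])
    }, logical(1))
    names(regions_list)[bound]
  })
}
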