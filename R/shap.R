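#' @title SHAP attribution and aggregation
#' @description Per-instance per-feature SHAP values for the fold models
#'   (every instance is explained by the model that held out its TF, so
#'   explanations are on unseen TFs), plus the aggregations used to
#'   summarize feature influence: signed sums per feature class, net
#'   influence, positional profiles over bound genes, bound-responsive vs
#'   bound-nonresponsive bin tests, upstream/downstream importance, and
#'   input-vs-SHAP correlations.
#' @name shap_explain
NULL

#' Compute SHAP attributions for all instances
#'
#' Uses the tree-path-dependent TreeSHAP algorithm of the boosting
#' library. In margin (log-odds) space the attributions are exact: for
#' every instance, base value + sum of attributions = the model's margin
#' output (local accuracy). The probability option maps the base value and
#' prediction through the logistic and rescales each instance's
#' attributions proportionally so they sum to the probability deviation.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param fm the `feature_matrix` the models were trained on.
#' @param output_space `"margin"` (exact local accuracy) or
#'   `"probability"`.
#' @param engine `"exact"` (double-precision [tree_shap_values()]) or
#'   `"xgboost"` (the library's single-precision contribution predictor).
#' @return object of class `attribution_matrix`: `S` (same dimensions as
#'   `fm$X`), `base` (per instance), `output` (per-instance model output in
#'   the chosen space), `output_space`.
#' @export
compute_attributions <- function(cv, fm,
                                 output_space = c("margin", "probability"),
                                 engine = c("exact", "xgboost")) {
  output_space <- match.arg(output_space)
  engine <- match.arg(engine)
  S <- matrix(NA_real_, nrow = nrow(fm$X), ncol = ncol(fm$X),
              dimnames = dimnames(fm$X))
  base <- rep(NA_real_, nrow(fm$X))
  output <- rep(NA_real_, nrow(fm$X))
  for (mod in cv$models) {
    if (!identical(mod$feature_names, colnames(fm$X))) {
      stop("feature order mismatch between fold model and matrix")
    }
    rows <- which(fm$instances$tf_id %in% mod$test_tfs)
    if (length(rows) == 0L) next
    if (engine == "exact") {
      res <- tree_shap_values(mod$booster, fm$X[rows, , drop = FALSE])
      S[rows, ] <- res$phi
      base[rows] <- res$base
      output[rows] <- res$margin
    } else {
      d <- xgboost::xgb.DMatrix(fm$X[rows, , drop = FALSE], nthread = 1L)
      contrib <- predict(mod$booster, d, predcontrib = TRUE)
      S[rows, ] <- contrib[, seq_len(ncol(fm$X)), drop = FALSE]
      base[rows] <- contrib[, ncol(contrib)]
      output[rows] <- base[rows] + rowSums(S[rows, , drop = FALSE])
    }
  }
  if (anyNA(base)) stop("some instances were not explained by any fold")
  if (output_space == "probability") {
    p <- stats::plogis(output); b <- stats::plogis(base)
    scale <- ifelse(abs(output - base) < 1e-12, 0,
                    (p - b) / (output - base))
    S <- S * scale
    base <- b
    output <- p
  }
  structure(list(S = S, base = base, output = output,
                 output_space = output_space, engine = engine,
                 instances = fm$instances),
            class = "attribution_matrix")
}

.class_columns <- function(fm, cls) {
  which(fm$feature_info$class == cls)
}

#' Feature classes of a matrix
#' @param fm a `feature_matrix`.
#' @return character vector of class labels (dinucleotides pooled).
#' @export
feature_classes <- function(fm) unique(fm$feature_info$class)

#' Signed SHAP sums and net influence per feature class
#'
#' For each TF, feature class and gene group: `positive_sum` is the mean
#' over the group's genes of the summed positive per-bin SHAPs of the
#' class, `negative_sum` the analogue for negatives, `net_influence` their
#' sum (the sum of all the class's SHAPs regardless of sign or position,
#' averaged over the group), and `global_importance` the mean |SHAP| over
#' the class's columns and the group's genes.
#'
#' @param attr an `attribution_matrix`.
#' @param fm the matching `feature_matrix`.
#' @param groups named list per TF of lists mapping group label to gene_id
#'   vectors (e.g. from [gene_groups()]).
#' @return data.frame: tf_id, class, group, n_genes, positive_sum,
#'   negative_sum, net_influence, global_importance.
#' @export
signed_sums <- function(attr, fm, groups) {
  classes <- feature_classes(fm)
  out <- list()
  for (tf in names(groups)) {
    tf_rows <- which(fm$instances$tf_id == tf)
    gmap <- stats::setNames(tf_rows, fm$instances$gene_id[tf_rows])
    for (grp in names(groups[[tf]])) {
      genes <- intersect(groups[[tf]][[grp]], names(gmap))
      if (length(genes) == 0L) {
        warning("empty gene group ", grp, " for ", tf)
        rows <- NULL
      } else rows <- gmap[genes]
      for (cls in classes) {
        cols <- .class_columns(fm, cls)
        if (is.null(rows)) {
          pos <- neg <- gi <- NA_real_
        } else {
          sub <- attr$S[rows, cols, drop = FALSE]
          pos <- mean(rowSums(pmax(sub, 0)))
          neg <- mean(rowSums(pmin(sub, 0)))
          gi <- mean(abs(sub))
        }
        out[[length(out) + 1L]] <- data.frame(
          tf_id = tf, class = cls, group = grp,
          n_genes = length(genes), positive_sum = pos,
          negative_sum = neg, net_influence = pos + neg,
          global_importance = gi, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Standard gene groups per TF
#'
#' @param labels a `response_labels`.
#' @param bound optional [bound_gene_set()] result.
#' @return named list per TF: `all`, `responsive`, `nonresponsive`, and
#'   when `bound` is given also `bound`, `bound_responsive`,
#'   `bound_nonresponsive`.
#' @export
gene_groups <- function(labels, bound = NULL) {
  tfs <- unique(labels$tab$tf_id)
  stats::setNames(lapply(tfs, function(tf) {
    sub <- labels$tab[labels$tab$tf_id == tf, ]
    resp <- sub$gene_id[sub$responsive == 1L]
    nonresp <- sub$gene_id[sub$responsive == 0L]
    g <- list(all = sub$gene_id, responsive = resp, nonresponsive = nonresp)
    if (!is.null(bound)) {
      b <- bound[[tf]]
      g$bound <- b
      g$bound_responsive <- intersect(b, resp)
      g$bound_nonresponsive <- intersect(b, nonresp)
    }
    g
  }), tfs)
}

#' Positional profile of mean signed SHAP over promoter bins
#'
#' For each TF, the mean signed SHAP value of a track in each promoter
#' bin over a gene group (by default the TF's bound genes), bins ordered
#' 5' to 3'.
#'
#' @param attr an `attribution_matrix`.
#' @param fm the matching `feature_matrix`.
#' @param genes_by_tf named list per TF of gene ids (e.g. a
#'   [bound_gene_set()]).
#' @param track track label (default `"tf_binding"`).
#' @return matrix TF x promoter bin of mean signed SHAP (NA row for an
#'   empty group).
#' @export
positional_profile <- function(attr, fm, genes_by_tf,
                               track = "tf_binding") {
  info <- fm$feature_info
  cols <- which(info$track == track & info$kind == "promoter")
  cols <- cols[order(info$bin_index[cols])]
  tfs <- names(genes_by_tf)
  out <- matrix(NA_real_, nrow = length(tfs), ncol = length(cols),
                dimnames = list(tfs, info$bin[cols]))
  for (tf in tfs) {
    rows <- which(fm$instances$tf_id == tf &
                  fm$instances$gene_id %in% genes_by_tf[[tf]])
    if (length(rows) == 0L) next
    out[tf, ] <- colMeans(attr$S[rows, cols, drop = FALSE])
  }
  out
}

.wilcox_p <- function(x, y, alternative) {
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  exact <- length(x) <= 10L && length(y) <= 10L
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                      exact = exact, correct = TRUE)$p.value)
}

#' Bound-responsive vs bound-nonresponsive SHAP test per promoter bin
#'
#' One-sided Wilcoxon rank-sum (responsive > nonresponsive) on the signed
#' SHAP values of a track in each promoter bin, among the TF's bound
#' genes. Exact enumeration when both groups have at most 10 genes,
#' otherwise the normal approximation with tie correction.
#'
#' @param attr an `attribution_matrix`.
#' @param fm the matching `feature_matrix`.
#' @param groups a [gene_groups()] result built with a bound set.
#' @param track track label.
#' @param alpha per-bin significance threshold for the count.
#' @return list: `p` matrix (TF x bin), `n_significant_bins` per TF.
#' @export
bin_group_test <- function(attr, fm, groups, track = "tf_binding",
                           alpha = 0.05) {
  info <- fm$feature_info
  cols <- which(info$track == track & info$kind == "promoter")
  cols <- cols[order(info$bin_index[cols])]
  tfs <- names(groups)
  p <- matrix(NA_real_, nrow = length(tfs), ncol = length(cols),
              dimnames = list(tfs, info$bin[cols]))
  for (tf in tfs) {
    br <- groups[[tf]]$bound_responsive
    bn <- groups[[tf]]$bound_nonresponsive
    tf_rows <- which(fm$instances$tf_id == tf)
    gmap <- stats::setNames(tf_rows, fm$instances$gene_id[tf_rows])
    rr <- gmap[intersect(br, names(gmap))]
    rn <- gmap[intersect(bn, names(gmap))]
    for (j in seq_along(cols)) {
      p[tf, j] <- .wilcox_p(attr$S[rr, cols[j]], attr$S[rn, cols[j]],
                            alternative = "greater")
    }
  }
  list(p = p,
       n_significant_bins = apply(p, 1L, function(r) sum(r < alpha,
                                                         na.rm = TRUE)))
}

#' Upstream vs downstream global importance of a feature class
#'
#' For each TF, the mean |SHAP| of the class over all genes and all
#' promoter bins upstream of the TSS, and likewise downstream; plus an
#' across-TF Wilcoxon rank-sum test comparing the two sides.
#'
#' @param attr an `attribution_matrix`.
#' @param fm the matching `feature_matrix`.
#' @param class feature class label (e.g. an HM track name).
#' @return list: `per_tf` data.frame (tf_id, upstream, downstream),
#'   `p_value` of the across-TF test (two-sided),
#'   `p_downstream_greater` (one-sided).
#' @export
updown_importance <- function(attr, fm, class) {
  info <- fm$feature_info
  cls_cols <- which(info$class == class & info$kind == "promoter")
  if (length(cls_cols) == 0L) stop("no promoter columns for class ", class)
  up <- cls_cols[info$side[cls_cols] == "upstream"]
  dn <- cls_cols[info$side[cls_cols] == "downstream"]
  tfs <- unique(fm$instances$tf_id)
  per_tf <- do.call(rbind, lapply(tfs, function(tf) {
    rows <- which(fm$instances$tf_id == tf)
    data.frame(tf_id = tf,
               upstream = mean(abs(attr$S[rows, up, drop = FALSE])),
               downstream = mean(abs(attr$S[rows, dn, drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  list(per_tf = per_tf,
       p_value = .wilcox_p(per_tf$downstream, per_tf$upstream, "two.sided"),
       p_downstream_greater = .wilcox_p(per_tf$downstream, per_tf$upstream,
                                        "greater"))
}

#' Spearman correlation between a feature's inputs and its SHAP values
#'
#' @param attr an `attribution_matrix`.
#' @param fm the matching `feature_matrix`.
#' @param feature feature (column) name, e.g. `"gex_level@gene"`.
#' @return named numeric vector: one correlation per TF (NA when the
#'   feature has zero variance within the TF's instances).
#' @export
input_attribution_correlation <- function(attr, fm, feature) {
  j <- match(feature, colnames(fm$X))
  if (is.na(j)) stop("unknown feature: ", feature)
  tfs <- unique(fm$instances$tf_id)
  vapply(stats::setNames(tfs, tfs), function(tf) {
    rows <- which(fm$instances$tf_id == tf)
    x <- fm$X[rows, j]
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(stats::cor(x, attr$S[rows, j], method = "spearman"))
  }, numeric(1))
}
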