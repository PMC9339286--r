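#' @title Exact TreeSHAP engine
#' @description Double-precision path-dependent TreeSHAP over the dumped
#'   trees of a fitted booster. Per tree, the attributions sum exactly to
#'   leaf(x) minus the cover-weighted expected leaf value, so the local
#'   accuracy identity base + sum(phi) = margin output holds to numerical
#'   precision; the boosting library's own (single-precision) contribution
#'   predictor serves as an independent cross-check in the test suite.
#' @name treeshap
NULL

# Flatten a booster into node-parallel arrays (one block per tree).
.model_trees <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  dt <- dt[order(dt$Tree, dt$Node), , drop = FALSE]
  is_leaf <- dt$Feature == "Leaf"
  feat <- match(dt$Feature, feature_names) - 1L
  if (any(is.na(feat) & !is_leaf)) {
    stop("model features not found in the supplied feature names")
  }
  node_of <- function(s) ifelse(is.na(s), -1L,
                                as.integer(sub("^.*-", "", s)))
  counts <- as.integer(table(factor(dt$Tree, levels = unique(dt$Tree))))
  list(tree_offset = c(0L, cumsum(counts)),
       feature = ifelse(is_leaf, -1L, feat),
       split = ifelse(is_leaf, 0, dt$Split),
       yes = node_of(dt$Yes), no = node_of(dt$No),
       value = ifelse(is_leaf, dt$Gain, 0),
       cover = dt$Cover)
}

.base_margin <- function(booster) {
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(
    booster, raw_format = "json")))
  bs <- as.numeric(j$learner$learner_model_param$base_score)
  stats::qlogis(bs)
}

#' Exact SHAP values of a booster on a data matrix
#'
#' @param booster a fitted `xgb.Booster` (binary logistic objective).
#' @param X numeric matrix whose columns match the training features.
#' @return list: `phi` (n x p attribution matrix), `base` (scalar expected
#'   margin over the training distribution), `margin` (double-precision
#'   margin output per row; `base + rowSums(phi)` equals it to numerical
#'   precision).
#' @export
tree_shap_values <- function(booster, X) {
  tr <- .model_trees(booster, colnames(X))
  out <- .treeshap_cpp(X, tr$tree_offset, tr$feature, tr$split, tr$yes,
                       tr$no, tr$value, tr$cover, .base_margin(booster))
  colnames(out$phi) <- colnames(X)
  out
}
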