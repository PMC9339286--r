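# Brute-force Shapley oracle for small tree ensembles, independent of the
# package's TreeSHAP engine. The conditional expectation E[f(x) | x_S]
# follows the tree paths: splits on features in S follow x, splits on
# other features average the children weighted by cover.
oracle_trees <- function(booster) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  dt <- dt[order(dt$Tree, dt$Node), , drop = FALSE]
  split(dt, dt$Tree)
}

# round a double through float32, replicating the booster's comparisons
float32 <- function(v) {
  readBin(writeBin(as.vector(v, "numeric"), raw(), size = 4L),
          "numeric", size = 4L, n = length(v))
}

oracle_expected <- function(nodes, x, S) {
  rec <- function(node_idx) {
    nd <- nodes[nodes$Node == node_idx, ]
    if (nd$Feature == "Leaf") return(nd$Gain)
    child <- function(id) as.integer(sub("^.*-", "", id))
    if (nd$Feature %in% S) {
      nxt <- if (float32(x[[nd$Feature]]) < float32(nd$Split)) nd$Yes
             else nd$No
      rec(child(nxt))
    } else {
      cy <- nodes[nodes$Node == child(nd$Yes), "Cover"]
      cn <- nodes[nodes$Node == child(nd$No), "Cover"]
      (cy * rec(child(nd$Yes)) + cn * rec(child(nd$No))) / (cy + cn)
    }
  }
  rec(0L)
}

brute_shap <- function(booster, x, feature_names) {
  trees <- oracle_trees(booster)
  v <- function(S) {
    sum(vapply(trees, oracle_expected, numeric(1), x = x, S = S))
  }
  p <- length(feature_names)
  phi <- stats::setNames(numeric(p), feature_names)
  subsets <- function(set) {
    if (length(set) == 0L) return(list(character()))
    unlist(lapply(0:length(set), function(k) {
      if (k == 0L) list(character()) else {
        apply(utils::combn(set, k), 2L, identity, simplify = FALSE)
      }
    }), recursive = FALSE)
  }
  for (f in feature_names) {
    rest <- setdiff(feature_names, f)
    for (S in subsets(rest)) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1L) /
        factorial(p)
      phi[f] <- phi[f] + w * (v(c(S, f)) - v(S))
    }
  }
  phi
}
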