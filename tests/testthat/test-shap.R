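test_that("attributions match exhaustive Shapley on small trees", {
  # depth-1 stump, 2 features
  tb <- toy_booster(n = 300, p = 2, nrounds = 1, max_depth = 1)
  res <- tree_shap_values(tb$booster, tb$X[1:20, , drop = FALSE])
  for (i in 1:20) {
    phi <- brute_shap(tb$booster, as.list(tb$X[i, ]), colnames(tb$X))
    expect_equal(unname(res$phi[i, ]), unname(phi), tolerance = 1e-8)
  }
  # depth-2 trees, 4 features, several rounds (the dumped float32 leaf
  # and cover values accumulate in different orders in the two methods)
  tb2 <- toy_booster(n = 400, p = 4, nrounds = 3, max_depth = 2, seed = 2)
  res2 <- tree_shap_values(tb2$booster, tb2$X[1:10, , drop = FALSE])
  for (i in 1:10) {
    phi <- brute_shap(tb2$booster, as.list(tb2$X[i, ]), colnames(tb2$X))
    expect_equal(unname(res2$phi[i, ]), unname(phi), tolerance = 1e-6)
  }
})

test_that("an ensemble with no splits attributes nothing", {
  # min_child_weight larger than the data forces single-leaf trees
  tb <- toy_booster(n = 100, p = 2, nrounds = 3, max_depth = 3,
                    min_child_weight = 1e6)
  res <- tree_shap_values(tb$booster, tb$X[1:5, , drop = FALSE])
  expect_true(all(res$phi == 0))
  expect_equal(res$margin, rep(res$base, 5), tolerance = 1e-12)
})

test_that("local accuracy holds exactly and matches the booster", {
  fx <- yeast_fx()
  at <- yeast_attr()
  expect_lt(max(abs(at$base + rowSums(at$S) - at$output)), 1e-10)
  # double-precision margins agree with the booster's float pipeline
  expect_lt(max(abs(at$output - fx$runs$full$cv$predictions$margin)),
            1e-4)
  # independent cross-check against the library's contribution predictor
  mod <- fx$runs$full$cv$models[[1L]]
  rows <- which(fx$fm$instances$tf_id %in% mod$test_tfs)[1:50]
  d <- xgboost::xgb.DMatrix(fx$fm$X[rows, , drop = FALSE], nthread = 1)
  co <- predict(mod$booster, d, predcontrib = TRUE)
  expect_lt(max(abs(co[, -ncol(co)] - at$S[rows, ])), 1e-4)
})

test_that("probability-space attributions sum to the probability deviation", {
  fx <- yeast_fx()
  at <- compute_attributions(fx$runs$full$cv, fx$runs$full$fm,
                             output_space = "probability")
  expect_lt(max(abs(at$base + rowSums(at$S) - at$output)), 1e-8)
  expect_true(all(at$output >= 0 & at$output <= 1))
})

# hand-built attribution object over a tiny matrix
mk_attr <- function(S, fm) {
  structure(list(S = S, base = rep(0, nrow(S)), output = rowSums(S),
                 output_space = "margin", instances = fm$instances),
            class = "attribution_matrix")
}

mk_tiny_fm <- function(S_cols, genes, tfs) {
  sch <- bin_scheme("yeast")
  gf <- matrix(0, length(genes), length(S_cols),
               dimnames = list(genes, S_cols))
  bins <- scheme_bins(sch)$bin
  bf <- lapply(stats::setNames(seq_along(tfs), tfs), function(i) {
    matrix(0, length(genes), 15,
           dimnames = list(genes, paste0("tf_binding@", bins)))
  })
  assemble_feature_matrix(gf, bf, sch)
}

test_that("signed sums and net influence follow the stated arithmetic", {
  fm <- mk_tiny_fm(c("H3K4me3@prom_b01", "H3K4me3@prom_b02",
                     "H3K4me3@prom_b03"), c("g1", "g2"), "TFa")
  S <- matrix(0, 2, ncol(fm$X), dimnames = list(NULL, colnames(fm$X)))
  S[1, c("H3K4me3@prom_b01", "H3K4me3@prom_b02", "H3K4me3@prom_b03")] <-
    c(0.1, 0.2, -0.05)
  S[2, c("H3K4me3@prom_b01", "H3K4me3@prom_b02", "H3K4me3@prom_b03")] <-
    c(0.15, 0, 0)
  at <- mk_attr(S, fm)
  groups <- list(TFa = list(all = c("g1", "g2"), one = "g1"))
  out <- signed_sums(at, fm, groups)
  hm1 <- out[out$class == "H3K4me3" & out$group == "one", ]
  expect_equal(hm1$positive_sum, 0.3)
  expect_equal(hm1$negative_sum, -0.05)
  expect_equal(hm1$net_influence, 0.25)
  hm_all <- out[out$class == "H3K4me3" & out$group == "all", ]
  expect_equal(hm_all$net_influence, mean(c(0.25, 0.15)))
  expect_equal(hm_all$net_influence,
               hm_all$positive_sum + hm_all$negative_sum,
               tolerance = 1e-10)
  # all-zero attributions summarize to zero
  z <- signed_sums(mk_attr(S * 0, fm), fm, groups)
  expect_true(all(z$net_influence == 0))
  expect_warning(signed_sums(at, fm, list(TFa = list(none = character()))),
                 "empty")
})

test_that("attribution completeness: class nets add up to output deviation", {
  fx <- yeast_fx()
  at <- yeast_attr()
  fm <- fx$runs$full$fm
  groups <- gene_groups(fx$labels)
  out <- signed_sums(at, fm, groups)
  tf <- unique(fm$instances$tf_id)[1L]
  rows <- fm$instances$tf_id == tf
  nets <- out$net_influence[out$tf_id == tf & out$group == "all"]
  expect_equal(sum(nets), mean(at$output[rows] - at$base[rows]),
               tolerance = 1e-8)
})

test_that("positional profiles localize the planted proximal binding", {
  fx <- yeast_fx()
  at <- yeast_attr()
  fm <- fx$runs$full$fm
  bound <- fx$bound
  prof <- positional_profile(at, fm, bound)
  info <- fm$feature_info[fm$feature_info$track == "tf_binding", ]
  peak_bin <- colnames(prof)[which.max(colMeans(prof))]
  rel <- info[match(peak_bin, info$bin), c("rel_start", "rel_end")]
  # summits were planted around 150 bp upstream of the TSS
  expect_gte(rel$rel_start, -500)
  expect_lte(rel$rel_end, 0)
  # single bound gene: profile equals that gene's per-bin attributions
  tf <- names(bound)[1L]
  g <- bound[[tf]][1L]
  one <- positional_profile(at, fm, stats::setNames(list(g), tf))
  row <- which(fm$instances$tf_id == tf & fm$instances$gene_id == g)
  cols <- fm$feature_info$track == "tf_binding" &
    fm$feature_info$kind == "promoter"
  expect_equal(unname(one[1, ]), unname(at$S[row, cols]))
  # empty bound set: NA row
  prof_na <- positional_profile(at, fm,
                                stats::setNames(list(character()), tf))
  expect_true(all(is.na(prof_na)))
})

test_that("per-bin rank-sum tests separate shifted groups", {
  fm <- mk_tiny_fm("gex_level@gene", sprintf("g%03d", 1:100), "TFa")
  cols <- which(fm$feature_info$track == "tf_binding")
  resp <- sprintf("g%03d", 1:50); nonresp <- sprintf("g%03d", 51:100)
  groups <- list(TFa = list(bound_responsive = resp,
                            bound_nonresponsive = nonresp))
  # identical samples: one-sided p near 1
  S <- matrix(0, 100, ncol(fm$X), dimnames = list(NULL, colnames(fm$X)))
  S[, cols] <- 1
  res_same <- bin_group_test(mk_attr(S, fm), fm, groups)
  expect_true(all(res_same$p[1, ] > 0.4))
  # responsive group shifted +1 SD: strong rejection in most repetitions
  set.seed(31)
  hits <- replicate(30, {
    S2 <- S
    S2[, cols] <- rnorm(100 * length(cols)) + rep(c(1, 0), each = 50)
    all(bin_group_test(mk_attr(S2, fm), fm, groups)$p[1, ] < 0.01)
  })
  expect_gte(mean(hits), 0.9)
  # 1 vs 1: exact enumeration gives p in {0.5, 1}
  g2 <- list(TFa = list(bound_responsive = "g001",
                        bound_nonresponsive = "g002"))
  S3 <- S; S3[1, cols] <- 2; S3[2, cols] <- 1
  expect_true(all(bin_group_test(mk_attr(S3, fm), fm, g2)$p[1, ] %in%
                    c(0.5, 1)))
})

test_that("upstream/downstream importance splits at the TSS", {
  fm <- mk_tiny_fm("gex_level@gene", sprintf("g%02d", 1:20), "TFa")
  info <- fm$feature_info
  dn <- info$name[info$track == "tf_binding" & info$side %in% "downstream"]
  S <- matrix(0, 20, ncol(fm$X), dimnames = list(NULL, colnames(fm$X)))
  S[, dn] <- 0.5
  res <- updown_importance(mk_attr(S, fm), fm, "tf_binding")
  expect_equal(res$per_tf$upstream, 0)
  expect_equal(res$per_tf$downstream, 0.5)
  # symmetric attributions: equal importance on both sides
  S2 <- matrix(0.25, 20, ncol(fm$X), dimnames = list(NULL, colnames(fm$X)))
  res2 <- updown_importance(mk_attr(S2, fm), fm, "tf_binding")
  expect_equal(res2$per_tf$upstream, res2$per_tf$downstream)
  expect_error(updown_importance(mk_attr(S, fm), fm, "missing_class"),
               "no promoter columns")
})

test_that("planted downstream histone effect shows up as asymmetry", {
  fx <- yeast_fx()
  at <- yeast_attr()
  res <- updown_importance(at, fx$runs$full$fm, "H3K4me3")
  expect_gt(mean(res$per_tf$downstream > res$per_tf$upstream), 0.8)
})

test_that("input-SHAP correlations detect monotone relations", {
  fm <- mk_tiny_fm("gex_level@gene", sprintf("g%03d", 1:200), "TFa")
  j <- match("gex_level@gene", colnames(fm$X))
  set.seed(33)
  fm$X[, j] <- rnorm(200)
  S <- matrix(0, 200, ncol(fm$X), dimnames = list(NULL, colnames(fm$X)))
  S[, j] <- exp(fm$X[, j])  # strictly increasing
  expect_equal(unname(input_attribution_correlation(mk_attr(S, fm), fm,
                                                    "gex_level@gene")), 1)
  S[, j] <- rnorm(200)      # independent
  expect_lt(abs(input_attribution_correlation(mk_attr(S, fm), fm,
                                              "gex_level@gene")), 0.2)
  fm$X[, j] <- 0            # degenerate input
  expect_true(is.na(input_attribution_correlation(mk_attr(S, fm), fm,
                                                  "gex_level@gene")))
})
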