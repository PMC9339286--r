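test_that("average precision matches hand-enumerated cases", {
  # perfect ranking at any prevalence
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # ranked 1,0,1,0: precision 1 at the 1st positive, 2/3 at the 2nd
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2)
  # all scores tied: single block, precision = prevalence at recall 1
  expect_equal(auprc(rep(0.5, 20), c(rep(1, 3), rep(0, 17))), 0.15)
  # tied block in the middle: block enters at one threshold
  # ranking: 1 | {1,0,0} | 0 -> tp at block ends: 1, 2; prec 1, 2/4
  expect_equal(auprc(c(0.9, 0.5, 0.5, 0.5, 0.1), c(1, 1, 0, 0, 0)),
               (1 * 1 + 1 * 2 / 4) / 2)
  expect_error(auprc(1:3, c(0, 0, 0)), "zero positive")
  expect_error(auprc(1:3, c(1, 1, 1)), "zero negative")
})

test_that("random-score AUPRC concentrates at prevalence", {
  set.seed(10)
  n <- 2000
  y <- c(rep(1, 100), rep(0, n - 100))  # prevalence 0.05
  reps <- replicate(200, auprc(runif(n), y))
  expect_lt(abs(mean(reps) - 0.05), 0.01)
})

test_that("label permutation preserves per-TF counts and is seeded", {
  de <- list(TFa = data.frame(gene_id = sprintf("g%02d", 1:20),
                              log2fc = c(rep(2, 5), rep(0, 15)),
                              padj = c(rep(0.01, 5), rep(0.9, 15))),
             TFb = data.frame(gene_id = sprintf("g%02d", 1:20),
                              log2fc = rep(0, 20), padj = rep(1, 20)))
  lb <- build_response_labels(de, sprintf("g%02d", 1:20))
  pm <- permute_labels(lb, seed = 3)
  expect_equal(sum(pm$tab$responsive[pm$tab$tf_id == "TFa"]), 5L)
  expect_identical(pm$tab, permute_labels(lb, seed = 3)$tab)
  # all-negative labels remain unchanged
  expect_equal(pm$tab$responsive[pm$tab$tf_id == "TFb"], rep(0L, 20))
})

test_that("permutation null means sit near the response fractions", {
  genes <- sprintf("g%04d", 1:300)
  sch <- bin_scheme("yeast")
  set.seed(12)
  gf <- matrix(rnorm(300 * 2), 300, 2,
               dimnames = list(genes, c("gex_level@gene", "gex_var@gene")))
  bf <- lapply(stats::setNames(1:3, c("TFa", "TFb", "TFc")), function(i) {
    matrix(rnorm(300), 300, 1,
           dimnames = list(genes, "tf_binding@prom_b01"))
  })
  fm <- assemble_feature_matrix(gf, bf, sch)
  de <- lapply(stats::setNames(c(15, 30, 45), c("TFa", "TFb", "TFc")),
               function(k) {
    data.frame(gene_id = genes,
               log2fc = c(rep(2, k), rep(0, 300 - k)),
               padj = c(rep(0.01, k), rep(0.9, 300 - k)))
  })
  lb <- build_response_labels(de, genes)
  a <- make_tf_folds(c("TFa", "TFb", "TFc"), 3, seed = 1)
  null <- permutation_null(fm, lb, a, n_perm = 5, seed = 2,
                           xgb_hyperparams(nrounds = 10, max_depth = 2))
  expect_equal(dim(null$auprc), c(3L, 5L))
  se <- null$sd / sqrt(null$n_perm)
  expect_true(all(abs(null$mean - lb$fractions[rownames(null$auprc)]) <
                    3 * pmax(se, 0.01)))
  expect_error(permutation_null(fm, lb, a, n_perm = 1), ">= 2")
})

test_that("LSD fits recover exact lines and quintile maxima", {
  f <- c(0.012, 0.02, 0.04, 0.07, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
  sd <- exp(-1 + 0.8 * log(f))
  names(sd) <- names(f) <- sprintf("TF%02d", seq_along(f))
  fit <- fit_lsd(sd, f, "ordinary")
  expect_equal(fit$slope, 0.8, tolerance = 1e-9)
  expect_equal(fit$intercept, -1, tolerance = 1e-9)

  # conservative: one dominating (collinear) outlier per quintile
  sd2 <- sd
  tops <- c("TF01", "TF03", "TF05", "TF07", "TF09")
  sd2[tops] <- exp(-0.5 + 0.6 * log(f[tops]))
  fit2 <- fit_lsd(sd2, f, "conservative")
  expect_equal(fit2$slope, 0.6, tolerance = 1e-9)
  expect_equal(fit2$intercept, -0.5, tolerance = 1e-9)
  expect_equal(nrow(fit2$points), 5L)

  expect_error(fit_lsd(sd, f, responder_floor = 0.9), "fewer than 2")
})

test_that("per-TF p-values follow the normal-tail construction", {
  f <- c(TFa = 0.05, TFb = 0.2)
  sd <- c(TFa = 0.01, TFb = 0.05)
  lsd <- fit_lsd(sd, f, "ordinary")
  sigma <- predict_lsd_sd(lsd, 0.05)
  expect_equal(tf_pvalue(0.05, 0.05, NULL, lsd, "TFa")$p, 0.5)
  expect_equal(tf_pvalue(0.05 + 1.959964 * sigma, 0.05, NULL, lsd,
                         "TFa")$p, 0.025, tolerance = 1e-4)
  # below the responder floor: empirical SD takes over
  null <- structure(list(sd = c(TFx = 0.004)), class = "null_model")
  res <- tf_pvalue(0.02, 0.005, null, lsd, "TFx", responder_floor = 0.01)
  expect_equal(res$sd_source, "empirical")
  expect_equal(res$z, (0.02 - 0.005) / 0.004)
  # p strictly decreases in the real AUPRC
  ps <- vapply(seq(0.05, 0.3, by = 0.05), function(a) {
    tf_pvalue(a, 0.05, NULL, lsd, "TFa")$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  bad <- structure(list(sd = c(TFx = 0)), class = "null_model")
  expect_error(tf_pvalue(0.02, 0.005, bad, lsd, "TFx"), "zero")
})

test_that("empirically centered null p-values are approximately uniform", {
  # The average-precision estimator's null mean sits ~0.5 SD above the
  # response fraction, so the analytic centering is shifted by design;
  # the diagnostic empirical-mean centering is the calibrated null.
  set.seed(21)
  n <- 2000
  one_batch <- function() {
    n_tf <- 40
    fr <- runif(n_tf, 0.015, 0.12)
    sds <- mus <- reals <- numeric(n_tf)
    for (i in seq_len(n_tf)) {
      k <- round(fr[i] * n)
      y <- c(rep(1, k), rep(0, n - k))
      scores <- runif(n)  # a model with no information
      perm <- replicate(40, auprc(scores, sample(y)))
      sds[i] <- sd(perm); mus[i] <- mean(perm)
      reals[i] <- auprc(scores, sample(y))
    }
    names(sds) <- names(fr) <- sprintf("TF%02d", seq_len(n_tf))
    lsd <- fit_lsd(sds, fr, "ordinary")
    vapply(seq_len(n_tf), function(i) {
      tf_pvalue(reals[i], fr[i], NULL, lsd, names(fr)[i],
                mu = mus[i])$p
    }, numeric(1))
  }
  ps <- c(one_batch(), one_batch(), one_batch(), one_batch(),
          one_batch())
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("efficacy report joins per-TF accuracy with perturbation size", {
  pr <- data.frame(tf_id = c("TFb", "TFa"), auprc = c(0.2, 0.1),
                   random_expectation = c(0.05, 0.05), ratio = c(4, 2))
  lb <- list(efficacy = c(TFa = 2.5, TFb = NA))
  class(lb) <- "response_labels"
  rep <- efficacy_report(pr, lb)
  expect_equal(rep$tf_id, c("TFa", "TFb"))
  expect_equal(rep$efficacy, c(2.5, NA))
  expect_equal(rep$ratio, rep$auprc / rep$random_expectation)
})
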