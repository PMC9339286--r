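mk_regions <- function(strand = "+", tss = 10000) {
  build_regions(data.frame(gene_id = "g1", chrom = "chr1", tss = tss,
                           strand = strand), NULL, bin_scheme("yeast"), 1e6)
}

test_that("peaks contribute their whole signal to the summit's bin", {
  rg <- mk_regions()
  pk <- data.frame(chrom = "chr1", start = 9800, end = 9900, signal = 5,
                   summit = 50)  # summit at 9850 = TSS-150
  v <- map_peaks_to_bins(pk, rg)
  hit <- rg$bins$bin[rg$bins$rel_start == -200]
  expect_equal(unname(v[hit]), 5)
  expect_equal(sum(v), 5)

  # two peaks in one bin add up
  pk2 <- rbind(pk, transform(pk, signal = 4))
  expect_equal(unname(map_peaks_to_bins(pk2, rg)[hit]), 9)

  # summit absent: anchored at the interval midpoint
  pk3 <- data.frame(chrom = "chr1", start = 9800, end = 9900, signal = 2,
                    summit = NA)
  expect_equal(unname(map_peaks_to_bins(pk3, rg)[hit]), 2)

  # outside the window: ignored
  off <- data.frame(chrom = "chr1", start = 8700, end = 8900, signal = 9,
                    summit = 100)
  expect_true(all(map_peaks_to_bins(off, rg) == 0))
})

test_that("mapping peaks is additive over concatenation", {
  rg <- mk_regions()
  set.seed(1)
  mk <- function(n) {
    s <- sample(8900:10400, n)
    data.frame(chrom = "chr1", start = s, end = s + 120, signal = runif(n),
               summit = sample(0:119, n, replace = TRUE))
  }
  a <- mk(20); b <- mk(15)
  expect_equal(map_peaks_to_bins(rbind(a, b), rg),
               map_peaks_to_bins(a, rg) + map_peaks_to_bins(b, rg))
})

test_that("coverage maps by base-pair-weighted sums and conserves mass", {
  rg <- mk_regions()
  # value 2.0 over exactly one bin: 2 * 100 = 200
  one <- data.frame(chrom = "chr1", start = 9000, end = 9100, value = 2)
  v <- map_coverage_to_bins(one, rg)
  expect_equal(unname(v[rg$bins$bin[1L]]), 200)
  expect_equal(sum(v), 200)

  # value 2.0 split 50/50 over two adjacent bins
  half <- data.frame(chrom = "chr1", start = 9050, end = 9150, value = 2)
  v2 <- map_coverage_to_bins(half, rg)
  expect_equal(unname(v2[rg$bins$bin[1:2]]), c(100, 100))

  # empty track
  expect_true(all(map_coverage_to_bins(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric()), rg) == 0))

  # mass conservation against a direct integral over the window
  set.seed(2)
  st <- seq(8800, 10700, by = 50)
  cov <- data.frame(chrom = "chr1", start = st, end = st + 50,
                    value = runif(length(st)))
  v3 <- map_coverage_to_bins(cov, rg)
  direct <- sum(pmax(0, pmin(cov$end, 10500) - pmax(cov$start, 9000)) *
                  cov$value)
  expect_equal(sum(v3), direct, tolerance = 1e-9)
})

test_that("dinucleotide frequencies follow the N-exclusion rule", {
  v <- dinucleotide_freqs("ACGT")
  expect_equal(unname(v[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  expect_equal(unname(dinucleotide_freqs("AAAA")["AA"]), 1)
  # windows AA, AN, NA: only AA valid
  v2 <- dinucleotide_freqs("AANA")
  expect_equal(unname(v2["AA"]), 1)
  expect_equal(sum(v2), 1)
  expect_warning(v3 <- dinucleotide_freqs("NNNN"), "dinucleotide")
  expect_true(all(v3 == 0))
  expect_warning(dinucleotide_freqs("A"), "shorter")
})

test_that("expression level is the median log2(x+1) (or median log)", {
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     s1 = c(3, 0, 1), s2 = c(3, 0, 3))
  lv_log <- compute_gex_level(expr, "log")
  expect_equal(unname(lv_log), c(3, 0, 2))
  lv_lin <- compute_gex_level(expr, "linear")
  expect_equal(unname(lv_lin["b"]), 0)          # log2(0+1) = 0
  expect_equal(unname(lv_lin["a"]), log2(4))
})

test_that("expression variation is the LOESS residual of CV on level", {
  # two samples per gene constructed so the empirical CV lies exactly on
  # a smooth curve of the level: the fit absorbs (nearly) everything
  n <- 120
  mu <- seq(2, 10, length.out = n)
  cv <- 0.35 - 0.03 * mu  # locally linear: inside the smoother's span
  m <- 2^mu
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     s1 = m * (1 + cv / sqrt(2)),
                     s2 = m * (1 - cv / sqrt(2)))
  res <- compute_gex_variation(expr, "linear")
  expect_lt(max(abs(res)), 0.01)  # < 4% of the smallest CV in the fixture

  # same level, doubled spread: the noisier gene scores higher
  probe <- data.frame(gene_id = c(expr$gene_id, "noisy", "quiet"),
                      s1 = c(expr$s1, 2^6 * (1 + 0.4), 2^6 * (1 + 0.2)),
                      s2 = c(expr$s2, 2^6 * (1 - 0.4), 2^6 * (1 - 0.2)))
  res2 <- compute_gex_variation(probe, "linear")
  expect_gt(res2[["noisy"]], res2[["quiet"]])

  expect_error(compute_gex_variation(
    data.frame(gene_id = "a", s1 = 1), "linear"), ">=2 samples")
})

test_that("planted CV noise is recovered and decorrelated from level", {
  set.seed(4)
  n <- 500
  mu <- runif(n, 2, 10)
  e <- rnorm(n, 0, 0.05)
  cv <- pmax(0.05 + 0.5 * exp(-mu / 3) + e, 0.01)
  sdlog <- sqrt(log(1 + cv^2))
  X <- sapply(1:60, function(s) 2^mu * exp(rnorm(n, 0, sdlog) - sdlog^2/2))
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n), X)
  varf <- compute_gex_variation(expr, "linear")
  lev <- compute_gex_level(expr, "linear")
  expect_gt(cor(varf, e), 0.9)
  expect_lt(abs(cor(lev, varf)), 0.1)
})

test_that("assembled matrices are rectangular, TF-blocked, deterministic", {
  sch <- bin_scheme("yeast")
  genes <- sprintf("g%02d", 1:10)
  gf <- matrix(rnorm(10 * 2), 10, 2,
               dimnames = list(genes, c("gex_level@gene", "gex_var@gene")))
  bins <- scheme_bins(sch)$bin
  bf <- lapply(setNames(1:3, c("TF1", "TF2", "TF3")), function(i) {
    m <- matrix(i, 10, 15, dimnames = list(genes,
                                           paste0("tf_binding@", bins)))
    m
  })
  fm <- assemble_feature_matrix(gf, bf, sch)
  expect_equal(nrow(fm$X), 30L)
  expect_equal(ncol(fm$X), 17L)
  # same gene, two TFs: identical except tf_binding columns
  r1 <- fm$X[fm$instances$tf_id == "TF1" & fm$instances$gene_id == "g01", ]
  r2 <- fm$X[fm$instances$tf_id == "TF2" & fm$instances$gene_id == "g01", ]
  gene_cols <- fm$feature_info$class != "tf_binding"
  expect_identical(r1[gene_cols], r2[gene_cols])
  expect_false(any(r1[!gene_cols] == r2[!gene_cols]))
  # determinism
  expect_identical(fm$X, assemble_feature_matrix(gf, bf, sch)$X)
  # missing gene in a binding track
  expect_error(assemble_feature_matrix(gf, lapply(bf, function(m)
    m[-1, , drop = FALSE]), sch), "missing track")
})

test_that("feature subsets drop the advertised column groups", {
  fx <- human_fx()
  fm <- fx$fm
  expect_equal(ncol(select_feature_subset(fm, "gex_only")$X), 2L)
  expect_identical(select_feature_subset(fm, "full")$X, fm$X)
  nb <- select_feature_subset(fm, "no_binding")
  expect_false(any(nb$feature_info$class == "tf_binding"))
  expect_equal(ncol(nb$X), ncol(fm$X) - 42L)
  po <- select_feature_subset(fm, "prom_only")
  expect_false(any(po$feature_info$kind %in% c("enh_bin", "enh_agg")))
  gb <- select_feature_subset(fm, "gene_body_2kb")
  expect_false(any(gb$feature_info$side %in% "upstream" &
                     gb$feature_info$kind == "promoter"))
  expect_true(all(c("gex_level", "gex_var") %in% gb$feature_info$class))
  expect_error(select_feature_subset(fm, "nope"))
})
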