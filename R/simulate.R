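#' @title Synthetic datasets with planted effect structure
#' @description Generates complete file-backed datasets (TSS table, per-TF
#'   narrowPeak binding, per-mark bedGraph coverage, accessibility
#'   coverage, promoter FASTA, preperturbation expression TSV, enhancer
#'   links, per-TF DE tables) whose responsiveness is driven by a
#'   configurable logistic mixture of binding and gene-centric effects:
#'   `logit(p) = b0 + b_bind*(binding) + b_gex*z(level) + b_var*z(variation)
#'   + b_hm*z(downstream HM)`. The `yeastlike` preset makes binding
#'   dominant with proximal summits (N(-150 bp, 80 bp) upstream of the
#'   TSS); the `humanlike` preset sets the binding effect to zero, makes
#'   the expression features dominant, and scatters decoy peaks uniformly
#'   within +/-50 kb so that binding is present but uninformative.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param preset `"yeastlike"` or `"humanlike"`.
#' @param n_genes number of genes (>= 50).
#' @param n_tfs number of perturbed TFs.
#' @param n_samples preperturbation expression replicates.
#' @param betas named list of effect weights `b0, b_bind, b_gex, b_var,
#'   b_hm` on the logit scale; defaults depend on the preset and put the
#'   median per-TF response fraction in the 2-7% range typical of
#'   TF-perturbation compendia.
#' @param bound_fraction fraction of genes bound per TF.
#' @param summit_mean,summit_sd summit position relative to the TSS (bp;
#'   yeastlike preset).
#' @param indirect_fraction fraction of unbound (TF, gene) pairs receiving
#'   a binding-sized responsiveness boost without any peak (indirect
#'   regulation).
#' @param hm_rho correlation of the histone-mark latent with expression.
#' @param cv_noise_sd SD of the level-independent CV noise (the planted
#'   expression-variation effect).
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(preset = c("yeastlike", "humanlike"),
                       n_genes = 1000L, n_tfs = 10L, n_samples = 10L,
                       betas = NULL, bound_fraction = 0.10,
                       summit_mean = -150, summit_sd = 80,
                       indirect_fraction = 0.02, hm_rho = 0.5,
                       cv_noise_sd = 0.04, seed = 1L) {
  preset <- match.arg(preset)
  if (n_genes < 50L) stop("n_genes must be >= 50")
  if (is.null(betas)) {
    betas <- if (preset == "yeastlike") {
      list(b0 = stats::qlogis(0.02), b_bind = 2.2, b_gex = 0.6,
           b_var = 0.45, b_hm = 0.25)
    } else {
      list(b0 = stats::qlogis(0.02), b_bind = 0, b_gex = 1.1,
           b_var = 0.9, b_hm = 0.1)
    }
  }
  if (betas$b_bind > 0 && bound_fraction <= 0) {
    stop("b_bind > 0 requires a positive bound_fraction")
  }
  mode <- if (preset == "yeastlike") "yeast" else "human"
  spacing <- if (mode == "yeast") 4000L else 10000L
  marks <- if (mode == "yeast") c("H3K4me3", "H3K79me1", "H3K4me1")
           else c("H3K4me3", "H3K4me1", "H3K27ac")
  structure(list(preset = preset, mode = mode,
                 n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples), betas = betas,
                 bound_fraction = bound_fraction,
                 summit_mean = summit_mean, summit_sd = summit_sd,
                 indirect_fraction = indirect_fraction, hm_rho = hm_rho,
                 cv_noise_sd = cv_noise_sd, marks = marks,
                 spacing = spacing, seed = as.integer(seed)),
            class = "sim_config")
}

.zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate a synthetic dataset
#'
#' Writes all input files under `dir` plus a `dataset.yaml` manifest, and
#' returns the planted truth. DE tables are generated directly from the
#' sampled labels: responsive genes get |log2FC| > 0.5 with padj < 0.05
#' (and a nonzero `shrunken_lfc`), nonresponsive genes fail both
#' thresholds (and have `shrunken_lfc` 0), so recomputing labels from the
#' emitted tables reproduces the truth exactly. Each TF's own gene is
#' forced responsive with a large fold-change (the perturbation efficacy).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a `sim_truth` object: `instances` (tf_id, gene_id,
#'   prob, responsive, bound, signal), `genes` (latent expression and HM
#'   parameters), `tf_genes`, `dir`, `cfg`.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  dir.create(file.path(dir, "de"), showWarnings = FALSE)
  withr::with_seed(cfg$seed, .simulate_impl(cfg, dir))
}

.simulate_impl <- function(cfg, dir) {
  G <- cfg$n_genes; Tn <- cfg$n_tfs
  genes <- sprintf("g%04d", seq_len(G))
  tfs <- sprintf("TF%02d", seq_len(Tn))
  tf_genes <- stats::setNames(genes[seq_len(Tn)], tfs)
  scheme <- bin_scheme(cfg$mode)
  up <- -scheme$promoter_bounds[1L]; down <- scheme$promoter_bounds[2L]
  chrom <- "chr1"
  tss <- cfg$spacing * (seq_len(G) + 60L) # margin for enhancer reach
  strand <- sample(c("+", "-"), G, replace = TRUE)
  chrom_length <- cfg$spacing * (G + 121L)

  # latent expression: log2 mean level, CV curve + level-free noise
  mu <- stats::rnorm(G, mean = 5, sd = 2)
  eps <- stats::rnorm(G, 0, cfg$cv_noise_sd)
  cv_true <- pmax(0.05 + 0.6 * exp(-mu / 3) + eps, 0.01)
  sdlog <- sqrt(log(1 + cv_true^2))
  expr <- matrix(0, G, cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    expr[, s] <- 2^mu * exp(stats::rnorm(G, 0, 1) * sdlog - sdlog^2 / 2)
  }
  expr_tab <- data.frame(gene_id = genes, expr, stringsAsFactors = FALSE)
  names(expr_tab) <- c("gene_id", sprintf("s%02d", seq_len(cfg$n_samples)))

  # histone-mark and accessibility latents (first mark carries the
  # effect). The informative latent shapes the gene-body (downstream)
  # coverage; upstream coverage follows a weakly related latent, so the
  # information truly sits downstream of the TSS.
  hm_lat <- sapply(seq_along(cfg$marks), function(i) {
    cfg$hm_rho * .zscore(mu) +
      sqrt(1 - cfg$hm_rho^2) * stats::rnorm(G)
  })
  hm_up_lat <- sapply(seq_along(cfg$marks), function(i) {
    0.3 * hm_lat[, i] + sqrt(1 - 0.09) * stats::rnorm(G)
  })
  atac_lat <- 0.6 * .zscore(mu) + 0.8 * stats::rnorm(G)

  # binding: per-TF bound sets, signals, summit positions (relative bp)
  bound <- matrix(stats::runif(G * Tn) < cfg$bound_fraction, G, Tn,
                  dimnames = list(genes, tfs))
  signal <- matrix(0, G, Tn, dimnames = list(genes, tfs))
  rel_summit <- matrix(NA_real_, G, Tn)
  for (t in seq_len(Tn)) {
    nb <- sum(bound[, t])
    signal[bound[, t], t] <- 3 + stats::rexp(nb, rate = 0.5)
    rel_summit[bound[, t], t] <- if (cfg$preset == "yeastlike") {
      pmin(pmax(stats::rnorm(nb, cfg$summit_mean, cfg$summit_sd),
                -up + 10), down - 10)
    } else {
      stats::runif(nb, -50000, 50000)
    }
  }

  # responsiveness
  z_lev <- .zscore(mu); z_var <- .zscore(eps); z_hm <- .zscore(hm_lat[, 1L])
  b <- cfg$betas
  inst <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    indirect <- !bound[, t] & stats::runif(G) < cfg$indirect_fraction
    bind_term <- ifelse(bound[, t], signal[, t] / 5,
                        ifelse(indirect, (3 + stats::rexp(G, 0.5)) / 5, 0))
    lp <- b$b0 + b$b_bind * bind_term + b$b_gex * z_lev +
      b$b_var * z_var + b$b_hm * z_hm
    prob <- stats::plogis(lp)
    resp <- as.integer(stats::runif(G) < prob)
    self <- match(tf_genes[t], genes)
    resp[self] <- 1L; prob[self] <- 1
    inst[[t]] <- data.frame(tf_id = tfs[t], gene_id = genes, prob = prob,
                            responsive = resp, bound = bound[, t],
                            signal = signal[, t], stringsAsFactors = FALSE)
  }
  instances <- if (Tn > 0L) do.call(rbind, inst) else {
    data.frame(tf_id = character(), gene_id = character(),
               prob = numeric(), responsive = integer(),
               bound = logical(), signal = numeric())
  }
  rownames(instances) <- NULL

  # ---- write files ----
  tss_tab <- data.frame(gene_id = genes, chrom = chrom, tss = tss,
                        strand = strand, stringsAsFactors = FALSE)
  write_tsv_table(tss_tab, file.path(dir, "tss.tsv"))
  write_tsv_table(expr_tab, file.path(dir, "expression.tsv"))

  # promoter sequences (5'->3' in gene orientation), gene-specific GC
  width <- up + down
  gc <- stats::rbeta(G, 8, 12)
  seqs <- vapply(seq_len(G), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
                 prob = c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2,
                          (1 - gc[i]) / 2)), collapse = "")
  }, "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, genes)),
    file.path(dir, "promoters.fa"))

  # enhancer links (human mode only)
  if (cfg$mode == "human") {
    links <- list()
    n_enh <- sample(0:5, G, replace = TRUE)
    for (i in seq_len(G)) {
      if (n_enh[i] == 0L) next
      d <- stats::runif(n_enh[i], 3000, 490000) *
        sample(c(-1, 1), n_enh[i], replace = TRUE)
      w <- round(stats::runif(n_enh[i], 500, 2000))
      st <- pmax(round(tss[i] + d - w / 2), 0)
      links[[length(links) + 1L]] <- data.frame(
        gene_id = genes[i], chrom = chrom, start = st,
        end = pmin(st + w, chrom_length), tier = "double elite",
        stringsAsFactors = FALSE)
    }
    enh_tab <- if (length(links)) do.call(rbind, links) else
      data.frame(gene_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), tier = character())
    write_tsv_table(enh_tab, file.path(dir, "enhancers.tsv"))
  }

  # coverage tracks: per-gene amplitude x up/downstream profile, written
  # over the promoter window in bin-width steps (non-overlapping because
  # genes are spaced farther apart than the window)
  prom_lo <- ifelse(strand == "+", tss - up, tss - down)
  nbin <- width %/% scheme$bin_width
  write_track <- function(down_amp, up_amp, path) {
    rows <- vector("list", G)
    for (i in seq_len(G)) {
      starts <- prom_lo[i] + scheme$bin_width * (seq_len(nbin) - 1L)
      rel_mid <- if (strand[i] == "+") {
        starts + scheme$bin_width / 2 - tss[i]
      } else {
        tss[i] - (starts + scheme$bin_width / 2)
      }
      amp <- ifelse(rel_mid >= 0, down_amp[i], up_amp[i])
      rows[[i]] <- data.frame(chrom = chrom, start = starts,
                              end = starts + scheme$bin_width,
                              value = round(amp, 4),
                              stringsAsFactors = FALSE)
    }
    cov <- do.call(rbind, rows)
    cov <- cov[order(cov$start), ]
    write_coverage(cov, path)
  }
  for (m in seq_along(cfg$marks)) {
    write_track(2^hm_lat[, m], 0.3 * 2^hm_up_lat[, m],
                file.path(dir, "coverage",
                          paste0(cfg$marks[m], ".bedGraph")))
  }
  write_track(2^atac_lat, 2^atac_lat,
              file.path(dir, "coverage", "atac.bedGraph"))

  # per-TF peaks
  for (t in seq_len(Tn)) {
    sel <- which(bound[, t])
    if (length(sel)) {
      gsum <- ifelse(strand[sel] == "+",
                     tss[sel] + rel_summit[sel, t],
                     tss[sel] - rel_summit[sel, t])
      gsum <- pmin(pmax(round(gsum), 100), chrom_length - 100)
      pk <- data.frame(chrom = chrom, start = gsum - 100, end = gsum + 100,
                       signal = round(signal[sel, t], 4), summit = 100,
                       stringsAsFactors = FALSE)
      pk <- pk[order(pk$start), ]
    } else {
      pk <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), signal = numeric(),
                       summit = numeric())
    }
    write_peaks(pk, file.path(dir, "peaks", paste0(tfs[t], ".narrowPeak")))
  }

  # per-TF DE tables consistent with the sampled labels
  for (t in seq_len(Tn)) {
    resp <- instances$responsive[instances$tf_id == tfs[t]]
    n1 <- sum(resp); n0 <- G - n1
    lfc <- numeric(G); padj <- numeric(G)
    lfc[resp == 1L] <- sample(c(-1, 1), n1, replace = TRUE) *
      (0.51 + stats::rexp(n1, rate = 1.2))
    padj[resp == 1L] <- stats::runif(n1, 1e-8, 0.049)
    lfc[resp == 0L] <- pmin(pmax(stats::rnorm(n0, 0, 0.15), -0.5), 0.5)
    padj[resp == 0L] <- stats::runif(n0, 0.051, 1)
    self <- match(tf_genes[t], genes)
    lfc[self] <- sign(lfc[self] + 1e-9) *
      max(abs(lfc[self]), 0.6 + abs(stats::rnorm(1, 2, 0.5)))
    de <- data.frame(gene_id = genes, log2fc = round(lfc, 4),
                     padj = signif(padj, 6),
                     shrunken_lfc = round(ifelse(resp == 1L, lfc, 0), 4),
                     stringsAsFactors = FALSE)
    write_tsv_table(de, file.path(dir, "de", paste0(tfs[t], ".tsv")))
  }

  manifest <- list(mode = cfg$mode, preset = cfg$preset,
                   expression_scale = "linear", de_rule = "de",
                   chrom_lengths = stats::setNames(list(chrom_length),
                                                   chrom),
                   tfs = tfs, marks = as.list(cfg$marks),
                   tf_genes = as.list(tf_genes), seed = cfg$seed)
  yaml::write_yaml(manifest, file.path(dir, "dataset.yaml"))

  truth <- structure(list(instances = instances,
                          genes = data.frame(gene_id = genes, mu = mu,
                                             cv_noise = eps,
                                             hm_latent = hm_lat[, 1L],
                                             stringsAsFactors = FALSE),
                          tf_genes = tf_genes, dir = dir, cfg = cfg),
                     class = "sim_truth")
  invisible(truth)
}

#' Summaries of the planted truth
#'
#' @param truth a `sim_truth`.
#' @return list: `fractions` (per-TF realized response fractions),
#'   `overlap` (pooled bound x responsive contingency table),
#'   `p_resp_bound`, `p_resp_unbound`.
#' @export
summarize_truth <- function(truth) {
  ins <- truth$instances
  if (nrow(ins) == 0L) {
    return(list(fractions = numeric(), overlap = table(logical()),
                p_resp_bound = NA_real_, p_resp_unbound = NA_real_))
  }
  tfs <- unique(ins$tf_id)
  fractions <- vapply(stats::setNames(tfs, tfs), function(tf) {
    mean(ins$responsive[ins$tf_id == tf])
  }, numeric(1))
  overlap <- table(bound = ins$bound, responsive = ins$responsive)
  list(fractions = fractions, overlap = overlap,
       p_resp_bound = mean(ins$responsive[ins$bound]),
       p_resp_unbound = mean(ins$responsive[!ins$bound]))
}
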