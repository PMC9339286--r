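#' @title Feature construction
#' @description Turns signal tracks, promoter sequences, and preperturbation
#'   expression tables into the rectangular per-(TF, gene) feature matrix.
#'   Positional tracks (TF binding, histone marks, accessibility,
#'   dinucleotides) yield one column per scheme bin; the two gene-expression
#'   features are positionless.
#' @name features
NULL

.DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))

#' Sum peak signals into the positional features of one gene
#'
#' Each peak contributes its full signal to the single feature whose
#' genomic span contains its anchor: the summit when present, otherwise the
#' interval midpoint. Peaks outside every span are ignored.
#'
#' @param peaks peak data.frame ([read_peaks()] layout).
#' @param regions a [build_regions()] result.
#' @return named numeric vector over `scheme_bins()` feature ids.
#' @export
map_peaks_to_bins <- function(peaks, regions) {
  stopifnot(inherits(regions, "gene_regions"))
  out <- stats::setNames(numeric(nrow(regions$bins)), regions$bins$bin)
  if (is.null(peaks) || nrow(peaks) == 0L) return(out)
  peaks <- peaks[peaks$chrom == regions$chrom, , drop = FALSE]
  if (nrow(peaks) == 0L) return(out)
  anchor <- ifelse(is.na(peaks$summit),
                   floor((peaks$start + peaks$end) / 2),
                   peaks$start + peaks$summit)
  sp <- regions$spans
  # promoter bins tile a contiguous window: direct arithmetic, with
  # clipping handled by the span test below; enhancer members checked
  # span-by-span. Promoter containment wins over enhancer membership.
  for (i in seq_along(anchor)) {
    hit <- which(sp$start <= anchor[i] & anchor[i] < sp$end)
    if (length(hit) == 0L) next
    prom_hit <- hit[startsWith(sp$bin[hit], "prom_")]
    b <- if (length(prom_hit)) sp$bin[prom_hit[1L]] else sp$bin[hit[1L]]
    out[b] <- out[b] + peaks$signal[i]
  }
  out
}

#' Base-pair-weighted coverage sums over the positional features of a gene
#'
#' Feature value = sum over coverage records of value x overlap (bp) with
#' the feature's genomic span(s).
#'
#' @param cov coverage data.frame ([read_coverage()] layout), non-overlapping.
#' @param regions a [build_regions()] result.
#' @return named numeric vector over `scheme_bins()` feature ids.
#' @export
map_coverage_to_bins <- function(cov, regions) {
  stopifnot(inherits(regions, "gene_regions"))
  out <- stats::setNames(numeric(nrow(regions$bins)), regions$bins$bin)
  if (is.null(cov) || nrow(cov) == 0L) return(out)
  cov <- cov[cov$chrom == regions$chrom, , drop = FALSE]
  if (nrow(cov) == 0L) return(out)
  ci <- coverage_index(cov)
  sp <- regions$spans
  vals <- coverage_integral(ci, sp$start, sp$end)
  for (i in seq_len(nrow(sp))) out[sp$bin[i]] <- out[sp$bin[i]] + vals[i]
  out
}

#' Prefix-sum index over a sorted non-overlapping coverage track
#' @param cov single-chromosome coverage data.frame sorted by start.
#' @return index list used by [coverage_integral()].
#' @keywords internal
coverage_index <- function(cov) {
  o <- order(cov$start)
  cov <- cov[o, , drop = FALSE]
  seglen <- cov$end - cov$start
  list(start = cov$start, end = cov$end, value = cov$value,
       cum = c(0, cumsum(cov$value * seglen)))
}

#' Integral of coverage value over [a, b)
#' @param ci index from [coverage_index()].
#' @param a,b vectors of interval bounds (0-based half-open).
#' @return numeric vector of base-pair-weighted sums.
#' @keywords internal
coverage_integral <- function(ci, a, b) {
  # F(x) = integral of the step function from -Inf to x
  F <- function(x) {
    i <- findInterval(x, ci$start)
    val <- ci$cum[i + 1L]
    inside <- i >= 1L & x < ci$end[pmax(i, 1L)]
    di <- pmax(i, 1L)
    val[inside] <- ci$cum[di[inside]] +
      ci$value[di[inside]] * (x[inside] - ci$start[di[inside]])
    val[i == 0L] <- 0
    val
  }
  F(b) - F(a)
}

#' Overlapping dinucleotide frequencies of a sequence
#'
#' Windows containing `N` are excluded from numerator and denominator. An
#' all-`N` or too-short sequence yields all-zero frequencies with a warning.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @return named numeric vector of the 16 dinucleotide frequencies.
#' @export
dinucleotide_freqs <- function(seq) {
  out <- stats::setNames(numeric(16L), .DINUCS)
  n <- nchar(seq)
  if (n < 2L) {
    warning("sequence shorter than 2 bp: all dinucleotide features 0")
    return(out)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  di <- paste0(chars[-n], chars[-1L])
  di <- di[!grepl("N", di, fixed = TRUE)]
  if (length(di) == 0L) {
    warning("no N-free dinucleotide window: all dinucleotide features 0")
    return(out)
  }
  tab <- table(factor(di, levels = .DINUCS))
  out[] <- as.numeric(tab) / length(di)
  out
}

#' Per-bin dinucleotide features of a promoter sequence
#'
#' The sequence is given 5'-to-3' in gene orientation, covering the full
#' promoter window; it is split at the scheme's bin boundaries and
#' frequencies are computed within each bin (windows do not span bins).
#'
#' @param seq promoter sequence.
#' @param scheme a [bin_scheme()].
#' @return numeric vector named `dinuc_XX@bin` over promoter bins.
#' @export
dinucleotide_bin_features <- function(seq, scheme) {
  bins <- scheme_bins(scheme)
  prom <- bins[bins$kind == "promoter", ]
  width <- scheme$promoter_bounds[2L] - scheme$promoter_bounds[1L]
  if (nchar(seq) != width) {
    stop(sprintf("promoter sequence length %d != window width %d",
                 nchar(seq), width))
  }
  res <- lapply(seq_len(nrow(prom)), function(i) {
    off <- prom$rel_start[i] - scheme$promoter_bounds[1L]
    sub <- substr(seq, off + 1L, off + scheme$bin_width)
    suppressWarnings(dinucleotide_freqs(sub))
  })
  mat <- do.call(cbind, res)
  v <- as.vector(mat)
  names(v) <- as.vector(outer(paste0("dinuc_", .DINUCS), prom$bin,
                              function(t, b) paste0(t, "@", b)))
  v
}

#' Preperturbation expression level per gene
#'
#' Median over samples of log2(x + 1) for linear-scale tables, or the
#' median of the stored values for log-scale tables.
#'
#' @param expr expression data.frame (`gene_id` + sample columns).
#' @param scale `"linear"` (TPM-like) or `"log"`.
#' @return named numeric vector per gene.
#' @export
compute_gex_level <- function(expr, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  x <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  if (scale == "linear") {
    if (any(x < 0)) stop("negative values in a linear-scale table")
    x <- log2(x + 1)
  }
  stats::setNames(apply(x, 1L, stats::median), expr$gene_id)
}

#' Expression-variation feature: LOESS residual of CV on level
#'
#' The coefficient of variation (sd/mean on the linear scale) depends
#' strongly on expression level; a LOESS fit of CV against the level
#' feature removes that dependence and the residuals are the variation
#' feature, approximately uncorrelated with level.
#'
#' @param expr expression data.frame (`gene_id` + >=2 sample columns).
#' @param scale `"linear"` or `"log"` (log2 values are unlogged for the CV).
#' @param span LOESS span (degree 1).
#' @return named numeric vector of residuals per gene.
#' @export
compute_gex_variation <- function(expr, scale = c("linear", "log"),
                                  span = 0.75) {
  scale <- match.arg(scale)
  x <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  if (ncol(x) < 2L) stop("expression variation needs >=2 samples")
  if (scale == "log") x <- 2^x
  mu <- rowMeans(x)
  cv <- apply(x, 1L, stats::sd) / mu
  zero <- !is.finite(cv)
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero mean expression: variation 0")
    cv[zero] <- NA_real_
  }
  level <- compute_gex_level(expr, scale = scale)
  ok <- !is.na(cv)
  d <- data.frame(level = level[ok], cv = cv[ok])
  fit <- stats::loess(cv ~ level, data = d, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  resid <- rep(0, nrow(x))
  resid[ok] <- d$cv - stats::predict(fit, newdata = d)
  stats::setNames(resid, expr$gene_id)
}

.feature_class <- function(track) {
  ifelse(track == "tf_binding", "tf_binding",
  ifelse(startsWith(track, "dinuc_"), "dinuc",
  ifelse(track %in% c("gex_level", "gex_var"), track, track)))
}

#' Assemble the rectangular (TF, gene) feature matrix
#'
#' Rows are (TF, gene) instances (TF-major order); gene-centric columns are
#' identical across TFs for a fixed gene, only the `tf_binding` columns vary
#' by TF.
#'
#' @param gene_features numeric matrix genes x gene-centric features; column
#'   names `track@bin` (or `gex_level@gene` etc.).
#' @param binding_features named list (one per TF) of numeric matrices
#'   genes x binding features (`tf_binding@bin` columns).
#' @param scheme the [bin_scheme()] used (recorded, and used for positional
#'   metadata).
#' @return object of class `feature_matrix`: `instances` (tf_id, gene_id),
#'   `X`, and `feature_info` (name, track, class, kind, side, bin_index,
#'   rel_start, rel_end).
#' @export
assemble_feature_matrix <- function(gene_features, binding_features,
                                    scheme) {
  genes <- rownames(gene_features)
  if (is.null(genes)) stop("gene_features needs gene ids as rownames")
  tfs <- names(binding_features)
  if (is.null(tfs) || any(!nzchar(tfs))) {
    stop("binding_features must be a named per-TF list")
  }
  for (tf in tfs) {
    miss <- setdiff(genes, rownames(binding_features[[tf]]))
    if (length(miss)) {
      stop("gene ", miss[1L], " missing track tf_binding for TF ", tf)
    }
  }
  bind_cols <- colnames(binding_features[[1L]])
  cols <- c(bind_cols, colnames(gene_features))
  X <- matrix(0, nrow = length(tfs) * length(genes), ncol = length(cols),
              dimnames = list(NULL, cols))
  inst <- data.frame(
    tf_id = rep(tfs, each = length(genes)),
    gene_id = rep(genes, times = length(tfs)),
    stringsAsFactors = FALSE)
  for (i in seq_along(tfs)) {
    rows <- seq_len(length(genes)) + (i - 1L) * length(genes)
    X[rows, bind_cols] <- binding_features[[tfs[i]]][genes, , drop = FALSE]
    X[rows, colnames(gene_features)] <- gene_features
  }
  info <- .feature_info(cols, scheme)
  structure(list(instances = inst, X = X, feature_info = info,
                 scheme = scheme),
            class = "feature_matrix")
}

.feature_info <- function(cols, scheme) {
  parts <- strsplit(cols, "@", fixed = TRUE)
  track <- vapply(parts, `[[`, "", 1L)
  bin <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "gene", "")
  bins <- scheme_bins(scheme)
  m <- match(bin, bins$bin)
  data.frame(name = cols, track = track, class = .feature_class(track),
             bin = bin,
             kind = ifelse(is.na(m), "gene", bins$kind[m]),
             side = ifelse(is.na(m), NA_character_, bins$side[m]),
             bin_index = ifelse(is.na(m), NA_integer_, bins$bin_index[m]),
             rel_start = ifelse(is.na(m), NA_integer_, bins$rel_start[m]),
             rel_end = ifelse(is.na(m), NA_integer_, bins$rel_end[m]),
             stringsAsFactors = FALSE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d instances (%d TFs x %d genes), %d features\n",
              nrow(x$X), length(unique(x$instances$tf_id)),
              length(unique(x$instances$gene_id)), ncol(x$X)))
  invisible(x)
}

#' Restrict a feature matrix to a named feature subset
#'
#' Subsets mirror the ablations used to compare feature families:
#' `full`, `no_binding`, `no_gex`, `no_hm`, `binding_only`, `gex_only`,
#' `prom_only` (drop enhancer columns), `gene_body_2kb` (drop enhancer
#' columns and promoter columns upstream of the TSS).
#'
#' @param fm a `feature_matrix`.
#' @param subset subset name.
#' @return a `feature_matrix` with the reduced column set.
#' @export
select_feature_subset <- function(fm, subset = c("full", "no_binding",
                                                 "no_gex", "no_hm",
                                                 "binding_only", "gex_only",
                                                 "prom_only",
                                                 "gene_body_2kb")) {
  subset <- match.arg(subset)
  info <- fm$feature_info
  is_hm <- grepl("^H[0-9]", info$track)
  keep <- switch(subset,
    full = rep(TRUE, nrow(info)),
    no_binding = info$class != "tf_binding",
    no_gex = !info$class %in% c("gex_level", "gex_var"),
    no_hm = !is_hm,
    binding_only = info$class == "tf_binding",
    gex_only = info$class %in% c("gex_level", "gex_var"),
    prom_only = !info$kind %in% c("enh_bin", "enh_agg"),
    gene_body_2kb = !(info$kind %in% c("enh_bin", "enh_agg") |
                      (info$kind == "promoter" & info$side == "upstream")))
  out <- fm
  out$X <- fm$X[, keep, drop = FALSE]
  out$feature_info <- info[keep, , drop = FALSE]
  out
}
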