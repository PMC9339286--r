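#' @title Dataset loading and feature-matrix construction
#' @description A dataset directory holds `dataset.yaml` plus the input
#'   files written by [simulate_dataset()] (or assembled by hand in the
#'   same layout): `tss.tsv`, `expression.tsv`, `promoters.fa`, optional
#'   `enhancers.tsv`, `peaks/<tf>.narrowPeak`, `coverage/<track>.bedGraph`,
#'   `de/<tf>.tsv`.
#' @name dataset
NULL

#' Load a dataset directory
#'
#' @param dir dataset directory containing `dataset.yaml`.
#' @return list with elements `manifest`, `tss`, `expression`,
#'   `sequences`, `enhancers` (NULL if absent), `peaks` (named per-TF
#'   list), `coverage` (named per-track list), `de_tables` (named per-TF
#'   list), `tf_genes`.
#' @export
load_dataset <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  tfs <- unlist(mf$tfs)
  enh_path <- file.path(dir, "enhancers.tsv")
  tracks <- c(unlist(mf$marks), "atac")
  list(
    manifest = mf,
    tss = read_tables(file.path(dir, "tss.tsv"), "tss"),
    expression = read_tables(file.path(dir, "expression.tsv"),
                             "expression"),
    sequences = read_sequences(file.path(dir, "promoters.fa")),
    enhancers = if (file.exists(enh_path)) {
      read_tables(enh_path, "enhancer_links")
    },
    peaks = stats::setNames(lapply(tfs, function(tf) {
      read_peaks(file.path(dir, "peaks", paste0(tf, ".narrowPeak")))
    }), tfs),
    coverage = stats::setNames(lapply(tracks, function(tr) {
      read_coverage(file.path(dir, "coverage", paste0(tr, ".bedGraph")))
    }), tracks),
    de_tables = stats::setNames(lapply(tfs, function(tf) {
      read_tables(file.path(dir, "de", paste0(tf, ".tsv")), "de")
    }), tfs),
    tf_genes = unlist(mf$tf_genes)
  )
}

#' Build per-gene regions for every gene of a dataset
#'
#' @param ds a [load_dataset()] result.
#' @param scheme a [bin_scheme()]; defaults to the dataset's mode.
#' @return named list of [build_regions()] results.
#' @export
dataset_regions <- function(ds, scheme = NULL) {
  if (is.null(scheme)) scheme <- bin_scheme(ds$manifest$mode)
  lens <- ds$manifest$chrom_lengths
  stats::setNames(lapply(seq_len(nrow(ds$tss)), function(i) {
    row <- ds$tss[i, ]
    links <- if (!is.null(ds$enhancers)) {
      ds$enhancers[ds$enhancers$gene_id == row$gene_id, , drop = FALSE]
    }
    build_regions(row, links, scheme, chrom_length = lens[[row$chrom]])
  }), ds$tss$gene_id)
}

# peak anchors (summit else midpoint), sorted, for fast window queries
.peak_anchors <- function(pk) {
  anchor <- ifelse(is.na(pk$summit), floor((pk$start + pk$end) / 2),
                   pk$start + pk$summit)
  o <- order(pk$chrom, anchor)
  list(chrom = pk$chrom[o], anchor = anchor[o], signal = pk$signal[o],
       start = pk$start[o], end = pk$end[o], summit = pk$summit[o])
}

#' Assemble the full feature matrix of a dataset
#'
#' Maps every peak track, coverage track, promoter sequence, and the two
#' expression features onto the scheme's bins for every gene, then binds
#' the per-TF binding features with the shared gene-centric features into
#' the rectangular instance matrix.
#'
#' @param ds a [load_dataset()] result.
#' @param scheme a [bin_scheme()]; defaults to the dataset's mode.
#' @param regions optional precomputed [dataset_regions()].
#' @param loess_span span for the expression-variation LOESS.
#' @return a `feature_matrix`.
#' @export
build_feature_matrix <- function(ds, scheme = NULL, regions = NULL,
                                 loess_span = 0.75) {
  if (is.null(scheme)) scheme <- bin_scheme(ds$manifest$mode)
  if (is.null(regions)) regions <- dataset_regions(ds, scheme)
  genes <- names(regions)
  bins <- scheme_bins(scheme)
  nbin <- nrow(bins)

  # gene-centric positional tracks (coverage)
  track_mats <- lapply(names(ds$coverage), function(tr) {
    cov <- ds$coverage[[tr]]
    idx <- lapply(split(seq_len(nrow(cov)), cov$chrom), function(i) {
      coverage_index(cov[i, , drop = FALSE])
    })
    m <- matrix(0, length(genes), nbin,
                dimnames = list(genes, paste0(tr, "@", bins$bin)))
    for (g in genes) {
      rg <- regions[[g]]
      ci <- idx[[rg$chrom]]
      if (is.null(ci)) next
      sp <- rg$spans
      vals <- coverage_integral(ci, sp$start, sp$end)
      agg <- tapply(vals, sp$bin, sum)
      m[g, paste0(tr, "@", names(agg))] <- as.numeric(agg)
    }
    m
  })

  # dinucleotide features per promoter bin
  dinuc <- t(vapply(genes, function(g) {
    dinucleotide_bin_features(ds$sequences[[g]], scheme)
  }, dinucleotide_bin_features(ds$sequences[[genes[1L]]], scheme)))

  # expression features
  scale <- ds$manifest$expression_scale
  expr <- ds$expression[match(genes, ds$expression$gene_id), , drop = FALSE]
  gex <- cbind(`gex_level@gene` = compute_gex_level(expr, scale),
               `gex_var@gene` = compute_gex_variation(expr, scale,
                                                      span = loess_span))
  rownames(gex) <- genes

  gene_features <- do.call(cbind, c(track_mats, list(dinuc, gex)))

  # per-TF binding features
  binding <- lapply(ds$peaks, function(pk) {
    m <- matrix(0, length(genes), nbin,
                dimnames = list(genes, paste0("tf_binding@", bins$bin)))
    if (nrow(pk) == 0L) return(m)
    pa <- .peak_anchors(pk)
    for (g in genes) {
      rg <- regions[[g]]
      on_chr <- pa$chrom == rg$chrom
      lo <- min(rg$spans$start); hi <- max(rg$spans$end)
      near <- on_chr & pa$anchor >= lo & pa$anchor < hi
      if (!any(near)) next
      sub <- data.frame(chrom = pa$chrom[near], start = pa$start[near],
                        end = pa$end[near], signal = pa$signal[near],
                        summit = pa$summit[near], stringsAsFactors = FALSE)
      m[g, ] <- map_peaks_to_bins(sub, rg)
    }
    m
  })

  assemble_feature_matrix(gene_features, binding, scheme)
}
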