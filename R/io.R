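#' @title Readers and writers for the genomic and tabular formats the
#'   pipeline consumes
#'
#' @description All genomic coordinates are stored 0-based half-open
#'   (BED-compatible): `start` is inclusive, `end` exclusive, and a TSS is a
#'   0-based point. Readers that accept a 1-based inclusive dialect shift
#'   `start` by -1 on input.
#'
#' @name io_formats
NULL

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

.num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("malformed %s at line %d: non-numeric '%s'",
                 what, lineno[which(is.na(v))[1L]], x[which(is.na(v))[1L]]))
  }
  v
}

#' Read TF binding peaks
#'
#' @param path path to a peak file.
#' @param dialect `"narrowPeak"` (BED6+4: qValue in column 9 is the binding
#'   signal, summit offset in column 10, `-1` meaning absent) or `"tsv"`
#'   (header with columns `chrom,start,end,signal` and optional `summit`).
#' @param one_based set `TRUE` for a 1-based inclusive input; starts are
#'   shifted by -1.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `signal`,
#'   `summit` (bp offset from `start`, `NA` when absent), in file order.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "tsv"),
                       one_based = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .require_columns(tab, c("chrom", "start", "end", "signal"), path)
    if (is.null(tab$summit)) tab$summit <- NA_real_
    pk <- data.frame(chrom = as.character(tab$chrom), start = tab$start,
                     end = tab$end, signal = tab$signal,
                     summit = tab$summit, stringsAsFactors = FALSE)
  } else {
    lines <- .read_lines_checked(path)
    if (length(lines) == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), signal = numeric(),
                        summit = numeric()))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 10L)) {
      stop(sprintf("malformed narrowPeak at line %d: %d fields (need 10)",
                   which(nf < 10L)[1L], nf[which(nf < 10L)[1L]]))
    }
    ln <- seq_along(lines)
    pk <- data.frame(
      chrom  = vapply(fields, `[[`, "", 1L),
      start  = .num_or_stop(vapply(fields, `[[`, "", 2L), "narrowPeak", ln),
      end    = .num_or_stop(vapply(fields, `[[`, "", 3L), "narrowPeak", ln),
      signal = .num_or_stop(vapply(fields, `[[`, "", 9L), "narrowPeak", ln),
      summit = .num_or_stop(vapply(fields, `[[`, "", 10L), "narrowPeak", ln),
      stringsAsFactors = FALSE)
    pk$summit[pk$summit < 0] <- NA_real_
  }
  if (one_based) pk$start <- pk$start - 1
  if (any(pk$start < 0)) stop("negative coordinates in ", path)
  if (any(pk$end <= pk$start)) stop("empty or inverted interval in ", path)
  if (any(pk$signal < 0)) stop("negative peak signal in ", path)
  bad <- !is.na(pk$summit) & (pk$summit < 0 | pk$summit >= pk$end - pk$start)
  if (any(bad)) stop("summit offset outside peak at line ", which(bad)[1L])
  pk
}

#' Read per-bp signal coverage (fold-change over control)
#'
#' @param path path to a 4-column bedGraph file.
#' @return data.frame `chrom`, `start`, `end`, `value`, sorted by
#'   (chrom, start). Overlapping intervals within the track are an error.
#' @export
read_coverage <- function(path, dialect = "bedGraph") {
  stopifnot(identical(dialect, "bedGraph"))
  lines <- .read_lines_checked(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("malformed bedGraph at line %d: %d fields (need 4)",
                 which(nf < 4L)[1L], nf[which(nf < 4L)[1L]]))
  }
  ln <- seq_along(lines)
  cov <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = .num_or_stop(vapply(fields, `[[`, "", 2L), "bedGraph", ln),
    end   = .num_or_stop(vapply(fields, `[[`, "", 3L), "bedGraph", ln),
    value = .num_or_stop(vapply(fields, `[[`, "", 4L), "bedGraph", ln),
    stringsAsFactors = FALSE)
  if (any(cov$start < 0)) stop("negative coordinates in ", path)
  if (any(cov$end <= cov$start)) stop("empty or inverted interval in ", path)
  if (any(!is.finite(cov$value))) stop("non-finite coverage value in ", path)
  cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]
  rownames(cov) <- NULL
  for (ch in unique(cov$chrom)) {
    sub <- cov[cov$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("overlapping coverage intervals on ", ch, " in ", path)
    }
  }
  cov
}

.require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  }
  invisible(tab)
}

#' Read a typed TSV table
#'
#' Header-carrying TSVs used by the pipeline. Unknown extra columns are
#' retained but ignored downstream.
#'
#' @param path file path.
#' @param kind one of `"tss"` (columns `gene_id,chrom,tss,strand`),
#'   `"enhancer_links"` (`gene_id,chrom,start,end,tier`), `"expression"`
#'   (`gene_id` plus one column per sample), `"de"` (`gene_id,log2fc` with
#'   optional `padj`, `shrunken_lfc`).
#' @return data.frame with validated columns.
#' @export
read_tables <- function(path, kind = c("tss", "enhancer_links",
                                       "expression", "de")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  switch(kind,
    tss = {
      .require_columns(tab, c("gene_id", "chrom", "tss", "strand"), path)
      if (anyDuplicated(tab$gene_id)) {
        stop("duplicate gene_id in TSS table: ",
             tab$gene_id[duplicated(tab$gene_id)][1L])
      }
      if (!all(tab$strand %in% c("+", "-"))) {
        stop("TSS strand must be '+' or '-' in ", path)
      }
      if (any(tab$tss < 0)) stop("negative TSS coordinate in ", path)
    },
    enhancer_links = {
      .require_columns(tab, c("gene_id", "chrom", "start", "end", "tier"),
                       path)
      if (any(tab$end <= tab$start)) stop("empty enhancer interval in ", path)
    },
    expression = {
      .require_columns(tab, "gene_id", path)
      if (ncol(tab) < 2L) stop("expression table needs >=1 sample column")
      if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in ", path)
    },
    de = {
      .require_columns(tab, c("gene_id", "log2fc"), path)
      if (!is.null(tab$padj) &&
          any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
        stop("padj outside [0,1] in ", path)
      }
    })
  tab
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file; record ids are region (gene) identifiers.
#' @return named character vector of uppercase sequences over {A,C,G,T,N}.
#' @export
read_sequences <- function(path) {
  # BStringSet keeps letters verbatim (DNAStringSet silently drops
  # non-IUPAC characters), so invalid input can be rejected
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("non-IUPAC (non-ACGTN) characters in sequence ",
         names(out)[bad][1L])
  }
  out
}

#' Write a table as TSV (round-trip safe for the typed readers)
#' @param tab data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write peaks as narrowPeak (BED6+4)
#' @param pk peak data.frame as returned by [read_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(pk, path) {
  summit <- ifelse(is.na(pk$summit), -1L, as.integer(pk$summit))
  lines <- sprintf("%s\t%d\t%d\tpeak%d\t0\t.\t0\t0\t%.6g\t%d",
                   pk$chrom, as.integer(pk$start), as.integer(pk$end),
                   seq_len(nrow(pk)), pk$signal, summit)
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#' @param cov coverage data.frame as returned by [read_coverage()].
#' @param path output path.
#' @export
write_coverage <- function(cov, path) {
  lines <- sprintf("%s\t%d\t%d\t%.6g", cov$chrom, as.integer(cov$start),
                   as.integer(cov$end), cov$value)
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration
#'
#' Houses the labeling thresholds (adjusted p < 0.05, |log2FC| > 0.5), the
#' per-TF significance threshold (p < 1e-3), the <1%-responders floor below
#' which the empirical permuted SD replaces the LSD-model SD, fold and
#' permutation counts, and the boosting hyperparameters.
#'
#' @param mode `"yeast"` or `"human"`.
#' @param quick use the light boosting profile (100 rounds, 5 permutations).
#' @return named list mirroring the on-disk YAML config.
#' @export
default_config <- function(mode = c("yeast", "human"), quick = FALSE) {
  mode <- match.arg(mode)
  list(
    mode = mode,
    fold_count = 10L,
    permutation_count = if (quick) 5L else 35L,
    seed = 1L,
    feature_subset = "full",
    enhancer_scheme = if (mode == "human") "aggregated" else "none",
    thresholds = list(padj_max = 0.05, lfc_min = 0.5,
                      significance_p = 1e-3, responder_floor = 0.01),
    hyperparams = xgb_hyperparams(nrounds = if (quick) 100L else 300L)
  )
}

#' Read a YAML run configuration, filling defaults
#' @param path YAML file; keys override [default_config()].
#' @return config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(mode = if (is.null(user$mode)) "yeast" else user$mode)
  modifyList(cfg, user)
}
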