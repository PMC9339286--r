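#' Cis-regulatory binning scheme
#'
#' Defines how the regulatory region of a gene is partitioned into
#' positional features. The yeast scheme spans (-1000, +500) bp around the
#' TSS in fifteen 100-bp bins. The human scheme is a 4-kb promoter centered
#' on the 5'-most TSS (forty 100-bp bins) plus enhancer features: either 32
#' growing bins per side (widths 1, 2, 3, ... kb, starting at the promoter
#' edge and truncated at the 500-kb reach) or two per-side aggregates.
#'
#' @param mode `"yeast"` or `"human"`.
#' @param enhancer_scheme `"binned"`, `"aggregated"` or `"none"` (forced to
#'   `"none"` for yeast).
#' @param promoter_bounds length-2 numeric, bp relative to the TSS
#'   (upstream negative); default (-1000, 500) for yeast, (-2000, 2000) for
#'   human.
#' @param bin_width promoter bin width in bp.
#' @param enhancer_bin_count growing bins per side.
#' @param enhancer_reach maximum distance (bp) from the promoter edge at
#'   which an enhancer still contributes.
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(mode = c("yeast", "human"),
                       enhancer_scheme = NULL,
                       promoter_bounds = NULL,
                       bin_width = 100L,
                       enhancer_bin_count = 32L,
                       enhancer_reach = 500000L) {
  mode <- match.arg(mode)
  if (is.null(promoter_bounds)) {
    promoter_bounds <- if (mode == "yeast") c(-1000L, 500L)
                       else c(-2000L, 2000L)
  }
  if (is.null(enhancer_scheme)) {
    enhancer_scheme <- if (mode == "yeast") "none" else "aggregated"
  }
  enhancer_scheme <- match.arg(enhancer_scheme,
                               c("binned", "aggregated", "none"))
  if (mode == "yeast") enhancer_scheme <- "none"
  width <- promoter_bounds[2L] - promoter_bounds[1L]
  if (width <= 0 || width %% bin_width != 0) {
    stop("promoter window must be a positive multiple of bin_width")
  }
  structure(list(mode = mode,
                 promoter_bounds = as.integer(promoter_bounds),
                 bin_width = as.integer(bin_width),
                 enhancer_scheme = enhancer_scheme,
                 enhancer_bin_count = as.integer(enhancer_bin_count),
                 enhancer_reach = as.integer(enhancer_reach)),
            class = "bin_scheme")
}

#' Positional feature ids of a scheme, in 5'-to-3' promoter order
#'
#' @param scheme a [bin_scheme()].
#' @return data.frame with one row per positional feature: `bin`, `kind`
#'   (`promoter`, `enh_bin`, `enh_agg`), `side` (`upstream`/`downstream`),
#'   `bin_index`, and for promoter bins the relative bounds `rel_start`,
#'   `rel_end` (half-open, bp from TSS).
#' @export
scheme_bins <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  a <- scheme$promoter_bounds[1L]; b <- scheme$promoter_bounds[2L]
  starts <- seq(a, b - scheme$bin_width, by = scheme$bin_width)
  prom <- data.frame(
    bin = sprintf("prom_b%02d", seq_along(starts)),
    kind = "promoter",
    side = ifelse(starts + scheme$bin_width <= 0, "upstream", "downstream"),
    bin_index = seq_along(starts),
    rel_start = starts,
    rel_end = starts + scheme$bin_width,
    stringsAsFactors = FALSE)
  enh <- NULL
  if (scheme$enhancer_scheme == "binned") {
    k <- seq_len(scheme$enhancer_bin_count)
    enh <- rbind(
      data.frame(bin = sprintf("enh_up_b%02d", k), kind = "enh_bin",
                 side = "upstream", bin_index = k,
                 rel_start = NA_integer_, rel_end = NA_integer_,
                 stringsAsFactors = FALSE),
      data.frame(bin = sprintf("enh_dn_b%02d", k), kind = "enh_bin",
                 side = "downstream", bin_index = k,
                 rel_start = NA_integer_, rel_end = NA_integer_,
                 stringsAsFactors = FALSE))
  } else if (scheme$enhancer_scheme == "aggregated") {
    enh <- data.frame(bin = c("enh_up_agg", "enh_dn_agg"), kind = "enh_agg",
                      side = c("upstream", "downstream"), bin_index = 1L,
                      rel_start = NA_integer_, rel_end = NA_integer_,
                      stringsAsFactors = FALSE)
  }
  rbind(prom, enh)
}

#' Number of positional features per signal track
#'
#' Yeast: 15. Human with aggregated enhancers: 40 + 2 = 42. Human with
#' binned enhancers: 40 + 32 + 32 = 104.
#'
#' @param scheme a [bin_scheme()].
#' @return integer count.
#' @export
count_features <- function(scheme) nrow(scheme_bins(scheme))

# Cumulative outer edges (bp from the promoter edge) of the growing
# enhancer bins, truncated at the reach.
.enhancer_bin_edges <- function(scheme) {
  widths <- 1000 * seq_len(scheme$enhancer_bin_count)
  edges <- pmin(cumsum(widths), scheme$enhancer_reach)
  edges
}

#' Build the cis-regulatory regions of one gene
#'
#' Maps the scheme's relative bins to genomic coordinates (strand-aware:
#' relative `[a,b)` maps to `[tss+a, tss+b)` on the plus strand and to
#' `[tss-b, tss-a)` on the minus strand), clips at chromosome bounds
#' (clipped bins keep their identity over a reduced span), and assigns each
#' enhancer link to exactly one enhancer feature by the position of its
#' interval midpoint relative to the promoter edge. Enhancers whose midpoint
#' is beyond the reach are dropped; midpoints inside the promoter window are
#' dropped too (the promoter bins already cover that territory).
#'
#' @param tss single-row data.frame or list with `gene_id`, `chrom`, `tss`
#'   (0-based bp), `strand`.
#' @param links enhancer-link data.frame (`gene_id,chrom,start,end,tier`)
#'   for this gene; may be `NULL`/empty.
#' @param scheme a [bin_scheme()].
#' @param chrom_length chromosome length in bp.
#' @return object of class `gene_regions`: the scheme bin table plus
#'   genomic `spans` (feature id, start, end; enhancer features carry one
#'   span per member link).
#' @export
build_regions <- function(tss, links = NULL, scheme, chrom_length) {
  stopifnot(inherits(scheme, "bin_scheme"))
  gene_id <- as.character(tss$gene_id)
  strand <- as.character(tss$strand)
  pos <- as.numeric(tss$tss)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (pos < 0 || pos >= chrom_length) {
    stop("TSS of ", gene_id, " is off-chromosome")
  }
  bins <- scheme_bins(scheme)
  prom <- bins[bins$kind == "promoter", ]
  if (strand == "+") {
    gstart <- pos + prom$rel_start
    gend <- pos + prom$rel_end
  } else {
    gstart <- pos - prom$rel_end
    gend <- pos - prom$rel_start
  }
  cl_start <- pmax(gstart, 0)
  cl_end <- pmin(gend, chrom_length)
  keep <- cl_end > cl_start
  spans <- data.frame(bin = prom$bin[keep], chrom = tss$chrom,
                      start = cl_start[keep], end = cl_end[keep],
                      stringsAsFactors = FALSE)
  prom_lo <- min(cl_start[keep]); prom_hi <- max(cl_end[keep])

  if (scheme$enhancer_scheme != "none" && !is.null(links) && nrow(links)) {
    if (any(links$chrom != tss$chrom)) {
      stop("enhancer on a different chromosome than the TSS of ", gene_id)
    }
    mid <- floor((links$start + links$end) / 2)
    # distance (bp, >=1) from the promoter edge; side in gene orientation
    left <- mid < prom_lo
    right <- mid >= prom_hi
    dist <- ifelse(left, prom_lo - mid, ifelse(right, mid - prom_hi + 1, 0))
    gen_side <- ifelse(left, "left", ifelse(right, "right", "inside"))
    side <- ifelse(gen_side == "inside", NA,
                   ifelse((gen_side == "left") == (strand == "+"),
                          "upstream", "downstream"))
    keep_e <- !is.na(side) & dist <= scheme$enhancer_reach
    if (any(keep_e)) {
      if (scheme$enhancer_scheme == "aggregated") {
        feat <- ifelse(side == "upstream", "enh_up_agg", "enh_dn_agg")
      } else {
        edges <- .enhancer_bin_edges(scheme)
        idx <- findInterval(dist - 1, c(0, edges)) # bin k: (edge_{k-1}, edge_k]
        idx <- pmin(idx, scheme$enhancer_bin_count)
        feat <- sprintf("enh_%s_b%02d",
                        ifelse(side == "upstream", "up", "dn"), idx)
      }
      spans <- rbind(spans, data.frame(
        bin = feat[keep_e], chrom = tss$chrom,
        start = pmax(links$start[keep_e], 0),
        end = pmin(links$end[keep_e], chrom_length),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(gene_id = gene_id, chrom = as.character(tss$chrom),
                 strand = strand, tss = pos, scheme = scheme,
                 bins = bins, spans = spans,
                 promoter_interval = c(prom_lo, prom_hi)),
            class = "gene_regions")
}

#' @export
print.gene_regions <- function(x, ...) {
  cat(sprintf("gene_regions %s %s:%d(%s), %d positional features, %d spans\n",
              x$gene_id, x$chrom, x$tss, x$strand, nrow(x$bins),
              nrow(x$spans)))
  invisible(x)
}
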