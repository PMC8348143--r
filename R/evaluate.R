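# Interval arithmetic is delegated to GenomicRanges; intervals are merged
# (reduced) on construction so overlapping called peaks never double-count.

# Internal: tibble (0-based half-open) -> reduced GRanges on a shared
# chromosome namespace.
as_reduced_granges <- function(x, chroms) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  GenomicRanges::reduce(gr)
}

# Internal: harmonize two interval tibbles into reduced GRanges.
interval_pair <- function(a, b) {
  check_interval_cols(a, "a"); check_interval_cols(b, "b")
  chroms <- union(unique(a$chrom), unique(b$chrom))
  list(a = as_reduced_granges(a, chroms), b = as_reduced_granges(b, chroms))
}

grange_bp <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

#' Nucleotide-level Jaccard index between two interval sets
#'
#' `|a intersect b| / |a union b|` in base pairs, pooled across
#' chromosomes; intervals are merged within each set first. Returns 0 when
#' the union is empty.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`; 0-based half-open).
#' @return A number in `[0, 1]`.
#' @export
peak_jaccard <- function(a, b) {
  gr <- interval_pair(a, b)
  inter <- grange_bp(GenomicRanges::intersect(gr$a, gr$b))
  uni <- grange_bp(GenomicRanges::union(gr$a, gr$b))
  if (uni == 0) 0 else inter / uni
}

#' Nucleotide-level true positive rate of called peaks
#'
#' `|called intersect truth| / |truth|` in base pairs.
#'
#' @param truth Ground-truth interval tibble (must be nonempty).
#' @param called Called peak tibble.
#' @return A number in `[0, 1]`.
#' @export
peak_tpr <- function(truth, called) {
  gr <- interval_pair(truth, called)
  real_bp <- grange_bp(gr$a)
  if (real_bp == 0) abort("TPR is undefined for an empty truth set")
  grange_bp(GenomicRanges::intersect(gr$a, gr$b)) / real_bp
}

#' Nucleotide-level false discovery rate of called peaks
#'
#' `|called minus truth| / |called|` in base pairs.
#'
#' @inheritParams peak_tpr
#' @param called Called peak tibble (must be nonempty).
#' @return A number in `[0, 1]`.
#' @export
peak_fdr <- function(truth, called) {
  gr <- interval_pair(truth, called)
  called_bp <- grange_bp(gr$b)
  if (called_bp == 0) abort("FDR is undefined for an empty called set")
  grange_bp(GenomicRanges::setdiff(gr$b, gr$a)) / called_bp
}

#' Compare called peaks with a truth set
#'
#' @inheritParams peak_tpr
#' @return A one-row tibble with `jaccard`, `tpr`, `fdr` and the total bp in
#'   each set.
#' @export
evaluate_peaks <- function(truth, called) {
  tibble(jaccard = peak_jaccard(truth, called),
         tpr = peak_tpr(truth, called),
         fdr = peak_fdr(truth, called),
         truth_bp = {gr <- interval_pair(truth, called); grange_bp(gr$a)},
         called_bp = grange_bp(interval_pair(truth, called)$b))
}

#' Genes overlapping any peak
#'
#' A gene is selected when it shares at least one nucleotide with any peak
#' (half-open coordinates: touching intervals do not overlap).
#'
#' @param genes Interval tibble with a `name` column.
#' @param peaks Peak interval tibble.
#' @return The subset of `genes` (unique names, input order) overlapping a
#'   peak.
#' @export
genes_overlapping <- function(genes, peaks) {
  check_interval_cols(genes, "genes"); check_interval_cols(peaks, "peaks")
  if (!"name" %in% names(genes)) abort("`genes` must carry a `name` column")
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(genes[0, ])
  chroms <- union(unique(genes$chrom), unique(peaks$chrom))
  g <- GenomicRanges::GRanges(factor(genes$chrom, levels = chroms),
                              IRanges::IRanges(genes$start + 1, genes$end))
  p <- as_reduced_granges(peaks, chroms)
  hits <- GenomicRanges::findOverlaps(g, p, minoverlap = 1)
  sel <- sort(unique(S4Vectors::queryHits(hits)))
  dplyr::distinct(genes[sel, , drop = FALSE], .data$name, .keep_all = TRUE)
}
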