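#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph file (chrom, start, end, value;
#'   0-based half-open, no header). Track/browser lines are skipped.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "cddd", comment = "#", progress = FALSE)
  x <- x[!grepl("^(track|browser)", x$chrom), , drop = FALSE]
  as_tibble(x)
}

#' Read a BED interval file
#'
#' Reads the first 3-6 columns of a BED file (0-based half-open). Used both
#' for read intervals and for peak / gene interval sets.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  ncol <- length(strsplit(first, "\t")[[1]])
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  types <- substr("cddcdc", 1, min(ncol, 6))
  x <- readr::read_tsv(path, col_names = cols, col_types = types,
                       comment = "#", progress = FALSE)
  as_tibble(x)
}

#' Read aligned reads from a BAM file
#'
#' Extracts the reference span of every mapped primary alignment. Spans are
#' computed from the CIGAR string (M/D/N/=/X operations advance the
#' reference), so spliced or deletion-containing alignments keep their true
#' footprint.
#'
#' @param path Path to an indexed BAM file.
#' @return A tibble of read intervals: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_bam_reads <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    abort("BAM input needs the Rsamtools and GenomicAlignments packages")
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar"), flag = flags)
  rec <- Rsamtools::scanBam(path, param = par)[[1]]
  keep <- !is.na(rec$pos)
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  tibble(chrom = as.character(rec$rname[keep]),
         start = rec$pos[keep] - 1,
         end = rec$pos[keep] - 1 + w)
}

# Internal: attribute accessors for coverage tibbles.
coverage_mode <- function(x) attr(x, "mode") %||% NA_character_
is_normalized <- function(x) isTRUE(attr(x, "normalized"))
`%||%` <- function(a, b) if (is.null(a)) b else a

set_coverage_attrs <- function(x, windows, mode, normalized) {
  attr(x, "width") <- windows_width(windows)
  attr(x, "chrom_sizes") <- attr(windows, "chrom_sizes")
  attr(x, "mode") <- mode
  attr(x, "normalized") <- normalized
  x
}

# Internal: names of the per-sample value columns of a coverage tibble.
value_cols <- function(coverage) {
  setdiff(names(coverage), c("chrom", "start", "end"))
}

# Internal: T x D matrix of coverage values.
coverage_values <- function(coverage) {
  as.matrix(coverage[value_cols(coverage)])
}

# Internal: per-base coverage Rle for one chromosome from read or track
# intervals (0-based half-open in, 1-based IRanges inside).
intervals_to_rle <- function(start, end, size, weight = NULL) {
  ir <- IRanges::IRanges(start = start + 1, end = end)
  if (is.null(weight)) {
    IRanges::coverage(ir, width = size)
  } else {
    IRanges::coverage(ir, width = size, weight = weight)
  }
}

#' Aggregate coverage into genome windows
#'
#' Computes per-window signal from aligned reads or a coverage track by
#' per-base pileup: the value of a window is the mean (Gaussian path) or the
#' sum (negative-binomial path) of the per-base read coverage over the
#' window's actual span. Windows with no overlapping signal get 0.
#'
#' @param windows Window tibble from [make_windows()].
#' @param source One of: a path to a BAM (`.bam`), bedGraph
#'   (`.bedgraph`/`.bdg`/`.bg`) or BED (`.bed`) file; a tibble of read
#'   intervals (`chrom`, `start`, `end`); or a tibble with a `value` column,
#'   treated as a per-base coverage track.
#' @param aggregator `"mean"` (default; use with Gaussian emissions) or
#'   `"sum"` (use with negative-binomial emissions; values are integer
#'   counts, fractional track input is rounded with a warning).
#' @param name Name of the resulting sample column.
#' @return The window tibble with an added value column; the aggregation
#'   mode is recorded in `attr(, "mode")`.
#' @export
bin_coverage <- function(windows, source, aggregator = c("mean", "sum"),
                         name = "coverage") {
  aggregator <- match.arg(aggregator)
  check_interval_cols(windows, "windows")
  src <- resolve_coverage_source(source)

  chroms <- unique(windows$chrom)
  sizes <- attr(windows, "chrom_sizes")
  if (is.null(sizes)) {
    sizes <- vapply(chroms, function(ch) max(windows$end[windows$chrom == ch]),
                    numeric(1))
  }

  extra <- setdiff(unique(src$data$chrom), chroms)
  if (length(extra) > 0) {
    warn(sprintf("skipping %d chromosome(s) absent from the window grid: %s",
                 length(extra), paste(head(extra, 5), collapse = ", ")))
  }
  missing <- setdiff(chroms, unique(src$data$chrom))
  if (length(missing) > 0) {
    warn(sprintf("no signal for chromosome(s) %s; coverage set to 0",
                 paste(head(missing, 5), collapse = ", ")))
  }

  vals <- numeric(nrow(windows))
  for (ch in chroms) {
    wsel <- windows$chrom == ch
    d <- src$data[src$data$chrom == ch, , drop = FALSE]
    size <- sizes[[ch]]
    if (nrow(d) == 0) next
    if (any(d$start < 0) || any(d$end > size)) {
      abort(sprintf("source coordinates on %s fall outside the declared chromosome size (%d)",
                    ch, as.integer(size)))
    }
    cov <- intervals_to_rle(d$start, d$end, size, weight = src$weights(d))
    v <- IRanges::Views(cov, start = windows$start[wsel] + 1,
                        end = windows$end[wsel])
    vals[wsel] <- if (aggregator == "mean") IRanges::viewMeans(v) else IRanges::viewSums(v)
  }

  if (aggregator == "sum") {
    rounded <- round(vals)
    if (max(abs(rounded - vals)) > 1e-9) {
      warn("fractional signal rounded to integer counts for sum aggregation")
    }
    vals <- rounded
  }

  out <- dplyr::select(as_tibble(windows), "chrom", "start", "end")
  out[[name]] <- vals
  set_coverage_attrs(out, windows, mode = aggregator, normalized = FALSE)
}

# Internal: normalise the polymorphic `source` argument of bin_coverage into
# a list(data = tibble, weights = function) pair.
resolve_coverage_source <- function(source) {
  if (is.character(source)) {
    stopifnot(length(source) == 1)
    if (!file.exists(source)) abort(sprintf("input file not found: %s", source))
    source <- switch(tolower(tools::file_ext(source)),
      bam = read_bam_reads(source),
      bedgraph = , bdg = , bg = read_bedgraph(source),
      bed = read_bed(source),
      abort(sprintf("unrecognised input format: %s (expected .bam, .bedgraph or .bed)",
                    source))
    )
  }
  check_interval_cols(source, "source")
  if (any(source$end <= source$start)) abort("source intervals must have end > start")
  if ("value" %in% names(source)) {
    list(data = source, weights = function(d) d$value)
  } else {
    list(data = source, weights = function(d) NULL)
  }
}

#' Normalize ChIP coverage against a control sample
#'
#' Replaces each ChIP window value with
#' `log2((chip + 1) / (control + 1))`; the pseudocount of 1 avoids division
#' by zero and log of zero. Only defined for mean-aggregated coverage
#' (the Gaussian path): the log-ratio is fractional, which the
#' negative-binomial model cannot emit.
#'
#' @param chip Coverage tibble with one or more ChIP sample columns.
#' @param control Coverage tibble with a single control/input column on the
#'   same window grid and aggregation mode.
#' @return A coverage tibble of log2 ratios with `attr(, "normalized")` set;
#'   values may be negative (depletion).
#' @export
normalize_with_control <- function(chip, control) {
  check_interval_cols(chip, "chip"); check_interval_cols(control, "control")
  if (nrow(chip) != nrow(control) ||
      !all(chip$chrom == control$chrom & chip$start == control$start &
           chip$end == control$end)) {
    abort("chip and control are on different window grids")
  }
  if (identical(coverage_mode(chip), "sum") || identical(coverage_mode(control), "sum")) {
    abort("control normalization is only defined for mean-aggregated coverage (Gaussian path)")
  }
  if (is_normalized(chip) || is_normalized(control)) {
    abort("inputs are already normalized")
  }
  cc <- value_cols(control)
  if (length(cc) != 1) abort("control must have exactly one sample column")
  ctrl <- control[[cc]]
  out <- chip
  for (vc in value_cols(chip)) {
    out[[vc]] <- log2((chip[[vc]] + 1) / (ctrl + 1))
  }
  attr(out, "mode") <- "mean"
  attr(out, "normalized") <- TRUE
  out
}

#' Combine coverage from multiple samples
#'
#' Two multi-sample strategies are supported: `"sum"` collapses all sample
#' columns into a single per-window total, while `"vector"` keeps one column
#' per sample so the HMM emits a vector per window.
#'
#' @param x A coverage tibble with several sample columns, or a list of
#'   single-sample coverage tibbles on the same window grid.
#' @param strategy `"sum"` or `"vector"`.
#' @return A coverage tibble; for `"sum"` the single column is named
#'   `coverage`.
#' @export
combine_samples <- function(x, strategy = c("sum", "vector")) {
  strategy <- match.arg(strategy)
  if (is.data.frame(x)) x <- list(x)
  stopifnot(length(x) >= 1)
  purrr::walk(x, check_interval_cols)
  grid <- x[[1]][c("chrom", "start", "end")]
  modes <- unique(purrr::map_chr(x, coverage_mode))
  norms <- unique(purrr::map_lgl(x, is_normalized))
  if (length(modes) > 1) abort("cannot combine samples with different aggregation modes")
  if (length(norms) > 1) abort("cannot mix normalized and unnormalized samples")
  for (xi in x[-1]) {
    if (!identical(xi[c("chrom", "start", "end")], grid)) {
      abort("samples are on different window grids")
    }
  }
  values <- purrr::imap(x, function(xi, i) {
    v <- xi[value_cols(xi)]
    names(v) <- make.unique(paste0(names(v), if (length(x) > 1) paste0(".", i) else ""))
    v
  })
  values <- bind_cols(values, .name_repair = "unique_quiet")
  out <- as_tibble(grid)
  if (strategy == "sum") {
    out$coverage <- rowSums(as.matrix(values))
  } else {
    out <- bind_cols(out, values)
  }
  set_coverage_attrs(out, x[[1]], mode = modes, normalized = norms)
}

#' Write a coverage column or track to bedGraph
#'
#' @param x A tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param column Value column to write (default: the single non-coordinate
#'   column, or `value` when present).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, column = NULL) {
  check_interval_cols(x)
  if (is.null(column)) {
    vc <- value_cols(x)
    column <- if ("value" %in% vc) "value" else vc[1]
  }
  out <- tibble(chrom = x$chrom, start = as.integer(x$start),
                end = as.integer(x$end), value = x[[column]])
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
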