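#' Read a chromosome-sizes table
#'
#' Reads a two-column, tab- or space-separated table of chromosome name and
#' length in bp (the format written by `samtools faidx` / UCSC `chrom.sizes`).
#'
#' @param path Path to the table. No header is expected.
#' @return A tibble with columns `chrom` (character) and `size` (integer bp).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_table(path, col_names = c("chrom", "size"),
                         col_types = readr::cols(chrom = "c", size = "d"))
  if (nrow(x) == 0) abort("empty chromosome-sizes table")
  if (any(!is.finite(x$size)) || any(x$size < 1)) {
    abort("chromosome sizes must be positive integers")
  }
  x
}

#' Tile chromosomes into fixed-width windows
#'
#' Divides every chromosome into adjacent, non-overlapping half-open windows
#' of `width` bp, left to right. The last window of a chromosome is truncated
#' at the chromosome end when the length is not a multiple of `width`, so the
#' per-chromosome window count is `ceiling(size / width)`.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `size` (bp), or a
#'   named numeric vector of chromosome lengths. Chromosome order is kept.
#' @param width Window width in bp (default 800, the package default
#'   resolution for broad marks).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   carrying the window width in `attr(, "width")`.
#' @examples
#' make_windows(c(chrA = 2000), width = 800)
#' @export
make_windows <- function(chrom_sizes, width = 800) {
  if (!is.data.frame(chrom_sizes)) {
    if (is.null(names(chrom_sizes)) || length(chrom_sizes) == 0) {
      abort("`chrom_sizes` must be a data frame (chrom, size) or a named vector")
    }
    chrom_sizes <- tibble(chrom = names(chrom_sizes),
                          size = as.numeric(chrom_sizes))
  }
  if (!all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("`chrom_sizes` needs columns `chrom` and `size`")
  }
  if (nrow(chrom_sizes) == 0) abort("empty chromosome table")
  if (length(width) != 1 || !is.finite(width) || width < 1) {
    abort("`width` must be a single positive number of bp")
  }
  width <- as.integer(width)
  if (any(chrom_sizes$size < 1)) abort("all chromosome lengths must be >= 1")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome names")

  out <- purrr::map2(chrom_sizes$chrom, chrom_sizes$size, function(ch, sz) {
    starts <- seq.int(0L, sz - 1L, by = width)
    tibble(chrom = ch, start = starts, end = pmin(starts + width, sz))
  }) %>% bind_rows()
  attr(out, "width") <- width
  attr(out, "chrom_sizes") <- stats::setNames(as.numeric(chrom_sizes$size),
                                              chrom_sizes$chrom)
  out
}

# Internal: window width of a windows/coverage tibble (attribute with
# fallback to the modal observed span, so dplyr round-trips keep working).
windows_width <- function(windows) {
  w <- attr(windows, "width")
  if (!is.null(w)) return(w)
  spans <- windows$end - windows$start
  as.integer(names(sort(table(spans), decreasing = TRUE))[1])
}
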