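#' Build a fixed-width truth peak set from template starts
#'
#' Every template start `s` becomes the interval `[s, s + peak_width)`. An
#' interval overlapping the previously retained one is dropped, as is any
#' interval running past the chromosome end; the retained template indices
#' are recorded so the same peaks can be removed across several widths
#' (see [make_fixed_width_peak_sets()]).
#'
#' @param template_starts Sorted (ascending) 0-based start positions.
#' @param peak_width Desired peak width in bp.
#' @param genome_size Chromosome length in bp.
#' @param chrom Chromosome name for the output intervals.
#' @return A tibble `chrom`, `start`, `end`, `template_index`; the dropped
#'   template indices are in `attr(, "dropped")`.
#' @export
make_fixed_width_peaks <- function(template_starts, peak_width, genome_size,
                                   chrom = "chrS") {
  stopifnot(peak_width >= 1, genome_size >= 1)
  if (length(template_starts) == 0) abort("no template starts given")
  if (is.unsorted(template_starts)) abort("`template_starts` must be sorted ascending")
  keep <- logical(length(template_starts))
  last_end <- -Inf
  for (i in seq_along(template_starts)) {
    s <- template_starts[i]
    e <- s + peak_width
    if (s >= last_end && e <= genome_size) {
      keep[i] <- TRUE
      last_end <- e
    }
  }
  if (!any(keep)) abort("all template peaks were dropped (overlap or out of range)")
  out <- tibble(chrom = chrom,
                start = template_starts[keep],
                end = template_starts[keep] + peak_width,
                template_index = which(keep))
  attr(out, "dropped") <- which(!keep)
  out
}

#' Fixed-width peak sets over several widths with a shared template
#'
#' Applies [make_fixed_width_peaks()] at every width and then removes, from
#' every set, any template peak that was dropped at *any* width, so all
#' sets contain the same peaks (by template index) and the same count.
#'
#' @inheritParams make_fixed_width_peaks
#' @param peak_widths Vector of widths in bp.
#' @return A tibble with columns `peak_width`, `chrom`, `start`, `end`,
#'   `template_index`; every width has the same number of rows.
#' @export
make_fixed_width_peak_sets <- function(template_starts, peak_widths, genome_size,
                                       chrom = "chrS") {
  sets <- purrr::map(peak_widths,
                     ~make_fixed_width_peaks(template_starts, .x, genome_size, chrom))
  dropped <- sort(unique(unlist(purrr::map(sets, attr, "dropped"))))
  purrr::map2(sets, peak_widths, function(s, w) {
    mutate(filter(s, !.data$template_index %in% dropped), peak_width = w)
  }) %>%
    bind_rows() %>%
    select("peak_width", "chrom", "start", "end", "template_index")
}

#' Number of reads needed to reach a target fold-coverage
#'
#' `round(coverage * span_bp / read_length)`: the read count whose total
#' sequenced bases average to `coverage` over `span_bp` base pairs.
#'
#' @param coverage Target mean fold-coverage (>= 0).
#' @param span_bp Total bp the reads are spread over (genome size for
#'   background, `peak_width * n_peaks` for peak reads).
#' @param read_length Read length in bp.
#' @return An integer read count.
#' @export
n_reads <- function(coverage, span_bp, read_length) {
  stopifnot(coverage >= 0, span_bp > 0, read_length > 0)
  round(coverage * span_bp / read_length)
}

#' Configuration for the ChIP-seq domain simulator
#'
#' Bundles and validates the generator parameters: a single synthetic
#' chromosome, fixed-width truth peaks at the template starts, uniform
#' background reads at mean coverage `noise_coverage` (x) and peak reads
#' adding mean coverage `peak_coverage` (y) on top, so the realized mean
#' coverage over peak regions is x + y.
#'
#' @param genome_size Chromosome length in bp.
#' @param peak_width Truth peak width in bp (>= `read_length`).
#' @param peak_coverage Mean fold-coverage contributed by peak reads (y).
#' @param noise_coverage Mean fold-coverage of the uniform background (x).
#' @param template_starts Optional sorted start positions; by default
#'   `n_peaks` starts evenly spaced along the chromosome.
#' @param n_peaks Number of evenly spaced peaks when `template_starts` is
#'   not given (default 20).
#' @param read_length Read length in bp (default 100).
#' @param seed Integer seed making the simulation reproducible.
#' @param chrom Chromosome name.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(genome_size, peak_width, peak_coverage,
                              noise_coverage, template_starts = NULL,
                              n_peaks = 20, read_length = 100, seed = 1,
                              chrom = "chrS") {
  stopifnot(genome_size >= 1, peak_width >= 1, n_peaks >= 1)
  if (peak_coverage < 0 || noise_coverage < 0) {
    abort("coverages must be non-negative")
  }
  if (peak_width < read_length) {
    abort("`peak_width` must be at least one read length")
  }
  if (is.null(template_starts)) {
    spacing <- genome_size / n_peaks
    if (spacing < peak_width) abort("peaks do not fit: reduce n_peaks or peak_width")
    template_starts <- round((seq_len(n_peaks) - 0.5) * spacing - peak_width / 2)
  }
  if (max(template_starts) + peak_width > genome_size) {
    abort("template peaks extend past the chromosome end")
  }
  structure(list(genome_size = genome_size, template_starts = template_starts,
                 peak_width = peak_width, peak_coverage = peak_coverage,
                 noise_coverage = noise_coverage, read_length = read_length,
                 seed = as.integer(seed), chrom = chrom),
            class = "simulation_config")
}

#' Simulate a ChIP-seq dataset with known truth peaks
#'
#' Background reads start uniformly on `[0, genome_size - read_length]`;
#' each peak read picks one retained truth peak uniformly and starts
#' uniformly inside it (clipped so the read stays inside the chromosome).
#' Read counts follow [n_reads()]: `x * genome_size / read_length`
#' background reads and `y * peak_width * n_peaks / read_length` peak
#' reads, so peak regions average coverage `x + y` over a background of
#' `x`. Reads are position-only (no sequence, no alignment step): the
#' per-base coverage the peak caller sees is what is emulated.
#'
#' @param config A [simulation_config()].
#' @return A list with `reads` (interval tibble), `truth` (truth peak
#'   tibble), `coverage` (run-length per-base coverage tibble, bedGraph
#'   layout), and `config`. Deterministic given `config$seed`.
#' @export
simulate_chipseq <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- make_fixed_width_peaks(config$template_starts, config$peak_width,
                                  config$genome_size, config$chrom)
  L <- config$read_length
  n_noise <- n_reads(config$noise_coverage, config$genome_size, L)
  n_peak <- n_reads(config$peak_coverage, config$peak_width * nrow(truth), L)

  reads <- withr::with_seed(config$seed, {
    noise_start <- floor(runif(n_noise, min = 0, max = config$genome_size - L + 1))
    which_peak <- if (n_peak > 0) sample.int(nrow(truth), n_peak, replace = TRUE) else integer(0)
    offset <- floor(runif(n_peak, min = 0, max = config$peak_width))
    peak_start <- pmin(truth$start[which_peak] + offset, config$genome_size - L)
    tibble(chrom = config$chrom,
           start = c(noise_start, peak_start),
           end = c(noise_start, peak_start) + L)
  })

  cov <- intervals_to_rle(reads$start, reads$end, config$genome_size)
  coverage <- tibble(chrom = config$chrom,
                     start = cumsum(c(0, S4Vectors::runLength(cov)))[seq_along(S4Vectors::runLength(cov))],
                     end = cumsum(S4Vectors::runLength(cov)),
                     value = as.numeric(S4Vectors::runValue(cov)))
  list(reads = reads, truth = select(truth, "chrom", "start", "end"),
       coverage = coverage, config = config)
}

#' The simulation parameter grid of the benchmark design
#'
#' Cartesian product of peak widths, peak coverages (y) and noise coverages
#' (x), width-major. The defaults are the published benchmark axes: 18 peak
#' widths from 50 bp to 50 kb and a 7 x 6 grid of enrichment (y in 2..25)
#' by noisiness (x in 0.25..5), i.e. 42 coverage variants per width.
#'
#' @param peak_widths,peak_coverages,noise_coverages Grid axes.
#' @return A tibble with one row per configuration: `peak_width`,
#'   `peak_coverage`, `noise_coverage`.
#' @export
make_grid <- function(peak_widths = c(50, 100, 200, 400, 600, 800, 1000, 1500,
                                      2000, 2500, 3000, 5000, 7500, 10000,
                                      20000, 30000, 40000, 50000),
                      peak_coverages = c(2, 3, 5, 10, 15, 20, 25),
                      noise_coverages = c(0.25, 0.5, 1, 2, 3, 5)) {
  if (length(peak_widths) == 0 || length(peak_coverages) == 0 ||
      length(noise_coverages) == 0) {
    abort("all grid axes must be nonempty")
  }
  tidyr::expand_grid(peak_width = peak_widths,
                     peak_coverage = peak_coverages,
                     noise_coverage = noise_coverages)
}
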