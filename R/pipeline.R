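#' Call peaks on a binned coverage tibble
#'
#' Mid-level entry point: initializes the three-state HMM on the coverage,
#' fits it by Baum-Welch, Viterbi-decodes the state path, labels states by
#' emission mean, merges adjacent peak windows and scores the peaks.
#'
#' @param coverage Coverage tibble from [bin_coverage()] /
#'   [normalize_with_control()] / [combine_samples()].
#' @inheritParams init_peak_hmm
#' @inheritParams fit_peak_hmm
#' @return The scored peak tibble; the fitted model, the decoded windows and
#'   the posterior matrix ride along as attributes `model`, `decoded` and
#'   `posteriors`.
#' @examples
#' sim <- simulate_chipseq(simulation_config(
#'   genome_size = 2e5, peak_width = 5000, peak_coverage = 10,
#'   noise_coverage = 1, n_peaks = 5, seed = 42))
#' windows <- make_windows(c(chrS = 2e5), width = 800)
#' coverage <- bin_coverage(windows, sim$reads)
#' peaks <- call_peaks(coverage)
#' evaluate_peaks(sim$truth, peaks)
#' @export
call_peaks <- function(coverage, distribution = c("gaussian", "nb"),
                       covariance_type = c("diagonal", "full", "spherical", "tied"),
                       means = NULL, tol = 1e-3, max_iter = 100) {
  distribution <- match.arg(distribution)
  covariance_type <- match.arg(covariance_type)
  model <- init_peak_hmm(coverage, distribution = distribution,
                         covariance_type = covariance_type, means = means)
  model <- fit_peak_hmm(model, coverage, tol = tol, max_iter = max_iter)
  decoded <- decode_viterbi(model, coverage)
  posteriors <- decode_posterior(model, coverage)
  peaks <- merge_peak_windows(decoded)
  peaks <- score_peaks(peaks, coverage, posteriors)
  attr(peaks, "model") <- model
  attr(peaks, "decoded") <- decoded
  attr(peaks, "posteriors") <- posteriors
  peaks
}

# Internal: accept a path, tibble or named vector as a chrom-sizes spec.
resolve_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1 && is.null(names(chrom_sizes))) {
    read_chrom_sizes(chrom_sizes)
  } else {
    chrom_sizes
  }
}

#' End-to-end peak calling from input files
#'
#' The full workflow: tile the genome into windows, aggregate coverage for
#' every ChIP sample (mean for Gaussian emissions, summed counts for
#' negative-binomial), optionally log2-normalize each sample against the
#' control, combine samples, fit the HMM, decode, merge and score peaks,
#' and (when `out_prefix` is given) write `<prefix>_peaks.bed`,
#' `<prefix>_peaks.tab` and a plain-text model dump `<prefix>_model.txt`.
#'
#' @param chip One or more ChIP inputs: file paths (BAM / bedGraph / BED) or
#'   read-interval tibbles (mixed in a list is fine).
#' @param chrom_sizes Chromosome sizes: a path to a two-column table, a data
#'   frame (`chrom`, `size`) or a named vector.
#' @param control Optional control/input sample (same forms as `chip`);
#'   only allowed with Gaussian emissions.
#' @param width Window width ("resolution") in bp, default 800.
#' @param combine Multi-sample strategy: `"sum"` (default) or `"vector"`.
#' @param score Score written to the BED file (see [write_peaks_bed()]).
#' @param seed Seed fixed before training for reproducible runs.
#' @param out_prefix Output path prefix; `NULL` skips file output.
#' @inheritParams call_peaks
#' @return The scored peak tibble (see [call_peaks()]).
#' @export
run_peak_calling <- function(chip, chrom_sizes, control = NULL, width = 800,
                             distribution = c("gaussian", "nb"),
                             covariance_type = c("diagonal", "full", "spherical", "tied"),
                             combine = c("sum", "vector"),
                             score = c("mean", "max", "posterior", "max_posterior"),
                             means = NULL, tol = 1e-3, max_iter = 100,
                             seed = 1, out_prefix = NULL) {
  distribution <- match.arg(distribution)
  covariance_type <- match.arg(covariance_type)
  combine <- match.arg(combine)
  score <- match.arg(score)
  if (!is.null(control) && distribution == "nb") {
    abort("a control sample can only be used with the Gaussian distribution")
  }
  windows <- make_windows(resolve_chrom_sizes(chrom_sizes), width = width)
  aggregator <- if (distribution == "gaussian") "mean" else "sum"

  if (is.data.frame(chip) || is.character(chip) && length(chip) == 1) chip <- list(chip)
  columns <- purrr::imap(chip, function(src, i) {
    bin_coverage(windows, src, aggregator = aggregator,
                 name = paste0("sample_", i))
  })
  if (!is.null(control)) {
    ctrl <- bin_coverage(windows, control, aggregator = "mean", name = "control")
    inform("normalizing each ChIP sample against the control before combining")
    columns <- purrr::map(columns, normalize_with_control, control = ctrl)
  }
  coverage <- combine_samples(columns, strategy = combine)

  set.seed(seed)
  peaks <- call_peaks(coverage, distribution = distribution,
                      covariance_type = covariance_type, means = means,
                      tol = tol, max_iter = max_iter)
  if (!is.null(out_prefix)) {
    write_peaks_bed(peaks, paste0(out_prefix, "_peaks.bed"), score = score)
    write_peaks_tab(peaks, paste0(out_prefix, "_peaks.tab"))
    write_peak_hmm(attr(peaks, "model"), paste0(out_prefix, "_model.txt"))
  }
  peaks
}
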