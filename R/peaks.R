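#' Merge adjacent peak-state windows into peaks
#'
#' Maximal runs of contiguous windows labelled `peak` become single
#' intervals. Runs never extend across chromosomes or across gaps in the
#' window grid.
#'
#' @param decoded Decoded window tibble from [decode_viterbi()] (columns
#'   `chrom`, `start`, `end`, `label`).
#' @return A tibble of unscored peaks: `chrom`, `start`, `end`, `n_windows`,
#'   sorted by (chrom, start).
#' @export
merge_peak_windows <- function(decoded) {
  check_interval_cols(decoded, "decoded")
  if (!"label" %in% names(decoded)) abort("`decoded` must have a `label` column")
  is_peak <- decoded$label == "peak"
  if (!any(is_peak)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer()))
  }
  new_run <- is_peak &
    (dplyr::lag(is_peak, default = FALSE) == FALSE |
     decoded$chrom != dplyr::lag(decoded$chrom, default = "") |
     decoded$start != dplyr::lag(decoded$end, default = -1))
  run_id <- cumsum(new_run)
  run_id[!is_peak] <- NA
  decoded %>%
    filter(is_peak) %>%
    mutate(run = run_id[is_peak]) %>%
    group_by(.data$run) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), n_windows = dplyr::n(), .groups = "drop") %>%
    arrange(.data$chrom, .data$start) %>%
    select("chrom", "start", "end", "n_windows")
}

#' Score peaks from window coverage and peak-state posteriors
#'
#' For each peak spanning windows `w_1..w_k`, four scores are computed:
#' the mean and the maximum of the window coverages, the product of the
#' per-window posterior probabilities of the `peak` state (the posterior
#' probability that all constituent windows are enriched; computed as
#' `exp(sum(log p))`, reported as 0 below 1e-300), and the maximum of those
#' posteriors. Multi-sample (vector-mode) coverage is reduced to its
#' per-window sum across samples before scoring.
#'
#' @param peaks Unscored peaks from [merge_peak_windows()].
#' @param coverage The coverage tibble used for calling.
#' @param posteriors Posterior tibble from [decode_posterior()] (needs the
#'   `p_peak` column) on the same window grid.
#' @return The peak tibble with `mean_coverage`, `max_coverage`,
#'   `posterior_product` and `max_posterior` columns.
#' @export
score_peaks <- function(peaks, coverage, posteriors) {
  check_interval_cols(peaks, "peaks")
  check_interval_cols(coverage, "coverage")
  if (!"p_peak" %in% names(posteriors)) abort("`posteriors` must have a `p_peak` column")
  if (nrow(coverage) != nrow(posteriors)) {
    abort("coverage and posteriors are on different window grids")
  }
  vals <- coverage_values(coverage)
  wcov <- if (ncol(vals) > 1) rowSums(vals) else as.vector(vals)
  pp <- posteriors$p_peak

  out <- peaks
  out$mean_coverage <- NA_real_
  out$max_coverage <- NA_real_
  out$posterior_product <- NA_real_
  out$max_posterior <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    sel <- coverage$chrom == peaks$chrom[i] &
      coverage$start >= peaks$start[i] & coverage$end <= peaks$end[i]
    if (!any(sel)) abort("peak does not align to the window grid")
    out$mean_coverage[i] <- mean(wcov[sel])
    out$max_coverage[i] <- max(wcov[sel])
    prod_log <- sum(log(pp[sel]))
    out$posterior_product[i] <- if (prod_log < log(1e-300)) 0 else exp(prod_log)
    out$max_posterior[i] <- max(pp[sel])
  }
  out
}

# Internal: map a --score choice to a score column.
score_column <- function(score) {
  switch(score,
         mean = "mean_coverage", max = "max_coverage",
         posterior = "posterior_product", max_posterior = "max_posterior",
         abort(sprintf("unknown score '%s'", score)))
}

#' Write peaks to a BED5 file
#'
#' Writes `chrom`, `start`, `end`, a generated name (`peak_N` in file
#' order) and one chosen score column (BED supports a single score field;
#' the default is the mean coverage).
#'
#' @param peaks Scored peak tibble from [score_peaks()] (an unscored tibble
#'   is written with score 0).
#' @param path Output path.
#' @param score Which score to put in column 5: `"mean"`, `"max"`,
#'   `"posterior"` or `"max_posterior"`.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path,
                            score = c("mean", "max", "posterior", "max_posterior")) {
  score <- match.arg(score)
  check_interval_cols(peaks, "peaks")
  col <- score_column(score)
  sc <- if (col %in% names(peaks)) peaks[[col]] else rep(0, nrow(peaks))
  out <- tibble(chrom = peaks$chrom, start = as.integer(peaks$start),
                end = as.integer(peaks$end),
                name = paste0("peak_", seq_len(nrow(peaks))), score = sc)
  out <- arrange(out, .data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write all four peak scores to a tab-separated table
#'
#' @param peaks Scored peak tibble.
#' @param path Output path; one header line, then one row per peak with
#'   `chrom`, `start`, `end`, `mean_coverage`, `max_coverage`,
#'   `posterior_product`, `max_posterior`.
#' @return `path`, invisibly.
#' @export
write_peaks_tab <- function(peaks, path) {
  check_interval_cols(peaks, "peaks")
  cols <- c("chrom", "start", "end", "mean_coverage", "max_coverage",
            "posterior_product", "max_posterior")
  out <- peaks
  for (cl in setdiff(cols, names(out))) out[[cl]] <- numeric(nrow(out))
  readr::write_tsv(out[cols], path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_peaks_tab
#' @export
read_peaks_tab <- function(path) {
  readr::read_tsv(path, col_types = "cdddddd", progress = FALSE)
}
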