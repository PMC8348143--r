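# hmmpeaks

Hidden-Markov-model peak calling for **broad, weakly enriched ChIP-seq
domains** — the regime of repressive histone marks such as H3K27me3, where
enrichment spans tens of kilobases at barely twice the background and
sharp-peak callers fragment or miss the signal. The package is for
epigenomics analysts who need domain-scale segmentations with per-window
confidence, and for method developers who want a fully simulatable,
metric-instrumented test bed for broad-mark calling.

## The model

The genome is tiled into adjacent windows of width *w* (default 800 bp).
Window *t* emits its aggregated read coverage *x<sub>t</sub>* from one of
three hidden states — *no signal*, *background*, *peak* — linked by a
first-order Markov chain (start distribution π, 3×3 transition matrix *A*).
Emissions are either Gaussian on mean window coverage (optionally
log2-normalised against a control: log2((ChIP+1)/(control+1))) or negative
binomial on summed integer counts, NB(r, p) with mean r(1−p)/p. Training is
Baum–Welch; because the NB M-step has no joint closed form, *r* and *p*
alternate across EM iterations: *p* by the closed-form weighted MLE

    p_j = Σ_t P_{j,t} r_j / Σ_t P_{j,t}(x_t + r_j)

and *r* by a derivative-guided step search on the weighted score

    dl/dr = Σ_t P_{j,t} [Ψ(x_t + r) − Ψ(r) + ln p_j]

(Ψ = digamma) that keeps its step while the sign holds, halves and reverses
it on a sign flip, and stops at |dl/dr| < 1e-5. The Viterbi path gives the
segmentation; maximal runs of peak-state windows merge into peaks, each
scored by mean/max coverage and the product/max of per-window peak-state
posteriors. Interval metrics (nucleotide-level Jaccard, TPR, FDR) and a
coverage-targeted read simulator with ground-truth BED output complete the
benchmark loop.

## Worked example

Twenty 20 kb domains at 2× enrichment (peak coverage 3 over background 3)
on a 2 Mb chromosome — the hard broad-mark regime:

```r
library(hmmpeaks)

cfg <- simulation_config(genome_size = 2e6, peak_width = 20000,
                         peak_coverage = 3, noise_coverage = 3,
                         n_peaks = 20, seed = 101)
sim <- simulate_chipseq(cfg)

windows  <- make_windows(c(chrS = 2e6), width = 800)
coverage <- bin_coverage(windows, sim$reads)
peaks    <- call_peaks(coverage)

tidy(attr(peaks, "model"))
#> # A tibble: 3 × 5
#>   state label      dimension  mean variance
#>   <int> <chr>          <int> <dbl>    <dbl>
#> 1     1 no_signal          1  2.72    0.224
#> 2     2 background         1  3.20    0.350
#> 3     3 peak               1  6.06    0.710

evaluate_peaks(sim$truth, peaks)
#> # A tibble: 1 × 5
#>   jaccard   tpr     fdr truth_bp called_bp
#>     <dbl> <dbl>   <dbl>    <dbl>     <dbl>
#> 1   0.994 0.998 0.00399   400000    400800
```

The fitted background state sits at mean 3.20 (the simulated noise floor),
the peak state at 6.06 (x + y = 3 + 3), and the caller recovers 99.8% of
truth nucleotides with 0.4% false discovery. `write_peaks_bed()` /
`write_peaks_tab()` export the calls; the same workflow runs from the shell
as

```sh
exec/hmmpeaks call --chip chip.bam --chrom-sizes sizes.txt --out run1
exec/hmmpeaks simulate --peak-coverage 3 --noise-coverage 3 --out sim
exec/hmmpeaks evaluate --truth sim_truth.bed --called run1_peaks.bed
```

See `vignettes/broad-domain-calling.Rmd` for the full account of the model,
its parameters and its limitations.

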