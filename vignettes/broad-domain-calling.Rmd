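---
title: "Calling broad, weakly enriched domains with a three-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling broad, weakly enriched domains with a three-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmpeaks)
library(dplyr)
```

## The problem

ChIP-seq against broadly deposited histone marks — H3K27me3 is the canonical
example — produces enrichment domains that stretch from kilobases to
megabases at enrichment ratios not far above the background. Threshold- and
hypothesis-testing peak callers built for sharp transcription-factor peaks
tend to fragment such domains or miss them outright. hmmpeaks models the
whole chromosome-wide coverage profile at once: segmentation emerges from a
hidden Markov model whose state persistence captures exactly the "long runs
of modest enrichment" structure that per-window significance tests throw
away.

## The model

The genome is tiled into adjacent fixed-width windows (800 bp by default;
the `--resolution` of the CLI). Window `t` emits a value `x_t` — the mean
per-base read coverage for Gaussian emissions, or the summed (integer)
coverage for negative-binomial emissions — and is assigned one of three
hidden states:

* **no signal** — zero or near-zero coverage (unmappable or empty regions),
* **background** — the genome-wide noise floor,
* **peak** — the enriched domains we want.

A first-order Markov chain with start distribution $\pi$ and $3\times 3$
transition matrix $A$ ties neighbouring windows together. Parameters are
estimated by Baum–Welch (EM); the reported segmentation is the Viterbi path,
and forward–backward posteriors $P_{j,t}$ provide per-window confidence.
Maximal runs of peak-state windows, merged across adjacency, are the called
peaks. Each chromosome is treated as an independent observation sequence.

### Emission models

With **Gaussian** emissions each state has a mean and a covariance whose
structure is selectable (`diagonal` default, `full`, `spherical`, `tied`).
This is the default path: it converges fast, accepts fractional values, and
is the only path on which control normalisation is allowed. With multiple
samples in vector mode the emission is a multivariate normal.

With **negative-binomial** emissions each state (and sample dimension) has
parameters $(r, p)$, mean $r(1-p)/p$, which accommodates the overdispersion
of read counts. Counts must be raw non-negative integers, which is why sum
aggregation is required and control-normalised input is refused. In vector
mode, dimensions are modelled as independent NB factors per state — a
pragmatic choice the data rarely justifies refining, and the only
"multidimensional NB" that admits a closed E-step.

### The negative-binomial M-step

The NB M-step has no closed form in both parameters, so `r` and `p` are
updated in turns: `r` on even EM iterations, `p` on odd ones (the chain
starts with `r`, so the moment-based initial `p` gets one round of data
before it moves). Given state posteriors $P_{j,t}$:

$$p_j = \frac{\sum_t P_{j,t}\, r_j}{\sum_t P_{j,t}(x_t + r_j)}$$

is the exact weighted maximum-likelihood update for fixed $r_j$. For $r_j$
the weighted score

$$\frac{dl}{dr} = \sum_t P_{j,t}\left[\Psi(x_t + r) - \Psi(r) + \ln p_j\right]$$

($\Psi$ the digamma function) drives a derivative-guided step search from
the previous estimate $r_0$: the step $\Delta$ is kept while the derivative
keeps its sign, halved and reversed when the sign flips, and the first step
is $+r_0$ (derivative positive) or $-r_0/2$ (negative). The search stops
when $|dl/dr| < 10^{-5}$. Two guards the bare loop needs in practice: a
positivity guard halves $\Delta$ until $r + \Delta > 0$, and an iteration
cap (100) returns the best $r$ seen with a warning. The stop rule is applied
to the *absolute* derivative — a signed reading would never terminate on
the descending side of the optimum.

### Initialisation and labelling

State means start at the 0, 0.5 and 0.99 quantiles of the data
(per dimension, linear-interpolation quantiles), so states begin ordered as
no-signal / background / peak; Gaussian covariances start at the sample
covariance in the requested structure, NB parameters by moment matching
$p = m/v$, $r = m^2/(v-m)$ against the per-dimension sample variance. When a
quantile target is 0 or the data are under-dispersed ($v \le m$) the moments
are floored ($m \ge 0.01$, $v \ge 1.001\,m$) so $p \in (0,1)$ and $r > 0$;
the flooring is messaged. $\pi$ and $A$ start uniform at $1/3$ — a
deliberately agnostic choice that biases no segment length. After training,
states are re-labelled by emission mean (summed over dimensions), lowest to
highest; EM is free to permute states, so labels must follow the fit, not
the initialisation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width` | 800 bp | window/resolution; 300–1000 bp works well for broad marks, 1000 is plenty for long domains |
| `distribution` | gaussian | emission family; `nb` for raw counts |
| `covariance_type` | diagonal | Gaussian covariance structure |
| `combine` | sum | multi-sample strategy (`sum` or `vector`) |
| `tol` | 1e-3 | EM stop: absolute change in total log-likelihood |
| `max_iter` | 100 | EM iteration cap |
| `score` | mean | which score the BED file carries |

EM tolerance and iteration cap are exposed because neither has a canonical
value; 1e-3 on the log-likelihood of a whole chromosome is far below any
difference that moves a window across states.

## Control normalisation and multiple samples

With an input/control sample, every window value becomes
$\log_2\!\frac{\text{ChIP}+1}{\text{control}+1}$ (the pseudocount avoids
division by zero and $\log 0$). The ratio is fractional, so this path is
Gaussian-only. With several ChIP samples and a single control, each ChIP
column is normalised against the control *before* the samples are combined
— normalisation is per-sample by nature, and doing it first keeps `sum` and
`vector` modes consistent; the pipeline logs the choice.

## Peak scores

Each merged peak over windows $w_1..w_k$ gets four scores: mean window
coverage, maximum window coverage, the product of the per-window peak-state
posteriors (the posterior probability that *all* constituent windows are
enriched — computed as the exponential of summed logs, reported as 0 below
1e-300, since a 1 Mb domain multiplies a thousand probabilities), and the
maximum posterior. All four go to `<prefix>_peaks.tab`; BED holds one score
column, mean coverage by default (`--score` switches it).

## The simulator

`simulate_chipseq()` emulates the benchmark design used to measure the
caller: fixed-width truth peaks placed at template starts (overlapping or
out-of-range templates are dropped, and `make_fixed_width_peak_sets()`
removes the same templates from every width set so all sets keep one peak
count), background reads uniform over the chromosome at mean coverage $x$,
and peak reads at mean extra coverage $y$ — read counts are
$x\cdot\text{genome}/L$ and $y\cdot\text{width}\cdot\text{npeaks}/L$ for
read length $L$, so peak regions average $x+y$. `make_grid()` reproduces
the benchmark axes: 18 peak widths (50 bp – 50 kb) times 7 enrichment
levels (2–25) times 6 noise levels (0.25–5), i.e. 42 coverage variants per
width.

Reads are position-only: no sequence is generated, no aligner is run.
Everything the caller observes — per-base coverage and its window
aggregates — is preserved; what is *not* emulated is mappability structure,
GC bias, duplicate towers and the read-loss of alignment, so passing tests
demonstrate correct recovery of the model's own signal class, not
robustness to every artefact of real libraries. Peak-read starts are
uniform within their peak, so a read can overhang the peak end by up to
$L-1$ bp; at domain scale ($L/W \le 2\%$) this is negligible against the
$x+y$ identity's 10% check. Simulation is bit-reproducible given the
config seed.

## A worked example

The hard regime for broad marks: 20 kb domains at 2× enrichment
(peak coverage 3 over background 3) on a 2 Mb chromosome.

```{r example}
cfg <- simulation_config(genome_size = 2e6, peak_width = 20000,
                         peak_coverage = 3, noise_coverage = 3,
                         n_peaks = 20, seed = 101)
sim <- simulate_chipseq(cfg)

windows <- make_windows(c(chrS = 2e6), width = 800)
coverage <- bin_coverage(windows, sim$reads)
peaks <- call_peaks(coverage)

glance(attr(peaks, "model"))
tidy(attr(peaks, "model"))
evaluate_peaks(sim$truth, peaks)
```

The background state settles near mean 3 and the peak state near 6
(that is, $x + y$), and nucleotide-level sensitivity is well above 0.8
despite the 2× enrichment. The same workflow is scripted as
`hmmpeaks call / simulate / evaluate` (see `exec/hmmpeaks`).

```{r plot, fig.width=7, fig.height=3}
plot_peak_calls(coverage, peaks, truth = sim$truth)
```

## Numerical choices and degenerate inputs

* Forward–backward runs with per-step scaling on per-row-max-shifted
  emission likelihoods; Viterbi runs in log space. Both are exact (the
  tests compare them with exhaustive path enumeration) and finite for any
  finite data.
* Gaussian variances are floored at 1e-6, and full/tied covariances are
  ridge-jittered until Cholesky succeeds, preventing state collapse onto a
  single value.
* A state with numerically zero posterior mass keeps its previous
  parameters for that iteration rather than producing 0/0.
* Viterbi ties break to the lowest state index; tied emission means at
  labelling time keep state-index order (messaged). Both are deterministic.
* Constant coverage in every sample is rejected at initialisation with
  guidance, as no 3-state fit is identifiable.
* Truncated terminal windows are kept and aggregated over their actual
  span; dropping them would lose terminal domains.
* Reads are piled up over their full aligned span; there is no fragment
  extension, shifting, strand handling or duplicate removal.
* Interval metrics (Jaccard, TPR, FDR) are computed genome-wide in
  nucleotides after merging each interval set, so overlapping called peaks
  never double-count.

## Problem sizes in the test suite

The suite validates decoding against exhaustive enumeration at $T \le 8$
(where $3^T$ paths are enumerable), parameter recovery at $T = 5000$
windows, and end-to-end calling on 2 Mb single-chromosome simulations —
sizes at which every property is measurable in seconds while leaving the
asymptotic behaviour (per-window work is $O(K^2)$, memory $O(TK)$)
unchanged for genome-scale runs.

## Known limitations

* Exactly three states; marks with graded enrichment tiers would need more.
* No duration modelling: state dwell times are geometric, so very short
  true domains compete badly with the persistence the long domains induce.
* No mappability or GC correction; a control sample is the only bias
  handle, and only on the Gaussian path.
* Single-end, position-level reads; paired-end inference is out of scope.
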