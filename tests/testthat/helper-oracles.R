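# Independent oracles used across the suite. None of these share code with
# the package internals they check.

# Wrap a numeric vector/matrix into a coverage tibble on a toy window grid.
cov_tbl <- function(values, chrom = "chrA", width = 100, mode = "mean",
                    normalized = FALSE) {
  values <- as.matrix(values)
  T_ <- nrow(values)
  out <- tibble::tibble(chrom = chrom,
                        start = (seq_len(T_) - 1) * width,
                        end = seq_len(T_) * width)
  for (d in seq_len(ncol(values))) out[[paste0("s", d)]] <- values[, d]
  attr(out, "mode") <- mode
  attr(out, "normalized") <- normalized
  attr(out, "width") <- width
  out
}

# Build a peak_hmm by hand (bypassing init_peak_hmm) for decoding tests.
make_gauss_model <- function(start_probs, transitions, means, vars) {
  means <- as.matrix(means)
  structure(list(
    distribution = "gaussian", n_dim = ncol(means),
    start_probs = start_probs, transitions = transitions,
    emissions = list(means = means,
                     cov = lapply(seq_len(nrow(means)), function(j)
                       diag(vars[j], ncol(means))),
                     covariance_type = "diagonal"),
    loglik_trace = numeric(0), n_iter = 0L, converged = NA
  ), class = "peak_hmm")
}

# Per-window Gaussian emission log densities (diagonal), independent of the
# package's emission code.
oracle_logB <- function(model, x) {
  x <- as.matrix(x)
  out <- sapply(1:3, function(j) {
    m <- sapply(seq_len(ncol(x)), function(d)
      dnorm(x[, d], model$emissions$means[j, d],
            sqrt(model$emissions$cov[[j]][d, d]), log = TRUE))
    rowSums(matrix(m, nrow = nrow(x)))
  })
  matrix(out, nrow = nrow(x))
}

# Exhaustive path enumeration: joint log-probability of all 3^T paths.
enum_path_logprobs <- function(start_probs, transitions, logB) {
  T_ <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  lp <- log(start_probs)[paths[, 1]]
  for (t in seq_len(T_)) lp <- lp + logB[cbind(t, paths[, t])]
  lgA <- log(transitions)
  if (T_ > 1) {
    for (t in 2:T_) lp <- lp + lgA[cbind(paths[, t - 1], paths[, t])]
  }
  list(paths = paths, logprob = lp)
}

enum_viterbi <- function(start_probs, transitions, logB) {
  e <- enum_path_logprobs(start_probs, transitions, logB)
  e$paths[which.max(e$logprob), ]
}

enum_posteriors <- function(start_probs, transitions, logB) {
  e <- enum_path_logprobs(start_probs, transitions, logB)
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  tot <- lse(e$logprob)
  t(sapply(seq_len(nrow(logB)), function(t)
    sapply(1:3, function(j) exp(lse(e$logprob[e$paths[, t] == j]) - tot))))
}

# Simulate observations from a known Gaussian HMM.
sim_gauss_hmm <- function(start_probs, transitions, means, sds, T_, seed) {
  withr::with_seed(seed, {
    s <- integer(T_)
    s[1] <- sample(1:3, 1, prob = start_probs)
    for (t in 2:T_) s[t] <- sample(1:3, 1, prob = transitions[s[t - 1], ])
    list(states = s, x = rnorm(T_, means[s], sds[s]))
  })
}

# Simulate observations from a known NB HMM (r, p per state).
sim_nb_hmm <- function(start_probs, transitions, r, p, T_, seed) {
  withr::with_seed(seed, {
    s <- integer(T_)
    s[1] <- sample(1:3, 1, prob = start_probs)
    for (t in 2:T_) s[t] <- sample(1:3, 1, prob = transitions[s[t - 1], ])
    list(states = s, x = rnbinom(T_, size = r[s], prob = p[s]))
  })
}

# Per-nucleotide bit-vector interval metrics on small toy chromosomes.
bitvec <- function(x, sizes) {
  out <- lapply(names(sizes), function(ch) {
    v <- logical(sizes[[ch]])
    d <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) v[(d$start[i] + 1):d$end[i]] <- TRUE
    }
    v
  })
  unlist(out)
}

oracle_metrics <- function(truth, called, sizes) {
  a <- bitvec(truth, sizes); b <- bitvec(called, sizes)
  list(jaccard = if (sum(a | b) == 0) 0 else sum(a & b) / sum(a | b),
       tpr = sum(a & b) / sum(a),
       fdr = sum(b & !a) / sum(b))
}

# Brute-force per-base pileup of read intervals on one chromosome.
oracle_pileup <- function(reads, size) {
  v <- numeric(size)
  for (i in seq_len(nrow(reads))) {
    v[(reads$start[i] + 1):reads$end[i]] <- v[(reads$start[i] + 1):reads$end[i]] + 1
  }
  v
}

# Random non-degenerate interval set on [0, size).
random_intervals <- function(n, size, chrom = "chrA", seed = NULL) {
  gen <- function() {
    s <- sort(sample.int(size - 2, n))
    e <- pmin(s + sample.int(round(size / n) + 5, n, replace = TRUE), size)
    tibble::tibble(chrom = chrom, start = s, end = e)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
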