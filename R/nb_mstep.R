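#' Closed-form M-step update for the negative-binomial success probability
#'
#' Weighted maximum-likelihood estimator of `p` for one state with the
#' dispersion `r` held fixed:
#' `p = sum_t(w_t * r) / sum_t(w_t * (x_t + r))`,
#' where `w_t` is the posterior probability that window `t` is in the state.
#'
#' @param weights Posterior weights in `[0, 1]`, one per window; must have a
#'   positive sum.
#' @param x Emitted counts (non-negative integers), one per window.
#' @param r Current dispersion parameter (> 0).
#' @return The updated `p`, clamped to `[1e-10, 1 - 1e-10]`.
#' @export
nb_update_p <- function(weights, x, r) {
  stopifnot(length(weights) == length(x), r > 0)
  wsum <- sum(weights)
  if (wsum <= 0) {
    abort("state has zero posterior weight; cannot update p (state collapse)")
  }
  p <- (wsum * r) / sum(weights * (x + r))
  min(max(p, 1e-10), 1 - 1e-10)
}

#' Derivative of the weighted NB log-likelihood with respect to r
#'
#' `dl/dr = sum_t w_t * (digamma(x_t + r) - digamma(r) + log(p))`; this is
#' the score function driving the iterative dispersion search of
#' [nb_update_r()].
#'
#' @inheritParams nb_update_p
#' @param p Success probability in `(0, 1)`, held fixed.
#' @return The derivative value (a single number).
#' @export
nb_loglik_dr <- function(weights, x, p, r) {
  stopifnot(r > 0, p > 0, p < 1)
  sum(weights * (digamma(x + r) - digamma(r) + log(p)))
}

# Internal: weighted NB log-likelihood (used to keep the best r seen when
# the inner search hits its iteration cap; also the brute-force oracle's
# objective in the tests).
nb_weighted_loglik <- function(weights, x, p, r) {
  sum(weights * dnbinom(x, size = r, prob = p, log = TRUE))
}

#' Iterative M-step update for the negative-binomial dispersion
#'
#' Maximizes the weighted log-likelihood over `r` with `p` fixed by a
#' derivative-guided step search starting from the previous EM iteration's
#' estimate `r_start`. The step `delta` follows a fixed case table: while the
#' derivative keeps its sign the step is kept; when the sign flips the step
#' is halved and reversed (`delta <- -delta/2`); the very first step is
#' `+r_start` for a positive derivative and `-r_start/2` for a negative one.
#' Iteration stops when `|dl/dr| < threshold`.
#'
#' @inheritParams nb_loglik_dr
#' @param r_start Starting value (> 0), typically the current estimate.
#' @param threshold Stop when the absolute derivative falls below this
#'   (default 1e-5).
#' @param max_inner Safety cap on iterations (default 100); if reached, a
#'   warning is raised and the best `r` seen (by log-likelihood) is
#'   returned.
#' @return The updated dispersion `r` (> 0).
#' @export
nb_update_r <- function(weights, x, p, r_start, threshold = 1e-5,
                        max_inner = 100) {
  stopifnot(r_start > 0, p > 0, p < 1)
  if (sum(weights) <= 0) {
    abort("state has zero posterior weight; cannot update r (state collapse)")
  }
  r <- r_start
  delta <- 0
  best_r <- r
  best_ll <- nb_weighted_loglik(weights, x, p, r)
  for (i in seq_len(max_inner)) {
    d <- nb_loglik_dr(weights, x, p, r)
    if (abs(d) < threshold) return(r)
    if (d > 0) {
      delta <- if (delta > 0) delta else if (delta < 0) -delta / 2 else r_start
    } else {
      delta <- if (delta < 0) delta else if (delta > 0) -delta / 2 else -r_start / 2
    }
    while (r + delta <= 0) delta <- delta / 2  # positivity guard
    r <- r + delta
    ll <- nb_weighted_loglik(weights, x, p, r)
    if (ll > best_ll) { best_ll <- ll; best_r <- r }
  }
  warn(sprintf("dispersion search hit the iteration cap (%d); returning best r seen",
               max_inner))
  best_r
}

# Internal: full NB emission M-step. r and p are updated in alternation
# across EM iterations (r on even iterations, p on odd), each state and
# sample dimension independently; zero-weight states are frozen.
nb_m_step <- function(gamma, X, emissions, em_iteration) {
  stopifnot(em_iteration >= 0)
  p <- emissions$p
  r <- emissions$r
  update_r <- em_iteration %% 2 == 0
  for (j in 1:3) {
    w <- gamma[, j]
    if (sum(w) <= 1e-12) next
    for (d in seq_len(ncol(X))) {
      if (update_r) {
        r[j, d] <- nb_update_r(w, X[, d], p[j, d], r[j, d])
      } else {
        p[j, d] <- nb_update_p(w, X[, d], r[j, d])
      }
    }
  }
  list(p = p, r = r)
}
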