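#' Initialize the three-state peak-calling HMM
#'
#' Builds the starting model for Baum-Welch training. Per sample dimension,
#' the three state means are set to the 0, 0.5 and 0.99 quantiles of the
#' data, so the states start out ordered as no-signal / background / peak.
#' For Gaussian emissions the covariance is initialized from the sample
#' covariance according to `covariance_type`; for negative-binomial
#' emissions the per-state parameters are derived by moment matching
#' (p as mean/var, r as mean^2/(var - mean)) using the per-dimension
#' sample variance. Start probabilities and transitions start uniform (1/3).
#'
#' @param data Coverage tibble from [bin_coverage()] /
#'   [combine_samples()]. Negative-binomial emissions require sum-aggregated,
#'   unnormalized integer counts.
#' @param distribution `"gaussian"` (default) or `"nb"`.
#' @param covariance_type Gaussian covariance structure: `"diagonal"`
#'   (default), `"full"`, `"spherical"` (one variance per state) or `"tied"`
#'   (one full covariance shared by all states).
#' @param means Optional user-supplied 3 x D matrix of initial state means
#'   overriding the quantile rule.
#' @return An object of class `peak_hmm`.
#' @export
init_peak_hmm <- function(data, distribution = c("gaussian", "nb"),
                          covariance_type = c("diagonal", "full", "spherical", "tied"),
                          means = NULL) {
  distribution <- match.arg(distribution)
  covariance_type <- match.arg(covariance_type)
  check_interval_cols(data, "data")
  X <- coverage_values(data)
  if (nrow(X) == 0 || ncol(X) == 0) abort("`data` has no coverage values")
  D <- ncol(X)

  if (distribution == "nb") {
    if (is_normalized(data) || any(X < 0)) {
      abort("negative-binomial emissions need unnormalized, non-negative counts")
    }
    if (identical(coverage_mode(data), "mean") ||
        max(abs(X - round(X))) > 1e-9) {
      abort("negative-binomial emissions need integer counts (sum aggregation)")
    }
  }
  if (all(apply(X, 2, function(v) diff(range(v)) == 0))) {
    abort(paste("coverage is constant in every sample; a 3-state model cannot",
                "be fit. Check the input or the window width."))
  }

  if (is.null(means)) {
    q <- apply(X, 2, quantile, probs = c(0, 0.5, 0.99), names = FALSE)
    means <- matrix(q, nrow = 3, ncol = D)  # 3 x D, states in rows
  } else {
    means <- as.matrix(means)
    if (!all(dim(means) == c(3, D))) {
      abort(sprintf("`means` must be a 3 x %d matrix (states x samples)", D))
    }
  }

  if (distribution == "gaussian") {
    v <- apply(X, 2, var)
    v <- pmax(v, 1e-6)
    cov_list <- switch(covariance_type,
      diagonal = replicate(3, diag(v, nrow = D), simplify = FALSE),
      spherical = replicate(3, diag(rep(mean(v), D), nrow = D), simplify = FALSE),
      full = , tied = {
        S <- var(X)
        diag(S) <- pmax(diag(S), 1e-6)
        replicate(3, S, simplify = FALSE)
      })
    emissions <- list(means = means, cov = cov_list, covariance_type = covariance_type)
  } else {
    v <- apply(X, 2, var)
    p <- r <- matrix(NA_real_, 3, D)
    floored <- FALSE
    for (d in seq_len(D)) {
      for (j in 1:3) {
        m <- means[j, d]
        if (m <= 0) { m <- 1e-2; floored <- TRUE }
        vv <- v[d]
        if (vv <= m) { vv <- m * 1.001; floored <- TRUE }
        p[j, d] <- m / vv
        r[j, d] <- m^2 / (vv - m)
      }
    }
    if (floored) {
      inform("moment initialization floored mean/variance to keep p in (0,1) and r > 0")
    }
    emissions <- list(p = pmin(pmax(p, 1e-10), 1 - 1e-10), r = pmax(r, 1e-10))
  }

  structure(list(
    distribution = distribution,
    n_dim = D,
    start_probs = rep(1 / 3, 3),
    transitions = matrix(1 / 3, 3, 3),
    emissions = emissions,
    loglik_trace = numeric(0),
    n_iter = 0L,
    converged = NA
  ), class = "peak_hmm")
}

# Internal: T x 3 matrix of per-window emission log densities.
emission_logprob <- function(model, X) {
  T_ <- nrow(X); D <- ncol(X)
  logB <- matrix(NA_real_, T_, 3)
  if (model$distribution == "gaussian") {
    for (j in 1:3) {
      mu <- model$emissions$means[j, ]
      S <- model$emissions$cov[[j]]
      R <- chol(S)
      logdet <- 2 * sum(log(diag(R)))
      xc <- sweep(X, 2, mu)
      z <- backsolve(R, t(xc), transpose = TRUE)  # R' z = xc'
      mahal <- colSums(z^2)
      logB[, j] <- -0.5 * (D * log(2 * pi) + logdet + mahal)
    }
  } else {
    for (j in 1:3) {
      acc <- numeric(T_)
      for (d in seq_len(D)) {
        acc <- acc + dnbinom(X[, d], size = model$emissions$r[j, d],
                             prob = model$emissions$p[j, d], log = TRUE)
      }
      logB[, j] <- acc
    }
  }
  logB
}

# Internal: scaled forward-backward for one observation sequence.
# Returns log-likelihood, smoothed posteriors gamma (T x 3) and the matrix
# of expected transition counts xi_sum (3 x 3).
forward_backward <- function(start_probs, transitions, logB) {
  T_ <- nrow(logB); K <- ncol(logB)
  if (any(!is.finite(logB) & logB != -Inf)) {
    bad <- which(rowSums(!is.finite(logB) & logB != -Inf) > 0)[1]
    abort(sprintf("non-finite emission likelihood at window %d", bad))
  }
  bmax <- apply(logB, 1, max)
  B <- exp(logB - bmax)
  A <- transitions

  alpha <- matrix(0, T_, K)
  cvec <- numeric(T_)
  a <- start_probs * B[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) abort("zero forward probability at window 1")
  alpha[1, ] <- a / cvec[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- as.vector(alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a)
      if (cvec[t] <= 0) abort(sprintf("zero forward probability at window %d", t))
      alpha[t, ] <- a / cvec[t]
    }
  }
  loglik <- sum(log(cvec)) + sum(bmax)

  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  xi_sum <- matrix(0, K, K)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      bb <- B[t + 1, ] * beta[t + 1, ]
      beta[t, ] <- as.vector(A %*% bb) / cvec[t + 1]
      xi_sum <- xi_sum + (alpha[t, ] %o% bb) * A / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum)
}

# Internal: split a coverage tibble into per-chromosome value matrices,
# preserving window order. Each chromosome is an independent HMM sequence.
split_sequences <- function(data) {
  X <- coverage_values(data)
  idx <- split(seq_len(nrow(X)), factor(data$chrom, levels = unique(data$chrom)))
  purrr::map(idx, function(i) X[i, , drop = FALSE])
}

#' Fit the peak HMM by Baum-Welch
#'
#' Runs expectation-maximization until the change in total log-likelihood
#' drops below `tol` or `max_iter` iterations are reached. Each chromosome
#' is treated as an independent observation sequence. Gaussian parameters
#' use the standard weighted M-step with a variance floor of 1e-6;
#' negative-binomial `r` and `p` are updated in alternation — `r` on even
#' EM iterations (via the iterative derivative search of [nb_update_r()]),
#' `p` on odd ones (closed form, [nb_update_p()]) — with the other parameter
#' held fixed. States with (numerically) zero posterior weight keep their
#' previous parameters for that iteration.
#'
#' @param model A `peak_hmm` from [init_peak_hmm()].
#' @param data The coverage tibble the model was initialized on.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-3).
#' @param max_iter Maximum EM iterations (default 100); 0 returns the
#'   initial model unchanged.
#' @return The fitted `peak_hmm`, with `loglik_trace`, `n_iter` and
#'   `converged` filled in.
#' @export
fit_peak_hmm <- function(model, data, tol = 1e-3, max_iter = 100) {
  stopifnot(inherits(model, "peak_hmm"))
  check_interval_cols(data, "data")
  seqs <- split_sequences(data)
  if (any(purrr::map_int(seqs, ncol) != model$n_dim)) {
    abort("data dimensionality does not match the model")
  }
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    es <- purrr::map(seqs, ~forward_backward(model$start_probs, model$transitions,
                                             emission_logprob(model, .x)))
    ll <- sum(purrr::map_dbl(es, "loglik"))
    trace <- c(trace, ll)
    if (length(trace) > 1 && abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }

    gamma_all <- do.call(rbind, purrr::map(es, "gamma"))
    X_all <- do.call(rbind, seqs)
    xi_sum <- Reduce(`+`, purrr::map(es, "xi_sum"))
    gamma1 <- Reduce(`+`, purrr::map(es, ~.x$gamma[1, ]))

    model$start_probs <- gamma1 / sum(gamma1)
    rs <- rowSums(xi_sum)
    A <- model$transitions
    for (j in 1:3) if (rs[j] > 0) A[j, ] <- xi_sum[j, ] / rs[j]
    model$transitions <- A

    if (model$distribution == "gaussian") {
      model$emissions <- gaussian_m_step(gamma_all, X_all, model$emissions)
    } else {
      model$emissions <- nb_m_step(gamma_all, X_all, model$emissions,
                                   em_iteration = iter)
    }
    iter <- iter + 1L
  }
  model$loglik_trace <- trace
  model$n_iter <- iter
  model$converged <- converged
  model
}

# Internal: weighted Gaussian M-step under the four covariance structures.
gaussian_m_step <- function(gamma, X, emissions, floor = 1e-6) {
  D <- ncol(X)
  type <- emissions$covariance_type
  wsum <- colSums(gamma)
  means <- emissions$means
  covs <- emissions$cov
  scatter <- vector("list", 3)
  for (j in 1:3) {
    if (wsum[j] <= 1e-12) next  # state collapsed: freeze its parameters
    w <- gamma[, j]
    mu <- colSums(w * X) / wsum[j]
    means[j, ] <- mu
    xc <- sweep(X, 2, mu)
    scatter[[j]] <- crossprod(xc * sqrt(w)) / wsum[j]
  }
  if (type == "tied") {
    live <- which(!purrr::map_lgl(scatter, is.null))
    if (length(live) > 0) {
      S <- Reduce(`+`, purrr::map(live, ~scatter[[.x]] * wsum[.x])) / sum(wsum[live])
      S <- floor_cov(S, floor)
      covs <- replicate(3, S, simplify = FALSE)
    }
  } else {
    for (j in 1:3) {
      if (is.null(scatter[[j]])) next
      S <- scatter[[j]]
      covs[[j]] <- switch(type,
        full = floor_cov(S, floor),
        diagonal = diag(pmax(diag(S), floor), nrow = D),
        spherical = diag(rep(max(mean(diag(S)), floor), D), nrow = D))
    }
  }
  list(means = means, cov = covs, covariance_type = type)
}

# Internal: keep a covariance matrix positive definite (diagonal floor plus
# jitter until the Cholesky succeeds).
floor_cov <- function(S, floor = 1e-6) {
  diag(S) <- pmax(diag(S), floor)
  eps <- floor
  while (inherits(try(chol(S), silent = TRUE), "try-error")) {
    S <- S + diag(eps, nrow(S))
    eps <- eps * 10
  }
  S
}

#' Most likely state path (Viterbi decoding)
#'
#' @param model A fitted `peak_hmm`.
#' @param data The coverage tibble to decode (each chromosome decoded as an
#'   independent sequence).
#' @return The window tibble with `state` (1-3) and `label`
#'   (`no_signal` / `background` / `peak`) columns.
#' @export
decode_viterbi <- function(model, data) {
  stopifnot(inherits(model, "peak_hmm"))
  seqs <- split_sequences(data)
  path <- unlist(purrr::map(seqs, function(X) {
    viterbi_one(log(model$start_probs), log(model$transitions),
                emission_logprob(model, X))
  }), use.names = FALSE)
  labels <- label_states(model)
  out <- dplyr::select(as_tibble(data), "chrom", "start", "end")
  out$state <- path
  out$label <- factor(labels[path], levels = c("no_signal", "background", "peak"))
  out
}

# Internal: log-space Viterbi for one sequence; ties resolved to the lowest
# state index.
viterbi_one <- function(logpi, logA, logB) {
  T_ <- nrow(logB); K <- ncol(logB)
  delta <- logpi + logB[1, ]
  psi <- matrix(0L, T_, K)
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- delta + logA  # K x K: cand[i, j] = delta_i + logA[i, j]
      best <- apply(cand, 2, which.max)
      psi[t, ] <- best
      delta <- cand[cbind(best, 1:K)] + logB[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Posterior state probabilities (forward-backward smoothing)
#'
#' @inheritParams decode_viterbi
#' @return The window tibble with columns `p_no_signal`, `p_background`
#'   and `p_peak`; every row sums to 1.
#' @export
decode_posterior <- function(model, data) {
  stopifnot(inherits(model, "peak_hmm"))
  seqs <- split_sequences(data)
  gamma <- do.call(rbind, purrr::map(seqs, function(X) {
    forward_backward(model$start_probs, model$transitions,
                     emission_logprob(model, X))$gamma
  }))
  labels <- label_states(model)
  out <- dplyr::select(as_tibble(data), "chrom", "start", "end")
  for (role in c("no_signal", "background", "peak")) {
    out[[paste0("p_", role)]] <- gamma[, which(labels == role)]
  }
  out
}

# Internal: per-state emission mean, summed over sample dimensions.
state_means <- function(model) {
  if (model$distribution == "gaussian") {
    rowSums(model$emissions$means)
  } else {
    rowSums(model$emissions$r * (1 - model$emissions$p) / model$emissions$p)
  }
}

#' Assign biological roles to the HMM states
#'
#' States are ranked by their emission mean (summed across sample
#' dimensions; negative-binomial mean is `r(1-p)/p`): the lowest becomes
#' `no_signal`, the middle `background` and the highest `peak`. Ties keep
#' the original state order.
#'
#' @param model A `peak_hmm`.
#' @return Character vector of length 3: the role of each state index.
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "peak_hmm"))
  m <- state_means(model)
  if (anyDuplicated(m)) inform("tied state means; labels follow state index order")
  roles <- c("no_signal", "background", "peak")
  out <- character(3)
  out[order(m)] <- roles
  out
}

#' @export
print.peak_hmm <- function(x, ...) {
  cat(sprintf("3-state peak HMM (%s emissions, %d sample dimension%s)\n",
              x$distribution, x$n_dim, if (x$n_dim > 1) "s" else ""))
  cat(sprintf("  EM iterations: %d%s\n", x$n_iter,
              if (isTRUE(x$converged)) " (converged)" else ""))
  if (length(x$loglik_trace) > 0) {
    cat(sprintf("  log-likelihood: %.3f\n", tail(x$loglik_trace, 1)))
  }
  labels <- label_states(x)
  m <- state_means(x)
  for (j in order(m)) {
    cat(sprintf("  state %d [%s]: mean %.4g\n", j, labels[j], m[j]))
  }
  invisible(x)
}

#' Tidy a fitted peak HMM
#'
#' @param x A `peak_hmm`.
#' @param ... Unused.
#' @return One row per state and sample dimension with the emission
#'   parameters: Gaussian (`mean`, `variance`) or negative-binomial
#'   (`r`, `p`, `mean`).
#' @exportS3Method generics::tidy
tidy.peak_hmm <- function(x, ...) {
  labels <- label_states(x)
  grid <- tidyr::expand_grid(state = 1:3, dimension = seq_len(x$n_dim))
  out <- mutate(grid, label = labels[.data$state])
  if (x$distribution == "gaussian") {
    out$mean <- x$emissions$means[cbind(grid$state, grid$dimension)]
    out$variance <- purrr::map2_dbl(grid$state, grid$dimension,
                                    ~x$emissions$cov[[.x]][.y, .y])
  } else {
    out$r <- x$emissions$r[cbind(grid$state, grid$dimension)]
    out$p <- x$emissions$p[cbind(grid$state, grid$dimension)]
    out$mean <- out$r * (1 - out$p) / out$p
  }
  dplyr::relocate(out, "state", "label", "dimension")
}

#' Summarize a fitted peak HMM in one row
#'
#' @inheritParams tidy.peak_hmm
#' @return A one-row tibble: distribution, dimensions, final log-likelihood,
#'   iteration count and convergence flag.
#' @exportS3Method generics::glance
glance.peak_hmm <- function(x, ...) {
  tibble(distribution = x$distribution, n_states = 3L, n_dim = x$n_dim,
         log_lik = if (length(x$loglik_trace)) tail(x$loglik_trace, 1) else NA_real_,
         n_iter = x$n_iter, converged = x$converged)
}

#' Plot the EM log-likelihood trace
#'
#' @param object A fitted `peak_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.peak_hmm <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loglik_trace),
               log_likelihood = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Dump / load a peak HMM as a plain-text key-value file
#'
#' @param model A `peak_hmm`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_peak_hmm()` returns the model.
#' @export
write_peak_hmm <- function(model, path) {
  stopifnot(inherits(model, "peak_hmm"))
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  lines <- c(
    paste0("distribution\t", model$distribution),
    paste0("n_dim\t", model$n_dim),
    paste0("start_probs\t", num(model$start_probs)),
    paste0("transitions\t", num(t(model$transitions))),
    paste0("n_iter\t", model$n_iter),
    paste0("converged\t", isTRUE(model$converged)),
    paste0("loglik_trace\t", num(model$loglik_trace))
  )
  if (model$distribution == "gaussian") {
    lines <- c(lines,
      paste0("covariance_type\t", model$emissions$covariance_type),
      paste0("means\t", num(t(model$emissions$means))),
      purrr::map_chr(1:3, ~paste0("cov_state", .x, "\t", num(t(model$emissions$cov[[.x]])))))
  } else {
    lines <- c(lines,
      paste0("nb_p\t", num(t(model$emissions$p))),
      paste0("nb_r\t", num(t(model$emissions$r))))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_peak_hmm
#' @export
read_peak_hmm <- function(path) {
  kv <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  keys <- purrr::map_chr(kv, 1)
  vals <- purrr::map(kv, ~if (length(.x) > 1) .x[[2]] else "")
  names(vals) <- keys
  nums <- function(k) as.numeric(strsplit(trimws(vals[[k]]), " +")[[1]])
  D <- as.integer(vals$n_dim)
  distribution <- vals$distribution
  emissions <- if (distribution == "gaussian") {
    list(means = matrix(nums("means"), 3, D, byrow = TRUE),
         cov = purrr::map(1:3, ~matrix(nums(paste0("cov_state", .x)), D, D, byrow = TRUE)),
         covariance_type = vals$covariance_type)
  } else {
    list(p = matrix(nums("nb_p"), 3, D, byrow = TRUE),
         r = matrix(nums("nb_r"), 3, D, byrow = TRUE))
  }
  trace <- if (nzchar(trimws(vals$loglik_trace))) nums("loglik_trace") else numeric(0)
  structure(list(
    distribution = distribution, n_dim = D,
    start_probs = nums("start_probs"),
    transitions = matrix(nums("transitions"), 3, 3, byrow = TRUE),
    emissions = emissions,
    loglik_trace = trace,
    n_iter = as.integer(vals$n_iter),
    converged = as.logical(vals$converged)
  ), class = "peak_hmm")
}
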