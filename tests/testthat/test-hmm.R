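test_that("quantile initialization follows the 0/0.5/0.99 rule", {
  cv <- cov_tbl(0:100)
  m <- init_peak_hmm(cv, "gaussian")
  expect_equal(as.vector(m$emissions$means), c(0, 50, 99))
  expect_equal(m$start_probs, rep(1 / 3, 3))
  expect_equal(m$transitions, matrix(1 / 3, 3, 3))
})

test_that("NB moment initialization inverts to the target means", {
  # mean 2, variance 4 -> p = 0.5, r = 2 (checked through a data column whose
  # median is 2 and variance 4)
  x <- c(0, 0, 1, 2, 2, 2, 3, 4, 5)  # median 2
  cv <- cov_tbl(x, mode = "sum")
  # the 0-quantile state has mean 0, which the initializer floors (messaged)
  expect_message(m <- init_peak_hmm(cv, "nb"), "floored")
  v <- var(x)
  expect_equal(m$emissions$p[2, 1], 2 / v)
  expect_equal(m$emissions$r[2, 1], 4 / (v - 2))
  # implied means reproduce the quantile targets
  means <- m$emissions$r * (1 - m$emissions$p) / m$emissions$p
  expect_equal(means[2, 1], 2, tolerance = 1e-9)
})

test_that("under-dispersed counts are floored so p and r stay legal", {
  x <- rep(c(4, 5), 30)  # variance < mean
  expect_message(m <- init_peak_hmm(cov_tbl(x, mode = "sum"), "nb"), "floored")
  expect_true(all(m$emissions$p > 0 & m$emissions$p < 1))
  expect_true(all(is.finite(m$emissions$r) & m$emissions$r > 0))
})

test_that("initialization guards its preconditions", {
  expect_error(init_peak_hmm(cov_tbl(rep(3, 50)), "gaussian"), "constant")
  expect_error(init_peak_hmm(cov_tbl(c(0.5, 1.2, 3)), "nb"), "integer")
  expect_error(init_peak_hmm(cov_tbl(0:10), "gaussian", means = matrix(1, 2, 1)),
               "3 x 1")
})

test_that("Viterbi and posteriors agree with exhaustive path enumeration", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      T_ <- sample(2:8, 1)
      pi_ <- runif(3); pi_ <- pi_ / sum(pi_)
      A <- matrix(runif(9), 3, 3); A <- A / rowSums(A)
      mdl <- make_gauss_model(pi_, A, means = matrix(rnorm(3, sd = 3), 3, 1),
                              vars = runif(3, 0.3, 2))
      x <- rnorm(T_, sample(mdl$emissions$means, T_, replace = TRUE), 1)
      cv <- cov_tbl(x)
      logB <- oracle_logB(mdl, x)

      got_path <- decode_viterbi(mdl, cv)$state
      expect_equal(got_path, unname(enum_viterbi(pi_, A, logB)))

      post <- decode_posterior(mdl, cv)
      labels <- label_states(mdl)
      # reorder posterior columns back to state index order
      got_gamma <- sapply(1:3, function(j) post[[paste0("p_", labels[j])]])
      expect_equal(unname(got_gamma), unname(enum_posteriors(pi_, A, logB)),
                   tolerance = 1e-9)
      expect_equal(rowSums(got_gamma), rep(1, T_), tolerance = 1e-9)
    }
  })
})

test_that("single-window Viterbi is the posterior argmax over start state", {
  mdl <- make_gauss_model(c(0.5, 0.3, 0.2), matrix(1 / 3, 3, 3),
                          matrix(c(0, 2, 10), 3, 1), rep(1, 3))
  x <- 1.4
  expect_equal(decode_viterbi(mdl, cov_tbl(x))$state,
               which.max(log(mdl$start_probs) + oracle_logB(mdl, x)[1, ]))
})

test_that("symmetric models give uniform posteriors", {
  mdl <- make_gauss_model(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                          matrix(c(5, 5, 5), 3, 1), rep(2, 3))
  post <- decode_posterior(mdl, cov_tbl(c(1, 9, 4, 5)))
  expect_equal(as.matrix(post[, 4:6]), matrix(1 / 3, 4, 3),
               ignore_attr = TRUE)
})

test_that("EM log-likelihood is monotone and simplexes stay normalized", {
  withr::with_seed(32, {
    x <- c(rnorm(150, 0, 0.5), rnorm(100, 3, 1), rnorm(80, 9, 1.5))
    x <- x[sample(length(x))]
  })
  cv <- cov_tbl(x)
  m <- init_peak_hmm(cv, "gaussian")
  f <- fit_peak_hmm(m, cv, tol = 1e-8, max_iter = 40)
  expect_true(all(diff(f$loglik_trace) >= -1e-8))
  expect_equal(rowSums(f$transitions), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(f$start_probs), 1, tolerance = 1e-9)

  # one EM iteration never lowers the likelihood
  f1 <- fit_peak_hmm(m, cv, tol = 0, max_iter = 2)
  expect_gte(f1$loglik_trace[2], f1$loglik_trace[1] - 1e-8)

  # max_iter = 0 is the identity
  f0 <- fit_peak_hmm(m, cv, max_iter = 0)
  expect_equal(f0$emissions, m$emissions)
  expect_equal(f0$transitions, m$transitions)
})

test_that("NB EM log-likelihood is non-decreasing under alternating updates", {
  sim <- sim_nb_hmm(rep(1 / 3, 3),
                    matrix(c(.9, .05, .05, .05, .9, .05, .05, .05, .9), 3, 3, TRUE),
                    r = c(1, 4, 6), p = c(0.5, 1 / 3, 1 / 6), T_ = 1500, seed = 33)
  cv <- cov_tbl(sim$x, mode = "sum")
  m <- init_peak_hmm(cv, "nb")
  f <- fit_peak_hmm(m, cv, tol = 0, max_iter = 20)
  expect_true(all(diff(f$loglik_trace) >= -1e-6))
})

test_that("Gaussian parameters are recovered on well-separated simulated data", {
  A <- matrix(c(.95, .04, .01, .03, .94, .03, .02, .03, .95), 3, 3, TRUE)
  sim <- sim_gauss_hmm(rep(1 / 3, 3), A, means = c(0, 2, 10),
                       sds = c(0.5, 0.5, 1), T_ = 5000, seed = 34)
  cv <- cov_tbl(sim$x)
  f <- fit_peak_hmm(init_peak_hmm(cv, "gaussian"), cv, tol = 1e-6, max_iter = 100)
  expect_equal(sort(as.vector(f$emissions$means)), c(0, 2, 10), tolerance = 0.2)
})

test_that("NB state means are recovered within 15% on simulated counts", {
  A <- matrix(c(.95, .04, .01, .03, .94, .03, .02, .03, .95), 3, 3, TRUE)
  truth_means <- c(1, 8, 30)
  sim <- sim_nb_hmm(rep(1 / 3, 3), A, r = c(1, 4, 6), p = c(0.5, 1 / 3, 1 / 6),
                    T_ = 5000, seed = 35)
  cv <- cov_tbl(sim$x, mode = "sum")
  f <- fit_peak_hmm(init_peak_hmm(cv, "nb"), cv, tol = 1e-6, max_iter = 60)
  got <- sort(as.vector(f$emissions$r * (1 - f$emissions$p) / f$emissions$p))
  expect_equal(got, truth_means, tolerance = 0.15)
})

test_that("covariance structures all fit and stay positive definite", {
  withr::with_seed(36, {
    x1 <- c(rnorm(100, 0, 1), rnorm(100, 5, 1))
    x2 <- x1 * 0.5 + rnorm(200, 0, 0.7)
  })
  cv <- cov_tbl(cbind(x1, x2))
  for (type in c("diagonal", "full", "spherical", "tied")) {
    f <- fit_peak_hmm(init_peak_hmm(cv, "gaussian", covariance_type = type),
                      cv, max_iter = 15)
    expect_true(all(diff(f$loglik_trace) >= -1e-8), info = type)
    for (S in f$emissions$cov) expect_true(all(eigen(S)$values > 0), info = type)
    if (type == "spherical") {
      expect_equal(f$emissions$cov[[1]][1, 1], f$emissions$cov[[1]][2, 2])
    }
    if (type == "tied") {
      expect_equal(f$emissions$cov[[1]], f$emissions$cov[[3]])
    }
  }
})

test_that("states are labelled by emission mean, not by index", {
  g <- make_gauss_model(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                        matrix(c(3, 10, 0), 3, 1), rep(1, 3))
  expect_equal(label_states(g), c("background", "peak", "no_signal"))

  nb <- structure(list(distribution = "nb", n_dim = 1,
                       start_probs = rep(1 / 3, 3),
                       transitions = matrix(1 / 3, 3, 3),
                       emissions = list(p = matrix(0.5, 3, 1),
                                        r = matrix(c(2, 8, 20), 3, 1)),
                       loglik_trace = numeric(0), n_iter = 0L, converged = NA),
                  class = "peak_hmm")
  expect_equal(label_states(nb), c("no_signal", "background", "peak"))
})

test_that("deterministically separable emissions decode to their ranges", {
  mdl <- make_gauss_model(rep(1 / 3, 3),
                          matrix(c(.8, .1, .1, .1, .8, .1, .1, .1, .8), 3, 3, TRUE),
                          matrix(c(0, 50, 100), 3, 1), rep(1, 3))
  x <- c(0, 1, 50, 49, 100, 99, 0)
  d <- decode_viterbi(mdl, cov_tbl(x))
  expect_equal(d$state, c(1, 1, 2, 2, 3, 3, 1))
  expect_equal(as.character(d$label),
               c("no_signal", "no_signal", "background", "background",
                 "peak", "peak", "no_signal"))
})

test_that("each chromosome is decoded as an independent sequence", {
  mdl <- make_gauss_model(c(0.98, 0.01, 0.01),
                          matrix(c(.98, .01, .01, .01, .98, .01, .01, .01, .98),
                                 3, 3, TRUE),
                          matrix(c(0, 5, 10), 3, 1), rep(1, 3))
  cv <- dplyr::bind_rows(cov_tbl(c(10, 10, 10), chrom = "chrA"),
                         cov_tbl(c(0, 0, 0), chrom = "chrB"))
  d <- decode_viterbi(mdl, cv)
  # chrB restarts from the start distribution, unaffected by chrA's path
  expect_equal(d$state, c(3, 3, 3, 1, 1, 1))
})

test_that("fitted models round-trip through the plain-text dump", {
  withr::with_seed(37, x <- c(rnorm(60, 0, 1), rnorm(60, 6, 2)))
  cv <- cov_tbl(x)
  f <- fit_peak_hmm(init_peak_hmm(cv, "gaussian"), cv, max_iter = 10)
  path <- withr::local_tempfile()
  write_peak_hmm(f, path)
  g <- read_peak_hmm(path)
  expect_equal(g$transitions, f$transitions)
  expect_equal(g$emissions$means, f$emissions$means)
  expect_equal(g$emissions$cov, f$emissions$cov)
  expect_equal(decode_viterbi(g, cv)$state, decode_viterbi(f, cv)$state)

  fnb <- fit_peak_hmm(init_peak_hmm(cov_tbl(rpois(100, 4), mode = "sum"), "nb"),
                      cov_tbl(rpois(100, 4), mode = "sum"), max_iter = 0)
  write_peak_hmm(fnb, path)
  expect_equal(read_peak_hmm(path)$emissions, fnb$emissions)
})

test_that("tidy and glance summarize the fitted model", {
  withr::with_seed(38, x <- c(rnorm(80, 0, 1), rnorm(80, 8, 1)))
  cv <- cov_tbl(x)
  f <- fit_peak_hmm(init_peak_hmm(cv, "gaussian"), cv, max_iter = 20)
  td <- tidy(f)
  expect_equal(nrow(td), 3)
  expect_setequal(td$label, c("no_signal", "background", "peak"))
  gl <- glance(f)
  expect_equal(gl$log_lik, tail(f$loglik_trace, 1))
  expect_s3_class(autoplot(f), "ggplot")
})
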