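toy_windows <- function(size = 2000, width = 400, chrom = "chrA") {
  make_windows(stats::setNames(size, chrom), width = width)
}

test_that("window aggregation matches mean and sum of per-base pileup", {
  w <- toy_windows(size = 800, width = 4)
  # per-base coverages 2,2,3,3 in the first width-4 window
  track <- tibble::tibble(chrom = "chrA", start = c(0, 2), end = c(4, 4),
                          value = c(2, 1))
  expect_equal(bin_coverage(w, track, "mean")$coverage[1], 2.5)
  expect_equal(bin_coverage(w, track, "sum")$coverage[1], 10)

  # a single 100 bp read fully inside an 800 bp window
  w8 <- toy_windows(size = 1600, width = 800)
  read <- tibble::tibble(chrom = "chrA", start = 100, end = 200)
  expect_equal(bin_coverage(w8, read, "mean")$coverage, c(0.125, 0))
})

test_that("binning equals a brute-force per-base pileup on random reads", {
  size <- 10000
  w <- toy_windows(size = size, width = 800)
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(20:80, 1)
      starts <- sample.int(size - 120, n)
      reads <- tibble::tibble(chrom = "chrA", start = starts,
                              end = starts + sample(30:120, n, replace = TRUE))
      pile <- oracle_pileup(reads, size)
      got_sum <- bin_coverage(w, reads, "sum")$coverage
      got_mean <- bin_coverage(w, reads, "mean")$coverage
      exp_sum <- vapply(seq_len(nrow(w)), function(i)
        sum(pile[(w$start[i] + 1):w$end[i]]), numeric(1))
      expect_equal(got_sum, exp_sum)
      expect_equal(got_mean, exp_sum / (w$end - w$start))
    }
  })
})

test_that("constant tracks bin to the constant, including truncated windows", {
  w <- make_windows(c(chrA = 2100), width = 800)
  track <- tibble::tibble(chrom = "chrA", start = 0, end = 2100, value = 2.5)
  expect_equal(bin_coverage(w, track, "mean")$coverage, rep(2.5, 3))
})

test_that("chromosome mismatches are warned about, not fatal", {
  w <- make_windows(c(chrA = 1000, chrB = 1000), width = 500)
  reads <- tibble::tibble(chrom = c("chrA", "chrX"), start = c(0, 0),
                          end = c(100, 100))
  expect_warning(expect_warning(cv <- bin_coverage(w, reads, "sum"),
                                "chrX"), "chrB")
  expect_equal(cv$coverage, c(100, 0, 0, 0))
})

test_that("fractional signal is rounded for sum aggregation, with a warning", {
  w <- toy_windows(size = 400, width = 400)
  track <- tibble::tibble(chrom = "chrA", start = 0, end = 5, value = 0.5)
  expect_warning(cv <- bin_coverage(w, track, "sum"), "rounded")
  expect_equal(cv$coverage, 2)  # 2.5 rounds to even
})

test_that("control normalization is the printed log2 pseudocount formula", {
  w <- toy_windows(size = 1200, width = 400)
  chip <- w; chip$chip <- c(3, 0, 0)
  ctrl <- w; ctrl$control <- c(1, 0, 3)
  attr(chip, "mode") <- attr(ctrl, "mode") <- "mean"
  out <- normalize_with_control(chip, ctrl)
  expect_equal(out$chip, c(1, 0, -2))
  expect_true(attr(out, "normalized"))
})

test_that("normalizing a sample against itself is identically zero", {
  w <- toy_windows()
  x <- w; x$coverage <- runif(nrow(w), 0, 50)
  attr(x, "mode") <- "mean"
  expect_equal(normalize_with_control(x, x)$coverage, rep(0, nrow(w)))
})

test_that("normalization preconditions are enforced", {
  w <- toy_windows()
  x <- w; x$coverage <- rep(2, nrow(w)); attr(x, "mode") <- "mean"
  y <- x[-1, ]
  expect_error(normalize_with_control(x, y), "grids")
  xs <- w; xs$coverage <- rep(2, nrow(w)); attr(xs, "mode") <- "sum"
  expect_error(normalize_with_control(xs, xs), "Gaussian")
  norm <- normalize_with_control(x, x)
  expect_error(normalize_with_control(norm, x), "already normalized")
  expect_error(init_peak_hmm(norm, distribution = "nb"), "negative-binomial")
})

test_that("sample combination: sum equals the column-wise sum of vector mode", {
  w <- toy_windows(size = 800, width = 400)
  a <- w; a$coverage <- c(1, 2); attr(a, "mode") <- "mean"
  b <- w; b$coverage <- c(3, 4); attr(b, "mode") <- "mean"
  sum_ <- combine_samples(list(a, b), "sum")
  vec <- combine_samples(list(a, b), "vector")
  expect_equal(sum_$coverage, c(4, 6))
  expect_equal(ncol(vec), 5)  # chrom,start,end + 2 samples
  expect_equal(rowSums(as.matrix(vec[, 4:5])), sum_$coverage)
  expect_equal(combine_samples(a, "sum")$coverage, c(1, 2))  # identity
})

test_that("mixing normalized and raw samples is refused", {
  w <- toy_windows(size = 800, width = 400)
  a <- w; a$coverage <- c(1, 2); attr(a, "mode") <- "mean"
  b <- normalize_with_control(a, a)
  expect_error(combine_samples(list(a, b)), "mix")
})

test_that("bedGraph files round-trip through read and write", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  x <- tibble::tibble(chrom = "chrA", start = c(0, 500), end = c(500, 900),
                      value = c(2, 7))
  write_bedgraph(x, path)
  expect_equal(read_bedgraph(path), x)
})
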