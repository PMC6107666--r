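test_that("input validation rejects short, non-finite and accepts labelled series", {
  expect_error(as_time_series(1:10), "at least 16")
  expect_error(as_time_series(c(rnorm(20), NA)), "missing or non-finite")
  expect_error(as_time_series(c(rnorm(20), Inf)), "missing or non-finite")
  s <- as_time_series(rnorm(32), label = "probe")
  expect_s3_class(s, "time_series")
  expect_identical(attr(s, "label"), "probe")
})

test_that("a pure sinusoid is its own first IMF and the residual is negligible", {
  x <- tone(512, 16)
  d <- emd(x)
  expect_gt(cor(d$imfs[, 1], x), 0.99)
  expect_lt(sd(reconstruct(d) - d$imfs[, 1]), 0.05 * sd(x))
})

test_that("plain EMD is exactly additive on random inputs", {
  for (i in 1:100) {
    set.seed(i)
    x <- cumsum(rnorm(128)) + rnorm(128)
    d <- emd(x)
    expect_lt(max(abs(reconstruct(d) - x)) / sd(x), 1e-9)
  }
})

test_that("degenerate inputs: ramp and constant yield zero IMFs", {
  ramp <- seq(0, 1, length.out = 100)
  d <- emd(ramp)
  expect_identical(nimf(d), 0L)
  expect_equal(d$residual, ramp)
  dc <- emd(rep(2.5, 50))
  expect_identical(nimf(dc), 0L)
  expect_equal(dc$residual, rep(2.5, 50))
})

test_that("one sifting iteration matches an independent natural-spline reference", {
  set.seed(11)
  x <- two_tone(256) + 0.3 * rnorm(256)
  got <- emd(x, max_imfs = 1, sift_iterations = 1)$imfs[, 1]
  expect_equal(got, reference_sift_once(x), tolerance = 1e-10)
})

test_that("IMFs are ordered fine to coarse on a multi-tone signal", {
  x <- tone(512, 8) + tone(512, 32) + tone(512, 128)
  d <- emd(x)
  ex <- apply(d$imfs, 2, count_extrema)
  expect_true(all(diff(ex) <= 0))
})

test_that("band-separated tones decompose near-orthogonally", {
  x <- two_tone(512, 8, 64)
  d <- emd(x)
  ip <- abs(sum(d$imfs[, 1] * d$imfs[, 2]))
  expect_lt(ip / sum(x^2), 0.05)
})

test_that("EEMD with zero noise collapses to plain EMD", {
  x <- two_tone(256)
  expect_equal(eemd(x, 0, ensemble_size = 50), emd(x))
})

test_that("EEMD is bitwise reproducible under a fixed seed and validates inputs", {
  x <- two_tone(128)
  e1 <- eemd(x, 0.2, ensemble_size = 20, seed = 7)
  e2 <- eemd(x, 0.2, ensemble_size = 20, seed = 7)
  expect_identical(e1$imfs, e2$imfs)
  expect_identical(e1$residual, e2$residual)
  e3 <- eemd(x, 0.2, ensemble_size = 20, seed = 8)
  expect_false(identical(e1$imfs, e3$imfs))
  expect_error(eemd(x, -0.1, 20), "noise_level")
  expect_error(eemd(x, 1.5, 20), "noise_level")
  expect_error(eemd(x, 0.2, 0), "ensemble_size")
})

test_that("EEMD does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(eemd(two_tone(64), 0.2, ensemble_size = 5, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("EEMD reconstruction error shrinks as 1/sqrt(N)", {
  x <- two_tone(256)
  err <- function(N) {
    d <- eemd(x, 0.3, ensemble_size = N, seed = 5)
    sqrt(mean((reconstruct(d) - x)^2))
  }
  e50 <- err(50); e500 <- err(500)
  expect_lt(e500, e50)
  expect_lt(e500 / sd(x), 0.3 / sqrt(500) * 3)  # within 3x of the noise/sqrt(N) scale
})

test_that("EEMD ensemble means stabilise as the ensemble grows", {
  set.seed(21)
  x <- two_tone(256) + 0.5 * rnorm(256)
  d <- function(N, s) eemd(x, 0.2, ensemble_size = N, seed = s)$imfs
  small <- mean(abs(d(50, 1) - d(100, 2)))
  large <- mean(abs(d(250, 3) - d(500, 4)))
  expect_lt(large, small)
})

test_that("white noise decomposes as a dyadic filter bank", {
  # hallmark of EMD on white noise: the mean period doubles from one IMF to
  # the next, so the extrema count roughly halves, and the count of modes
  # above a 0.1% total-variance floor scales like log2(L)
  counts <- vapply(1:3, function(s) {
    set.seed(s)
    z <- rnorm(512)
    d <- eemd(z, 0.2, ensemble_size = 200, max_imfs = 11, seed = 100 + s)
    ex <- apply(d$imfs[, 1:4], 2, count_extrema)
    ratio <- ex[-1] / ex[-4]
    expect_true(all(ratio > 0.35 & ratio < 0.7))
    sum(apply(d$imfs, 2, var) >= 0.001 * var(z))
  }, numeric(1))
  expect_true(all(counts >= 6 & counts <= 8))
})
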