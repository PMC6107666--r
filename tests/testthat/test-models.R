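test_that("coupled logistic map reproduces hand-iterated values and stays bounded", {
  m <- coupled_logistic(400)
  # x(2) = 0.2*(3.8 - 3.8*0.2 - 0.02*0.4), y(2) = 0.4*(3.5 - 3.5*0.4 - 0.1*0.2)
  expect_equal(m$x[2], 0.6064)
  expect_equal(m$y[2], 0.832)
  expect_true(all(m$x > 0 & m$x < 1))
  expect_true(all(m$y > 0 & m$y < 1))
  # chaotic: no short periodicity
  ac <- acf(as.numeric(m$x), lag.max = 20, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 0.95))
  expect_error(coupled_logistic(400, x1 = 1.2), "0, 1")
  expect_error(coupled_logistic(10), ">= 16")
})

test_that("AR benchmark has the period-8 skeleton and y lagging x by 2", {
  # noise-free skeleton: roots 0.95 exp(+-i pi/4) -> 8-sample oscillation
  n <- 160
  x <- numeric(n); x[1:2] <- c(1, 1)
  for (t in 2:(n - 1)) x[t + 1] <- 0.95 * sqrt(2) * x[t] - 0.9025 * x[t - 1]
  ext <- count_extrema(x[41:n])  # 120 samples of settled oscillation
  expect_true(abs(ext - 120 / 8 * 2) <= 2)
  m <- ar_stochastic(10000, seed = 3)
  cc <- vapply(0:5, function(l)
    cor(m$x[1:(10000 - l)], m$y[(1 + l):10000]), numeric(1))
  expect_identical(which.max(cc) - 1L, 2L)
  m2 <- ar_stochastic(10000, seed = 3)
  expect_identical(as.numeric(m$x), as.numeric(m2$x))
  expect_identical(as.numeric(m$y), as.numeric(m2$y))
  m3 <- ar_stochastic(10000, seed = 4)
  expect_false(identical(as.numeric(m$x), as.numeric(m3$x)))
})

test_that("Lotka-Volterra conserves its fixed point and first integral", {
  # equilibrium x* = gamma/delta = 25, y* = alpha/beta = 20
  eq <- lotka_volterra(duration = 100, x0 = 25, y0 = 20)
  expect_lt(diff(range(eq$x)), 1e-6)
  expect_lt(diff(range(eq$y)), 1e-6)
  m <- lotka_volterra(duration = 50, dt = 0.01)
  H <- 0.02 * as.numeric(m$x) - 0.5 * log(as.numeric(m$x)) +
       0.05 * as.numeric(m$y) - 1 * log(as.numeric(m$y))
  expect_lt(diff(range(H)), 1e-4)
  # predator peaks lag prey peaks: cross-correlation maximal at positive lag
  cc <- vapply(0:10, function(l)
    cor(m$x[1:(length(m$x) - l)], m$y[(1 + l):length(m$y)]), numeric(1))
  expect_gt(which.max(cc) - 1L, 0L)
  expect_error(lotka_volterra(alpha = -1), "positive")
})

test_that("white-noise pairs are seeded, sized and uncorrelated", {
  pairs <- white_noise_pairs(200, length = 100, seed = 77)
  expect_length(pairs, 200)
  expect_true(all(vapply(pairs, function(p) length(p$x) == 100, logical(1))))
  again <- white_noise_pairs(200, length = 100, seed = 77)
  expect_identical(lapply(pairs, function(p) as.numeric(p$x)),
                   lapply(again, function(p) as.numeric(p$x)))
  rs <- vapply(pairs, function(p) abs(cor(as.numeric(p$x), as.numeric(p$y))),
               numeric(1))
  expect_gte(mean(rs < 3 / sqrt(100)), 0.97)
  lens <- white_noise_pairs(3, length = c(50, 200, 500), seed = 1)
  expect_identical(vapply(lens, function(p) length(p$x), integer(1)),
                   c(50L, 200L, 500L))
})

test_that("downsample keeps every factor-th sample and validates the result", {
  x <- as_time_series(rnorm(400))
  expect_identical(as.numeric(downsample(x, 1)), as.numeric(x))
  d2 <- downsample(x, 2)
  expect_length(d2, 200)
  expect_identical(as.numeric(d2), as.numeric(x)[seq(1, 400, by = 2)])
  expect_error(downsample(x, 30), "fewer than 16")
})

test_that("time shift trims to the overlap and the circular variant preserves length", {
  a <- as_time_series(seq_len(100) + 0)
  b <- as_time_series(seq_len(100) * 2)
  sh <- time_shift(a, b, 5)
  expect_length(sh$a, 95)
  expect_length(sh$b, 95)
  # shifting back recovers the overlap
  back <- time_shift(sh$a, sh$b, -5)
  expect_length(back$a, 90)
  circ <- time_shift(a, b, 7, circular = TRUE)
  expect_length(circ$b, 100)
  expect_identical(sort(as.numeric(circ$b)), sort(as.numeric(b)))
  expect_error(time_shift(a, b, 30), "length/4")
  id <- time_shift(a, b, 0)
  expect_identical(as.numeric(id$b), as.numeric(b))
})
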