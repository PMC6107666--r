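# small parameter set keeping EEMD cheap in unit tests
tiny_params <- function(seed = 5, ...) {
  eemd_params(0.2, ensemble_size = 10L, max_imfs = 4L, seed = seed, ...)
}

test_that("relative strengths follow the ratio rule and its small-distance guard", {
  r <- list(d_ab = 0.3, d_ba = 0.1)
  expect_equal(relative_strengths(r)$c_ab, 0.75)
  # both distances below 0.05: ratio formed from d + 1
  r0 <- relative_strengths(list(d_ab = 0, d_ba = 0))
  expect_equal(r0$c_ab, 0.5)
  expect_equal(r0$c_ba, 0.5)
  rg <- relative_strengths(list(d_ab = 0.04, d_ba = 0.02))
  expect_equal(rg$c_ab, 1.04 / 2.06)
  # guard only engages when BOTH are small
  rm <- relative_strengths(list(d_ab = 0.04, d_ba = 0.2))
  expect_equal(rm$c_ab, 0.04 / 0.24)
})

test_that("variance-weighted distance matches hand evaluation", {
  d <- causaldecomp:::coh_distance(c(0.9, 0.8), c(0.5, 0.8), c(0.5, 0.5),
                                   "full_profile", 1L)
  expect_equal(d, sqrt(0.5 * 0.16))
  # identical profiles give zero distance
  expect_equal(causaldecomp:::coh_distance(c(0.9, 0.8), c(0.9, 0.8),
                                           c(0.5, 0.5), "full_profile", 1L), 0)
})

test_that("absolute strengths produce bounded distances and normalised weights", {
  set.seed(2)
  x <- two_tone(200, 8, 64) + 0.2 * rnorm(200)
  y <- two_tone(200, 8, 64, a1 = 0.6) + 0.2 * rnorm(200)
  p <- tiny_params()
  da <- eemd(x, p$noise_level, p$ensemble_size, p$max_imfs, seed = 1)
  db <- eemd(y, p$noise_level, p$ensemble_size, p$max_imfs, seed = 2)
  r <- relative_strengths(absolute_strengths(x, y, da, db, 1, p))
  expect_equal(sum(r$weights), 1)
  expect_true(all(r$weights >= 0))
  expect_true(r$d_ab >= 0 && r$d_ab <= 1)
  expect_true(r$d_ba >= 0 && r$d_ba <= 1)
  expect_equal(r$c_ab + r$c_ba, 1, tolerance = 1e-12)
  expect_error(absolute_strengths(x, y, da, db, 99, p), "out of range")
})

test_that("redecomposition removes the target IMF and keeps the component count", {
  set.seed(3)
  x <- two_tone(256, 8, 64) + 0.1 * rnorm(256)
  p <- tiny_params()
  d <- eemd(x, p$noise_level, p$ensemble_size, p$max_imfs, seed = 1)
  d2 <- redecompose_without(x, d, 1, p)
  expect_identical(nimf(d2), nimf(d))
  # redecomposition reconstructs the remainder x - imf_1 up to the EEMD
  # residual-noise tolerance ~ noise_level / sqrt(ensemble_size)
  tol <- 3 * p$noise_level / sqrt(p$ensemble_size)
  expect_lt(max(abs(reconstruct(d2) - (x - d$imfs[, 1]))) / sd(x), tol)
  # the fast tone's energy no longer dominates the redecomposed IMF 1
  fast_energy <- function(v) {
    sp <- Mod(fft(v))^2
    n <- length(v)
    f <- (0:(n - 1)) / n
    sum(sp[f > 1 / 12 & f < 1 / 5])
  }
  expect_lt(fast_energy(d2$imfs[, 1]), 0.1 * fast_energy(d$imfs[, 1]))
  expect_error(redecompose_without(x, d, 0, p), "outside")
})

test_that("removing an all-zero IMF is a null operation for the coherence profile", {
  set.seed(12)
  x <- two_tone(128, 8, 64)
  p <- tiny_params(seed_mode = "shared")
  d <- eemd(x, p$noise_level, p$ensemble_size, p$max_imfs,
            seed = causaldecomp:::decomp_seed(p, 1L))
  dz <- d
  dz$imfs <- cbind(dz$imfs, imf5 = 0)  # append a zero component
  d2 <- redecompose_without(x, dz, 5, p, slot = 1L)
  expect_equal(d2$imfs[, 1:4], d$imfs, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical series give exactly symmetric causal strengths in shared-seed mode", {
  set.seed(7)
  x <- two_tone(160, 8, 64) + 0.3 * rnorm(160)
  p <- tiny_params(seed_mode = "shared")
  prof <- causal_profile(x, x, p, loo_runs = 0)
  expect_equal(c_ab_of(prof), rep(0.5, length(prof$results)))
  expect_length(prof$flagged, 0)
})

test_that("swapping the arguments exchanges the causal directions exactly (shared seeds)", {
  set.seed(18)
  x <- two_tone(160, 8, 64) + 0.3 * rnorm(160)
  y <- 0.6 * c(x[-1], x[1]) + 0.2 * rnorm(160)
  p <- tiny_params(seed_mode = "shared")
  p1 <- causal_profile(x, y, p, loo_runs = 0)
  p2 <- causal_profile(y, x, p, loo_runs = 0)
  expect_equal(c_ab_of(p1), 1 - c_ab_of(p2), tolerance = 1e-12)
})

test_that("independent white noise yields no flagged interaction", {
  pr <- white_noise_pairs(1, 300, seed = 44)[[1]]
  p <- eemd_params(0.15, ensemble_size = 30, seed = 9)
  prof <- causal_profile(pr$x, pr$y, p)
  expect_length(prof$flagged, 0)
  expect_true(all(abs(c_ab_of(prof) - 0.5) < prof$flag_margin |
                    seq_along(prof$results) %in% prof$flagged == FALSE))
})

test_that("leave-one-out uses every deletion point on short records and max_runs on long ones", {
  set.seed(30)
  x <- two_tone(71, 6, 24) + 0.2 * rnorm(71)
  y <- 0.8 * x + 0.2 * rnorm(71)
  p <- tiny_params(seed = 11)
  loo_short <- leave_one_out(x, y, 1, p)
  expect_length(loo_short$values, 71)
  x2 <- two_tone(400, 8, 64) + 0.2 * rnorm(400)
  y2 <- 0.8 * x2 + 0.2 * rnorm(400)
  p2 <- eemd_params(0.2, ensemble_size = 5L, max_imfs = 3L, seed = 12)
  loo_long <- leave_one_out(x2, y2, 1, p2)
  expect_length(loo_long$values, 100)
  expect_identical(length(unique(loo_long$deletion_points)), 100L)
  # seeded determinism of the whole validation
  loo_again <- leave_one_out(x2, y2, 1, p2)
  expect_identical(loo_long$values, loo_again$values)
  expect_error(leave_one_out(x[1:18], y[1:18], 1, p), "too short")
})

test_that("batched leave-one-out equals index-wise leave-one-out", {
  set.seed(40)
  x <- two_tone(80, 8, 32) + 0.2 * rnorm(80)
  y <- 0.7 * x + 0.3 * rnorm(80)
  p <- tiny_params(seed = 13)
  batch <- causaldecomp:::loo_batch(x, y, c(1L, 2L), p)
  expect_identical(batch[[1]]$values, leave_one_out(x, y, 1, p)$values)
  expect_identical(batch[[2]]$values, leave_one_out(x, y, 2, p)$values)
})

test_that("causal profile tabulates all removable indices with loo summaries", {
  set.seed(50)
  x <- two_tone(128, 8, 64) + 0.2 * rnorm(128)
  y <- 0.8 * x + 0.3 * rnorm(128)
  p <- tiny_params(seed = 14)
  prof <- causal_profile(x, y, p, loo_runs = 10)
  df <- as.data.frame(prof)
  expect_identical(nrow(df), length(prof$results))
  expect_true(all(df$c_ab + df$c_ba - 1 < 1e-12))
  expect_true(all(df$flagged %in% c(TRUE, FALSE)))
  if (length(prof$flagged))
    expect_false(any(is.na(df$loo_median[prof$flagged])))
})
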