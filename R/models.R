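#' Coupled two-species logistic difference system
#'
#' Iterates the chaotic benchmark map
#' `x(t+1) = x(t) [3.8 - 3.8 x(t) - 0.02 y(t)]`,
#' `y(t+1) = y(t) [3.5 - 3.5 y(t) - 0.1 x(t)]`.
#' The coupling is bidirectional but asymmetric: x forces y with coefficient
#' 0.1 while y forces x with only 0.02, so x is the dominant causal driver.
#' The trajectory is deterministic and stays inside the unit interval for
#' the default parameters and initial values.
#'
#' @param length number of points to return (default 400).
#' @param x1,y1 initial values in (0, 1) (defaults 0.2 and 0.4).
#' @return list with `x` and `y`, each a `time_series`.
#' @export
coupled_logistic <- function(length = 400L, x1 = 0.2, y1 = 0.4) {
  if (length < 16L) stop("length must be >= 16", call. = FALSE)
  if (x1 <= 0 || x1 >= 1 || y1 <= 0 || y1 >= 1)
    stop("initial values must lie in (0, 1)", call. = FALSE)
  x <- y <- numeric(length)
  x[1] <- x1; y[1] <- y1
  for (t in seq_len(length - 1L)) {
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t] - 0.02 * y[t])
    y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - 0.1 * x[t])
  }
  if (any(x <= 0 | x >= 1) || any(y <= 0 | y >= 1))
    stop("trajectory escaped (0, 1): parameters or initial values are ",
         "outside the map's stable regime", call. = FALSE)
  list(x = as_time_series(x, "logistic_x"), y = as_time_series(y, "logistic_y"))
}

#' Stochastic autoregressive benchmark pair
#'
#' Generates the linear stochastic system
#' `x(t+1) = 0.95 sqrt(2) x(t) - 0.9025 x(t-1) + w1(t)`,
#' `y(t+1) = 0.5 x(t-1) + w2(t)`,
#' with independent standard-Gaussian innovations. The noise-free skeleton
#' of x has characteristic roots `0.95 exp(+-i pi/4)` and so oscillates with
#' an 8-sample period; y is a pure lagged response to x (x drives y, never
#' the reverse). Initial values are standard normal and a 100-sample burn-in
#' is discarded.
#'
#' @param length number of points returned per series (default 1000).
#' @param seed integer seed for initial values and innovations.
#' @param burn_in samples discarded before recording (default 100).
#' @return list with `x` and `y` `time_series`.
#' @export
ar_stochastic <- function(length = 1000L, seed = NULL, burn_in = 100L) {
  if (length < 20L) stop("length must be >= 20", call. = FALSE)
  gen <- function() {
    n <- length + burn_in
    x <- y <- numeric(n)
    x[1:2] <- rnorm(2); y[1:2] <- rnorm(2)
    w1 <- rnorm(n); w2 <- rnorm(n)
    for (t in 2:(n - 1L)) {
      x[t + 1] <- 0.95 * sqrt(2) * x[t] - 0.9025 * x[t - 1] + w1[t]
      y[t + 1] <- 0.5 * x[t - 1] + w2[t]
    }
    list(x = x[(burn_in + 1L):n], y = y[(burn_in + 1L):n])
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  list(x = as_time_series(out$x, "ar_x"), y = as_time_series(out$y, "ar_y"))
}

#' Lotka-Volterra predator-prey trajectories
#'
#' Integrates `dx/dt = alpha x - beta x y`, `dy/dt = delta x y - gamma y`
#' (x prey, y predator) with classical 4th-order Runge-Kutta via
#' [deSolve::ode()] and samples the trajectory at regular intervals. The
#' defaults (several full population cycles in a 200-time-unit record,
#' sampled once per time unit) put the dominant cycle well inside the
#' resolvable IMF scales.
#'
#' @param duration model time span (default 200).
#' @param dt integration step (default 0.01).
#' @param sample_every sampling interval in model time (default 1).
#' @param alpha,beta,delta,gamma rate constants (defaults 1, 0.05, 0.02,
#'   0.5: prey growth, predation, predator gain, predator death).
#' @param x0,y0 initial abundances (defaults 30 and 10).
#' @return list with `x` (prey) and `y` (predator) `time_series`.
#' @export
lotka_volterra <- function(duration = 200, dt = 0.01, sample_every = 1,
                           alpha = 1, beta = 0.05, delta = 0.02, gamma = 0.5,
                           x0 = 30, y0 = 10) {
  if (any(c(alpha, beta, delta, gamma, x0, y0) <= 0))
    stop("parameters and initial abundances must be positive", call. = FALSE)
  deriv <- function(t, state, parms) {
    with(as.list(c(state, parms)), {
      list(c(dx = alpha * x - beta * x * y,
             dy = delta * x * y - gamma * y))
    })
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(y = c(x = x0, y = y0), times = times, func = deriv,
                      parms = c(alpha = alpha, beta = beta,
                                delta = delta, gamma = gamma),
                      method = "rk4")
  if (any(sol[, "x"] <= 0) || any(sol[, "y"] <= 0))
    stop("abundances became non-positive; use a smaller integration step dt",
         call. = FALSE)
  keep <- abs((times / sample_every) - round(times / sample_every)) < dt / 2
  list(x = as_time_series(sol[keep, "x"], "prey"),
       y = as_time_series(sol[keep, "y"], "predator"))
}

#' Ensembles of uncorrelated white-noise pairs
#'
#' Independent standard-Gaussian pairs for null calibration: no causality
#' should ever be inferred between them.
#'
#' @param n_pairs number of pairs.
#' @param length samples per series (scalar, recycled over pairs, or a
#'   vector of length `n_pairs`).
#' @param seed integer seed.
#' @return list of `n_pairs` elements, each a list with `x` and `y`.
#' @export
white_noise_pairs <- function(n_pairs, length = 200L, seed = NULL) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  lens <- rep_len(as.integer(length), n_pairs)
  gen <- function() lapply(seq_len(n_pairs), function(i)
    list(x = as_time_series(rnorm(lens[i]), paste0("noise_x_", i)),
         y = as_time_series(rnorm(lens[i]), paste0("noise_y_", i))))
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Down-sample a series
#'
#' Keeps every `factor`-th sample starting at the first. Down-sampling by a
#' factor above 2 destroys the within-scale causal dynamics of the benchmark
#' systems, which is the basis of the down-sampling null experiment.
#'
#' @param x numeric series.
#' @param factor integer >= 1 (1 is the identity).
#' @return the down-sampled `time_series`.
#' @export
downsample <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  v <- ts_values(x)[seq(1L, length(x), by = factor)]
  if (length(v) < 16L)
    stop("down-sampled series would have fewer than 16 points", call. = FALSE)
  as_time_series(v, paste0(series_label(x), "_ds", factor))
}

#' Temporally shift one series of a pair
#'
#' Shifts `b` by `k` samples relative to `a` (positive k lags b, negative k
#' advances it). By default both series are trimmed to the overlapping
#' support, shortening them by `|k|`; with `circular = TRUE` the shifted
#' series wraps around and lengths are preserved.
#'
#' @param a,b equal-length numeric series.
#' @param k integer shift, `|k| <= length/4`.
#' @param circular wrap instead of trimming (default FALSE).
#' @return list with shifted/trimmed `a` and `b`.
#' @export
time_shift <- function(a, b, k, circular = FALSE) {
  av <- ts_values(a); bv <- ts_values(b)
  L <- length(av)
  if (length(bv) != L) stop("series lengths differ", call. = FALSE)
  k <- as.integer(k)
  if (abs(k) > L / 4) stop("|k| must be at most length/4", call. = FALSE)
  if (k == 0) return(list(a = as_time_series(av, series_label(a)),
                          b = as_time_series(bv, series_label(b))))
  if (circular) {
    idx <- ((seq_len(L) - 1L - k) %% L) + 1L
    return(list(a = as_time_series(av, series_label(a)),
                b = as_time_series(bv[idx], paste0(series_label(b), "_shift", k))))
  }
  if (L - abs(k) < 16L)
    stop("overlap after shifting would have fewer than 16 points", call. = FALSE)
  if (k > 0) {
    av2 <- av[(k + 1L):L]; bv2 <- bv[1L:(L - k)]
  } else {
    av2 <- av[1L:(L + k)]; bv2 <- bv[(-k + 1L):L]
  }
  list(a = as_time_series(av2, series_label(a)),
       b = as_time_series(bv2, paste0(series_label(b), "_shift", k)))
}
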