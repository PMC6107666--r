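#' Validate a time series input
#'
#' Inputs to the decomposition functions are uniformly sampled real-valued
#' series. This checks finiteness and a minimum length (sifting on very short
#' records is meaningless) and attaches an optional label.
#'
#' @param x numeric vector, all values finite.
#' @param label free-text identifier carried through outputs.
#' @param min_length minimum admissible length (default 16).
#' @return `x` (numeric) with class `"time_series"` and a `label` attribute.
#' @export
as_time_series <- function(x, label = deparse(substitute(x)), min_length = 16L) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("time series contains missing or non-finite values", call. = FALSE)
  if (length(x) < min_length)
    stop("time series has length ", length(x), "; at least ", min_length,
         " samples are required for sifting", call. = FALSE)
  structure(x, label = as.character(label)[1L], class = "time_series")
}

# strip class/attributes for internal numeric work
ts_values <- function(x) as.numeric(unclass(x))

series_label <- function(x, fallback = "series") {
  lb <- attr(x, "label")
  if (is.null(lb)) fallback else lb
}

#' Default number of IMFs for a record of length L
#'
#' EMD acts as a dyadic filter bank on broadband signals, yielding about
#' log2(L) modes; one is reserved for the residual trend, hence
#' `floor(log2(L)) - 1`.
#'
#' @param n record length.
#' @return integer number of IMFs (at least 1).
#' @export
default_max_imfs <- function(n) max(1L, as.integer(floor(log2(n)) - 1L))

new_imf_set <- function(imfs, residual, noise_level, ensemble_size,
                        source_std, label = "series") {
  imfs <- as.matrix(imfs)
  k <- ncol(imfs)
  if (k > 0) colnames(imfs) <- paste0("imf", seq_len(k))
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 noise_level = noise_level, ensemble_size = ensemble_size,
                 source_std = source_std, label = label),
            class = "imf_set")
}

#' Assemble an IMF set from explicit components
#'
#' Mainly for constructing diagnostic inputs by hand; [emd()] and [eemd()]
#' are the usual producers.
#'
#' @param imfs numeric matrix, one column per IMF (rows are time).
#' @param residual numeric trend component, same length as the columns.
#' @param noise_level,ensemble_size EEMD metadata (0 and 1 for plain EMD).
#' @param label identifier.
#' @return an object of class `imf_set`.
#' @export
imf_set <- function(imfs, residual = numeric(nrow(as.matrix(imfs))),
                    noise_level = 0, ensemble_size = 1L, label = "series") {
  imfs <- as.matrix(imfs)
  if (length(residual) != nrow(imfs))
    stop("residual length must match the IMF rows", call. = FALSE)
  src <- rowSums(imfs) + residual
  new_imf_set(imfs, residual, noise_level, ensemble_size, sd(src), label)
}

#' @export
print.imf_set <- function(x, ...) {
  cat("IMF set for '", x$label, "': ", ncol(x$imfs), " IMFs + residual, ",
      length(x$residual), " samples", sep = "")
  if (x$noise_level > 0)
    cat(" (EEMD, r = ", x$noise_level, ", N = ", x$ensemble_size, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param d an `imf_set`.
#' @return integer count (residual excluded).
#' @export
nimf <- function(d) ncol(d$imfs)

#' Reconstruct the source series from a decomposition
#' @param d an `imf_set`.
#' @return numeric vector: row sums of the IMFs plus the residual.
#' @export
reconstruct <- function(d) {
  if (ncol(d$imfs) == 0) return(d$residual)
  rowSums(d$imfs) + d$residual
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions by sifting: upper and
#' lower envelopes are natural cubic splines through the local maxima and
#' minima (the two extrema nearest each end are mirrored across the record
#' boundary), and the mean envelope is subtracted a fixed number of times per
#' IMF. Extraction stops when the working residual has fewer than 3 local
#' extrema or `max_imfs` is reached; what remains is the residual trend.
#' Plain EMD is exactly additive: the IMFs plus residual reproduce the input
#' to machine precision.
#'
#' @param x numeric series (checked with [as_time_series()] rules).
#' @param max_imfs maximum number of IMFs; default [default_max_imfs()].
#' @param sift_iterations fixed sifting count per IMF (default 10).
#' @return an `imf_set` with `noise_level = 0`.
#' @export
#' @examples
#' x <- sin(2 * pi * (1:256) / 16)
#' d <- emd(x)
#' max(abs(reconstruct(d) - x)) < 1e-9
emd <- function(x, max_imfs = NULL, sift_iterations = 10L) {
  lb <- series_label(x); x <- ts_values(as_time_series(x, label = lb))
  if (is.null(max_imfs)) max_imfs <- default_max_imfs(length(x))
  max_imfs <- as.integer(max_imfs)
  if (max_imfs < 1L) stop("max_imfs must be >= 1", call. = FALSE)
  out <- .emd_cpp(x, max_imfs, as.integer(sift_iterations), FALSE)
  new_imf_set(out$imfs, out$residual, 0, 1L, sd(x), lb)
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Averages EMD over an ensemble of noise-added copies of the signal: each
#' trial decomposes `x + noise_level * sd(x) * w` with `w` standard Gaussian
#' white noise, forced to exactly `max_imfs` IMFs so that per-index averaging
#' is well defined; the returned IMFs and residual are the per-sample ensemble
#' means. The added noise provides a uniform dyadic reference frame that
#' stabilises which time scale each IMF carries.
#'
#' @inheritParams emd
#' @param noise_level added-noise amplitude as a fraction of `sd(x)`,
#'   in \[0, 1\]. 0 collapses the ensemble to plain [emd()].
#' @param ensemble_size number of trials N (default 1000).
#' @param seed optional integer fixing the white-noise stream; the caller's
#'   RNG state is left untouched.
#' @return an `imf_set` carrying `noise_level` and `ensemble_size`.
#' @export
eemd <- function(x, noise_level, ensemble_size = 1000L, max_imfs = NULL,
                 sift_iterations = 10L, seed = NULL) {
  lb <- series_label(x); x <- ts_values(as_time_series(x, label = lb))
  if (!is.numeric(noise_level) || noise_level < 0 || noise_level > 1)
    stop("noise_level must lie in [0, 1]", call. = FALSE)
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1", call. = FALSE)
  if (noise_level == 0) return(emd(x, max_imfs, sift_iterations))
  if (is.null(max_imfs)) max_imfs <- default_max_imfs(length(x))
  run <- function() .eemd_cpp(x, noise_level * sd(x), as.integer(ensemble_size),
                              as.integer(max_imfs), as.integer(sift_iterations))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  new_imf_set(out$imfs, out$residual, noise_level, as.integer(ensemble_size),
              sd(x), lb)
}

# evaluate expr under a fixed RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% 2147483629)
}

#' Count local extrema of a series
#'
#' Interior maxima plus minima; a flat extremum counts once (at its
#' midpoint). Used for the fine-to-coarse ordering diagnostic of an IMF set.
#'
#' @param x numeric vector.
#' @return integer count.
#' @export
count_extrema <- function(x) {
  e <- .extrema_cpp(as.numeric(x))
  length(e$maxima) + length(e$minima)
}
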