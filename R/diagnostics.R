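#' Nonorthogonal leakage of a decomposition
#'
#' Index of orthogonality of the components (IMFs and residual): the summed
#' cross-products of all distinct component pairs, normalised by the total
#' energy of the reconstructed signal, in absolute value. Computed via the
#' identity `sum(X^2) = sum_j sum(c_j^2) + cross-terms` with
#' `X = sum of components`, so a perfectly orthogonal set returns 0 and a
#' duplicated component contributes half of the total energy.
#'
#' @param d an `imf_set`.
#' @return a non-negative scalar; 0 (with a warning) when there are fewer
#'   than 2 components.
#' @export
nonorthogonal_leakage <- function(d) {
  stopifnot(inherits(d, "imf_set"))
  if (nimf(d) < 2L) {
    warning("fewer than 2 IMFs: leakage is 0 by convention")
    return(0)
  }
  comps <- cbind(d$imfs, residual = d$residual)
  x <- rowSums(comps)
  total <- sum(x^2)
  if (total == 0) return(0)
  abs(total - sum(comps^2)) / total
}

#' RMS of pairwise IMF correlations
#'
#' Pearson correlation for every unordered pair of IMFs (the residual trend
#' is not an oscillatory mode and is excluded), summarised as the root of the
#' mean of their squares. Low values mean the modes carry separated time
#' scales. A zero-variance IMF has no defined correlation; its pairs
#' contribute 0.
#'
#' @param d an `imf_set` with at least 2 IMFs.
#' @return a value in \[0, 1\].
#' @export
rms_pairwise_correlation <- function(d) {
  stopifnot(inherits(d, "imf_set"))
  k <- nimf(d)
  if (k < 2L) stop("need at least 2 IMFs for pairwise correlations", call. = FALSE)
  sds <- apply(d$imfs, 2, sd)
  r2 <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0 else cor(d$imfs[, i], d$imfs[, j])
      r2 <- c(r2, r^2)
    }
  }
  sqrt(mean(r2))
}

#' Select the EEMD noise level for a pair of series
#'
#' Scans a grid of candidate noise amplitudes r (fractions of each series'
#' standard deviation), decomposing both series by [eemd()] at each
#' candidate, and records the worse (maximum) nonorthogonal leakage and RMS
#' pairwise IMF correlation across the two series. The chosen r minimises
#' the RMS correlation among candidates whose leakage stays under
#' `leakage_threshold`; ties go to the smallest r (least perturbation). If
#' no candidate meets the leakage threshold the r with minimal leakage is
#' returned with a prominent warning — selection is advisory, never fatal.
#'
#' @param a,b numeric series.
#' @param grid strictly increasing candidate r values in \[0.05, 1\]
#'   (default `seq(0.05, 1, by = 0.05)`, 20 candidates).
#' @param leakage_threshold,rms_threshold acceptance guides (default 0.05
#'   each).
#' @param ensemble_size,max_imfs,sift_iterations passed to [eemd()].
#' @param seed integer; sub-seeds for every decomposition are derived from
#'   it, so the scan is deterministic.
#' @return an object of class `noise_selection`: list with `table` (one row
#'   per candidate: r, leakage per series, RMS correlation per series,
#'   chosen flag), `chosen_r`, `met_thresholds`, and the thresholds used.
#' @export
select_noise_level <- function(a, b, grid = seq(0.05, 1, by = 0.05),
                               leakage_threshold = 0.05, rms_threshold = 0.05,
                               ensemble_size = 1000L, max_imfs = NULL,
                               sift_iterations = 10L, seed = NULL) {
  if (any(diff(grid) <= 0) || min(grid) < 0.05 - 1e-12 || max(grid) > 1 + 1e-12)
    stop("grid must be strictly increasing within [0.05, 1]", call. = FALSE)
  n <- length(grid)
  tab <- data.frame(r = grid, leakage_a = NA_real_, leakage_b = NA_real_,
                    rms_corr_a = NA_real_, rms_corr_b = NA_real_,
                    chosen = FALSE)
  for (i in seq_len(n)) {
    da <- eemd(a, grid[i], ensemble_size, max_imfs, sift_iterations,
               seed = derive_seed(seed, 2L * i))
    db <- eemd(b, grid[i], ensemble_size, max_imfs, sift_iterations,
               seed = derive_seed(seed, 2L * i + 1L))
    tab$leakage_a[i] <- nonorthogonal_leakage(da)
    tab$leakage_b[i] <- nonorthogonal_leakage(db)
    tab$rms_corr_a[i] <- rms_pairwise_correlation(da)
    tab$rms_corr_b[i] <- rms_pairwise_correlation(db)
  }
  leak <- pmax(tab$leakage_a, tab$leakage_b)
  rmsc <- pmax(tab$rms_corr_a, tab$rms_corr_b)
  ok <- leak < leakage_threshold
  if (any(ok)) {
    idx <- which(ok)[which.min(rmsc[ok])]   # ties resolve to the smallest r
  } else {
    idx <- which.min(leak)
    warning("no candidate noise level keeps the nonorthogonal leakage under ",
            leakage_threshold, "; returning the least-leakage candidate r = ",
            grid[idx], ". Treat the selection as advisory.", call. = FALSE)
  }
  tab$chosen[idx] <- TRUE
  structure(list(table = tab, grid = grid, chosen_r = grid[idx],
                 leakage = leak, rms_corr = rmsc,
                 leakage_threshold = leakage_threshold,
                 rms_threshold = rms_threshold,
                 met_thresholds = ok[idx] && rmsc[idx] < rms_threshold),
            class = "noise_selection")
}

#' @export
print.noise_selection <- function(x, ...) {
  cat("EEMD noise-level selection over", length(x$grid), "candidates\n")
  cat("chosen r =", x$chosen_r,
      if (x$met_thresholds) "(leakage and RMS-correlation guides both met)\n"
      else "(thresholds not fully met; advisory choice)\n")
  invisible(x)
}

#' Export the noise-selection table
#' @param x a `noise_selection`.
#' @param ... unused.
#' @return the per-candidate diagnostics data frame.
#' @export
as.data.frame.noise_selection <- function(x, ...) x$table
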