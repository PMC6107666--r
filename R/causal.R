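#' Bundle EEMD parameters for a causal-decomposition run
#'
#' The same noise level r, ensemble size N and IMF count must be used for
#' every decomposition and redecomposition inside one analysis; this object
#' carries them, together with the seeding policy.
#'
#' @param noise_level EEMD added-noise amplitude r (fraction of the decomposed
#'   series' standard deviation), in \[0, 1\].
#' @param ensemble_size ensemble trials N (default 1000).
#' @param max_imfs IMF count per decomposition; NULL selects
#'   [default_max_imfs()] from the series length.
#' @param sift_iterations fixed sifting count per IMF.
#' @param seed integer base seed; every decomposition in the analysis draws
#'   its noise from a sub-stream derived deterministically from it.
#' @param seed_mode `"independent"` (default): the two series and every
#'   redecomposition use independently derived noise streams.
#'   `"shared"`: all decompositions reuse one stream, which makes the
#'   procedure exactly symmetric under exchanging identical series — useful
#'   for strict-reproducibility checks.
#' @param distance_scope `"full_profile"` (default): the coherence-change
#'   distance sums over all paired IMF indices j = 1..m while a single index
#'   i is removed; `"single_pair"` restricts the sum to j = i.
#' @param edge_exclude edge fraction excluded from coherence integration
#'   (default 0, full record).
#' @return an object of class `eemd_params`.
#' @export
eemd_params <- function(noise_level, ensemble_size = 1000L, max_imfs = NULL,
                        sift_iterations = 10L, seed = NULL,
                        seed_mode = c("independent", "shared"),
                        distance_scope = c("full_profile", "single_pair"),
                        edge_exclude = 0) {
  if (!is.numeric(noise_level) || noise_level < 0 || noise_level > 1)
    stop("noise_level must lie in [0, 1]", call. = FALSE)
  structure(list(noise_level = noise_level,
                 ensemble_size = as.integer(ensemble_size),
                 max_imfs = if (is.null(max_imfs)) NULL else as.integer(max_imfs),
                 sift_iterations = as.integer(sift_iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 seed_mode = match.arg(seed_mode),
                 distance_scope = match.arg(distance_scope),
                 edge_exclude = edge_exclude),
            class = "eemd_params")
}

# seed for one decomposition slot under the params' seeding policy;
# slots: 1 = series a, 2 = series b, 100+i / 200+i = redecompositions
decomp_seed <- function(p, slot) {
  if (is.null(p$seed)) return(NULL)
  if (p$seed_mode == "shared") return(derive_seed(p$seed, 1L))
  derive_seed(p$seed, slot)
}

decompose_with <- function(x, p, slot) {
  eemd(x, p$noise_level, p$ensemble_size, p$max_imfs, p$sift_iterations,
       seed = decomp_seed(p, slot))
}

#' Remove one IMF and redecompose the remainder
#'
#' The causal probe: IMF i is subtracted from the original series and the
#' remainder is re-run through [eemd()] with the same noise level, ensemble
#' size and IMF count, so the redecomposed set is comparable
#' component-by-component with the original. If the removed mode's phase
#' dynamics originated in the partner series, the redistribution that fills
#' the emptied scale comes from the series' own intrinsic dynamics and phase
#' coherence with the partner collapses at that scale.
#'
#' @param x the original series the decomposition `d` came from.
#' @param d an `imf_set` for `x`.
#' @param i index of the IMF to remove (1..`nimf(d)`).
#' @param params an [eemd_params()] object.
#' @param slot internal seeding slot; leave default unless orchestrating
#'   several redecompositions.
#' @return an `imf_set` of the remainder with the same component count as
#'   `d`.
#' @export
redecompose_without <- function(x, d, i, params, slot = 100L + i) {
  stopifnot(inherits(d, "imf_set"), inherits(params, "eemd_params"))
  i <- as.integer(i)
  if (i < 1L || i > nimf(d))
    stop("IMF index ", i, " is outside 1..", nimf(d), call. = FALSE)
  remainder <- ts_values(x) - d$imfs[, i]
  p <- params
  p$max_imfs <- nimf(d)   # keep the component count comparable
  eemd(remainder, p$noise_level, p$ensemble_size, p$max_imfs,
       p$sift_iterations, seed = decomp_seed(p, slot))
}

# variance weights W_j over paired IMFs: product of the per-series IMF
# variances, normalised to sum to 1
variance_weights <- function(da, db, m) {
  v1 <- apply(da$imfs[, seq_len(m), drop = FALSE], 2, var)
  v2 <- apply(db$imfs[, seq_len(m), drop = FALSE], 2, var)
  w <- v1 * v2
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate weights: all paired IMF variance products are zero",
         call. = FALSE)
  w / tot
}

# variance-weighted Euclidean distance between two coherence profiles
coh_distance <- function(base, after, w, scope, i) {
  diff2 <- (base - after)^2
  if (scope == "single_pair") {
    sqrt(diff2[i])               # single-index probe: weight is immaterial
  } else {
    sqrt(sum(w * diff2))
  }
}

#' Absolute causal strengths for one removal index
#'
#' Computes the baseline coherence profile of the two decompositions, then
#' removes IMF `i` from each series in turn, redecomposes, and measures the
#' variance-weighted Euclidean distance between the baseline profile and the
#' profile obtained against the redecomposed partner:
#' `D(a -> b)` uses the redecomposition of `b` (removing the mode from the
#' *target*), `D(b -> a)` the redecomposition of `a`. Weights are the
#' normalised products of the original paired-IMF variances.
#'
#' @param a,b the two series.
#' @param da,db their `imf_set` decompositions (from [eemd()] with the same
#'   parameters as `params`).
#' @param i removal index, valid for both sets.
#' @param params an [eemd_params()] object.
#' @return an object of class `causal_result` with `d_ab`, `d_ba`, the
#'   weights, the baseline and after-removal profiles; the relative
#'   strengths `c_ab`/`c_ba` are NA until [relative_strengths()] is applied.
#' @export
absolute_strengths <- function(a, b, da, db, i, params) {
  stopifnot(inherits(da, "imf_set"), inherits(db, "imf_set"),
            inherits(params, "eemd_params"))
  m <- min(nimf(da), nimf(db))
  i <- as.integer(i)
  if (i < 1L || i > m) stop("removal index out of range", call. = FALSE)
  base <- coherence_profile(da, db, edge_exclude = params$edge_exclude)
  w <- variance_weights(da, db, m)
  dbp <- redecompose_without(b, db, i, params, slot = 200L + i)
  dap <- redecompose_without(a, da, i, params, slot = 100L + i)
  after_b <- coherence_profile(da, dbp, edge_exclude = params$edge_exclude)
  after_a <- coherence_profile(dap, db, edge_exclude = params$edge_exclude)
  d_ab <- coh_distance(base$values[seq_len(m)], after_b$values[seq_len(m)],
                       w, params$distance_scope, i)
  d_ba <- coh_distance(base$values[seq_len(m)], after_a$values[seq_len(m)],
                       w, params$distance_scope, i)
  structure(list(removed_index = i, d_ab = d_ab, d_ba = d_ba,
                 c_ab = NA_real_, c_ba = NA_real_, weights = w,
                 baseline = base, profile_after_removal_from_b = after_b,
                 profile_after_removal_from_a = after_a),
            class = "causal_result")
}

#' Relative causal strengths from absolute distances
#'
#' `c_ab = d_ab / (d_ab + d_ba)` and symmetrically for `c_ba`, so the two
#' always sum to 1; 0.5 means no differential causality. When both absolute
#' distances are below 0.05 (no causal change of phase coherence under
#' redecomposition) the ratio is formed from `d + 1` instead, which pins the
#' result near 0.5 rather than amplifying numerical noise.
#'
#' @param r a `causal_result` from [absolute_strengths()], or a list with
#'   `d_ab`/`d_ba`.
#' @return `r` with `c_ab` and `c_ba` populated.
#' @export
relative_strengths <- function(r) {
  d_ab <- r$d_ab; d_ba <- r$d_ba
  if (is.na(d_ab) || is.na(d_ba))
    stop("absolute strengths must be computed first", call. = FALSE)
  if (d_ab < 0.05 && d_ba < 0.05) {
    d_ab <- d_ab + 1; d_ba <- d_ba + 1
  }
  r$c_ab <- d_ab / (d_ab + d_ba)
  r$c_ba <- d_ba / (d_ab + d_ba)
  r
}

#' @export
print.causal_result <- function(x, digits = 3, ...) {
  cat("causal result (IMF ", x$removed_index, " removed): D(a->b) = ",
      round(x$d_ab, digits), ", D(b->a) = ", round(x$d_ba, digits), sep = "")
  if (!is.na(x$c_ab))
    cat(", C(a->b) = ", round(x$c_ab, digits),
        ", C(b->a) = ", round(x$c_ba, digits), sep = "")
  cat("\n")
  invisible(x)
}

#' Leave-one-out validation of a causal strength
#'
#' Deletes a single time point (the same index from both series, preserving
#' alignment), recomputes the relative causal strength for removal index
#' `i` on the shortened pair, and repeats over deletion points to obtain an
#' empirical distribution whose median summarises the causal strength. All
#' deletion points are used when the record is shorter than 100 samples;
#' otherwise `max_runs` points are drawn uniformly without replacement under
#' the params' seed.
#'
#' @param a,b the two series.
#' @param i removal index.
#' @param params an [eemd_params()] object.
#' @param max_runs cap on the number of deletion tests (default 100).
#' @return an object of class `loo_result`: list with `values` (c_ab per
#'   run), `median`, `q025`, `q975`, `deletion_points`.
#' @export
leave_one_out <- function(a, b, i, params, max_runs = 100L) {
  loo_batch(a, b, i, params, max_runs)[[1]]
}

# leave-one-out over several removal indices at once, sharing the
# decompositions of each shortened pair; identical results to index-wise
# calls of leave_one_out() because decomposition seeds do not depend on the
# removal index
loo_batch <- function(a, b, indices, params, max_runs = 100L) {
  av <- ts_values(a); bv <- ts_values(b)
  L <- length(av)
  if (length(bv) != L) stop("series lengths differ", call. = FALSE)
  if (L - 1L <= 17L)
    stop("series too short for leave-one-out (needs > 17 points after deletion)",
         call. = FALSE)
  pts <- if (L < 100L) seq_len(L) else {
    draw <- function() sort(sample.int(L, max_runs))
    if (is.null(params$seed)) draw()
    else with_seed(derive_seed(params$seed, 999L), draw())
  }
  vals <- matrix(NA_real_, nrow = length(pts), ncol = length(indices))
  for (run in seq_along(pts)) {
    keep <- -pts[run]
    p <- params
    p$seed <- derive_seed(params$seed, 1000L + run)
    a1 <- av[keep]; b1 <- bv[keep]
    da <- decompose_with(a1, p, 1L)
    db <- decompose_with(b1, p, 2L)
    for (k in seq_along(indices))
      vals[run, k] <-
        relative_strengths(absolute_strengths(a1, b1, da, db, indices[k], p))$c_ab
  }
  lapply(seq_along(indices), function(k) {
    v <- vals[, k]
    structure(list(values = v, median = median(v),
                   q025 = unname(quantile(v, 0.025)),
                   q975 = unname(quantile(v, 0.975)),
                   deletion_points = pts),
              class = "loo_result")
  })
}

#' @export
print.loo_result <- function(x, digits = 3, ...) {
  cat("leave-one-out causal strength over ", length(x$values), " deletions: ",
      "median ", round(x$median, digits), " [",
      round(x$q025, digits), ", ", round(x$q975, digits), "]\n", sep = "")
  invisible(x)
}

#' Per-IMF causal profile of a pair of series
#'
#' The full causal-decomposition analysis: both series are decomposed once
#' by [eemd()]; for every removable IMF index the remove-and-redecompose
#' probe yields absolute distances and relative strengths; candidate indices
#' whose point estimate departs from 0.5 by at least `flag_margin` are
#' validated by [leave_one_out()], and an index is flagged as a significant
#' causal interaction when the central 95% of its leave-one-out distribution
#' excludes 0.5 and the distribution median also clears the margin.
#'
#' @param a,b the two series (equal length).
#' @param params an [eemd_params()] object.
#' @param flag_margin minimal departure of the relative strength from 0.5
#'   for an index to be considered causal (default 0.1).
#' @param loo_runs deletion tests per candidate index (default 100); 0
#'   disables leave-one-out, in which case flagging falls back to the point
#'   estimate alone.
#' @return an object of class `causal_profile`: list with `results` (one
#'   `causal_result` per index), `flagged` (integer indices), `loo` (per
#'   index, a `loo_result` or NULL), the decompositions `da`/`db`, and
#'   `params`.
#' @export
causal_profile <- function(a, b, params, flag_margin = 0.1, loo_runs = 100L) {
  av <- ts_values(as_time_series(a, label = series_label(a, "a")))
  bv <- ts_values(as_time_series(b, label = series_label(b, "b")))
  if (length(av) != length(bv)) stop("series lengths differ", call. = FALSE)
  stopifnot(inherits(params, "eemd_params"))
  da <- decompose_with(av, params, 1L)
  db <- decompose_with(bv, params, 2L)
  m <- min(nimf(da), nimf(db))
  results <- lapply(seq_len(m), function(i)
    relative_strengths(absolute_strengths(av, bv, da, db, i, params)))
  c_ab <- vapply(results, `[[`, numeric(1), "c_ab")
  candidates <- which(abs(c_ab - 0.5) >= flag_margin)
  loo <- vector("list", m)
  flagged <- integer(0)
  if (length(candidates) && loo_runs > 0L) {
    loo[candidates] <- loo_batch(av, bv, candidates, params,
                                 max_runs = loo_runs)
    for (i in candidates) {
      excl <- loo[[i]]$q025 > 0.5 || loo[[i]]$q975 < 0.5
      if (excl && abs(loo[[i]]$median - 0.5) >= flag_margin)
        flagged <- c(flagged, i)
    }
  } else {
    flagged <- candidates
  }
  structure(list(results = results, flagged = flagged, loo = loo,
                 da = da, db = db, params = params, flag_margin = flag_margin,
                 labels = c(series_label(a, "a"), series_label(b, "b"))),
            class = "causal_profile")
}

#' @export
print.causal_profile <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  cat("causal decomposition of '", x$labels[1], "' vs '", x$labels[2],
      "' (r = ", x$params$noise_level, ", N = ", x$params$ensemble_size,
      ")\n", sep = "")
  print(cbind(df[1], round(df[2:5], digits), df["flagged"]), row.names = FALSE)
  if (length(x$flagged))
    cat("flagged causal interaction at IMF", paste(x$flagged, collapse = ", "), "\n")
  else cat("no causal interaction flagged\n")
  invisible(x)
}

#' Tabulate a causal profile
#' @param x a `causal_profile`.
#' @param ... unused.
#' @return data frame with one row per removable IMF index: the absolute
#'   distances, relative strengths, leave-one-out summaries and flag.
#' @export
as.data.frame.causal_profile <- function(x, ...) {
  m <- length(x$results)
  loo_stat <- function(i, f) if (is.null(x$loo[[i]])) NA_real_ else x$loo[[i]][[f]]
  data.frame(
    imf_index = seq_len(m),
    d_ab = vapply(x$results, `[[`, numeric(1), "d_ab"),
    d_ba = vapply(x$results, `[[`, numeric(1), "d_ba"),
    c_ab = vapply(x$results, `[[`, numeric(1), "c_ab"),
    c_ba = vapply(x$results, `[[`, numeric(1), "c_ba"),
    loo_median = vapply(seq_len(m), loo_stat, numeric(1), f = "median"),
    loo_q025 = vapply(seq_len(m), loo_stat, numeric(1), f = "q025"),
    loo_q975 = vapply(seq_len(m), loo_stat, numeric(1), f = "q975"),
    flagged = seq_len(m) %in% x$flagged
  )
}
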