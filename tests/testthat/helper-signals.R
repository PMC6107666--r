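# deterministic test signals -------------------------------------------------

tone <- function(n, period, amp = 1, phase = 0) {
  amp * cos(2 * pi * (0:(n - 1)) / period + phase)
}

# two well-separated tones (periods 8 and 64 by default)
two_tone <- function(n = 512, p1 = 8, p2 = 64, a1 = 1, a2 = 1) {
  tone(n, p1, a1) + tone(n, p2, a2)
}

c_ab_of <- function(profile) {
  vapply(profile$results, `[[`, numeric(1), "c_ab")
}

# independent R reference for one sifting iteration: strict interior extrema,
# the two extrema nearest each end mirrored across the record boundary,
# natural cubic spline envelopes via stats::spline
reference_sift_once <- function(x) {
  n <- length(x)
  is_max <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  is_min <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  env <- function(idx) {
    pos <- idx - 1  # 0-based sample positions
    k <- min(2, length(pos))
    left <- rev(-pos[seq_len(k)])
    left <- left[left < pos[1]]
    right <- 2 * (n - 1) - pos[length(pos) + 1 - seq_len(k)]
    right <- right[right > pos[length(pos)]]
    xs <- c(left, pos, right)
    ys <- x[c(idx[match(abs(left), pos)], idx,
              idx[match(2 * (n - 1) - right, pos)])]
    stats::spline(xs, ys, xout = 0:(n - 1), method = "natural")$y
  }
  x - 0.5 * (env(is_max) + env(is_min))
}
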