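#' Analytic signal of an IMF
#'
#' Computes the discrete analytic signal by the frequency-domain construction
#' (negative frequencies zeroed, full record, no tapering) and derives the
#' instantaneous amplitude `A(t) = sqrt(S^2 + S_H^2)`, the instantaneous
#' phase `atan2(S_H, S)` (four-quadrant, so the phase is usable over full
#' cycles), and the instantaneous frequency as the discrete derivative of the
#' unwrapped phase, in radians per sample. At interior points
#' `A(t) * cos(phase(t))` reconstructs the IMF.
#'
#' @param imf numeric vector, one component of an `imf_set`, length >= 16.
#' @return an object of class `analytic_imf`: list with `signal`,
#'   `amplitude`, `phase`, `frequency`, and a `degenerate` flag (TRUE for an
#'   all-zero input, whose phase is 0 by convention).
#' @export
#' @examples
#' a <- analytic(cos(2 * pi * (0:255) / 32))
#' range(a$amplitude[20:230])     # ~1
analytic <- function(imf) {
  s <- as.numeric(imf)
  if (length(s) < 16L)
    stop("analytic signal needs at least 16 samples", call. = FALSE)
  if (anyNA(s) || any(!is.finite(s)))
    stop("IMF contains non-finite values", call. = FALSE)
  if (all(s == 0)) {
    n <- length(s)
    return(structure(list(signal = s, amplitude = numeric(n),
                          phase = numeric(n), frequency = numeric(n),
                          degenerate = TRUE), class = "analytic_imf"))
  }
  z <- analytic_signal(s)
  amplitude <- Mod(z)
  phase <- atan2(Im(z), Re(z))
  frequency <- pracma::gradient(as.numeric(signal::unwrap(phase)))
  structure(list(signal = s, amplitude = amplitude, phase = phase,
                 frequency = frequency, degenerate = FALSE),
            class = "analytic_imf")
}

# frequency-domain analytic signal: double positive frequencies, zero
# negative ones, keep DC (and Nyquist for even n) unscaled
analytic_signal <- function(s) {
  n <- length(s)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(s) * h, inverse = TRUE) / n
}

#' @export
print.analytic_imf <- function(x, ...) {
  cat("analytic IMF: ", length(x$signal), " samples",
      if (x$degenerate) " (degenerate: all-zero input)", "\n", sep = "")
  invisible(x)
}
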