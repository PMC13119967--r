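#' Zero-phase IIR filtering with reflection padding
#'
#' Applies an IIR filter forward and backward so the net result has zero
#' phase lag (event timing must not be biased by filter delay). The input is
#' extended at both ends by odd reflection about the end points before
#' filtering, and the extension is discarded afterwards, so start-up
#' transients decay inside the padding rather than inside the data.
#'
#' @param b,a numerator / denominator filter coefficients.
#' @param x numeric vector to filter.
#' @param pad padding length in samples; defaults to six time constants of a
#'   generic low-pass, capped at `length(x) - 1`.
#' @return filtered vector, same length as `x`.
#' @keywords internal
zero_phase_filter <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n < 2L) return(x)
  nflt <- max(length(a), length(b))
  if (is.null(pad)) pad <- 10L * nflt
  pad <- min(n - 1L, as.integer(pad))
  # removing the first value keeps the reflected extension near zero, so the
  # zero-state start-up transient is negligible even for long time constants
  x0 <- x[1L]
  xs <- x - x0
  xp <- c(2 * xs[1L] - xs[(pad + 1L):2L], xs, 2 * xs[n] - xs[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  g <- (sum(b) / sum(a))^2          # squared DC gain of the cascade
  y[(pad + 1L):(pad + n)] + x0 * g
}

#' Linear-phase FIR filtering with group-delay compensation
#'
#' Single forward pass of a linear-phase (symmetric) FIR filter; the output
#' is shifted back by the group delay so it is time-aligned with the input.
#' The filter order must be even so the group delay is an integer number of
#' samples. Ends are odd-reflected so edge samples see plausible context.
#'
#' @param b FIR coefficients (length = order + 1, order even).
#' @param x numeric vector.
#' @return filtered, delay-compensated vector of `length(x)`.
#' @keywords internal
fir_filter_linphase <- function(b, x) {
  n <- length(x)
  nb <- length(b)
  if (nb %% 2L == 0L)
    stop("FIR length must be odd (even order) for integer group delay")
  gd <- (nb - 1L) %/% 2L
  pad <- min(n - 1L, nb)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(b, 1, xp))
  y[(pad + gd + 1L):(pad + gd + n)]
}
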