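# Surface-EMG processing: spike clipping, envelope extraction, movement
# windowing, time normalization to 101 cycle nodes and per-participant
# amplitude normalization.

#' Clip transient high-amplitude spikes
#'
#' Samples whose magnitude exceeds `k_sd` robust standard deviations of the
#' channel (robust SD = 1.4826 x median absolute deviation) are replaced by
#' the median rectified amplitude of the surrounding `window_ms` window,
#' with the sign of the original sample preserved. All other samples are
#' untouched. An all-zero channel (degenerate threshold) is returned
#' unchanged.
#'
#' @param x raw EMG vector.
#' @param rate sampling rate, samples/s.
#' @param k_sd threshold in robust SD units (default 5).
#' @param window_ms half-window for the local replacement median, default 20.
#' @return cleaned vector, same length.
#' @export
clip_spikes <- function(x, rate, k_sd = 5, window_ms = 20) {
  x <- as.numeric(x)
  rsd <- 1.4826 * stats::mad(x, constant = 1)
  if (rsd <= 0) return(x)
  thr <- k_sd * rsd
  bad <- which(abs(x) > thr)
  if (length(bad) == 0L) return(x)
  hw <- max(1L, as.integer(round(window_ms / 1000 * rate)))
  out <- x
  for (i in bad) {
    w <- max(1L, i - hw):min(length(x), i + hw)
    out[i] <- sign(x[i]) * stats::median(abs(x[w]))
  }
  out
}

#' Extract the EMG linear envelope
#'
#' Band-pass filters the cleaned signal with a linear-phase FIR filter
#' (Hamming window, order of at least three periods of the low band edge,
#' group delay compensated), full-wave rectifies it, and low-pass filters
#' the result with a zero-phase second-order Butterworth filter. Residual
#' filter undershoot is clamped so the envelope is nonnegative everywhere.
#'
#' @param x cleaned EMG vector.
#' @param rate sampling rate, samples/s; must exceed 2 x the upper band edge.
#' @param band band-pass edges in Hz, default `c(40, 450)`.
#' @param lp_hz envelope low-pass cutoff, default 4 Hz.
#' @param lp_order designed Butterworth order, default 2 (zero-phase
#'   application doubles the effective roll-off).
#' @return nonnegative envelope, same length as `x`.
#' @export
emg_envelope <- function(x, rate, band = c(40, 450), lp_hz = 4, lp_order = 2) {
  if (rate <= 2 * band[2])
    stop("sampling rate ", rate, " cannot support a band edge at ", band[2],
         " Hz", call. = FALSE)
  ord <- ceiling(3 * rate / band[1])
  if (ord %% 2L == 1L) ord <- ord + 1L
  b <- signal::fir1(ord, band / (rate / 2), type = "pass")
  xf <- fir_filter_linphase(as.numeric(b), as.numeric(x))
  rect <- abs(xf)
  bw <- signal::butter(lp_order, lp_hz / (rate / 2), type = "low")
  env <- zero_phase_filter(bw$b, bw$a, rect, pad = ceiling(6 * rate / lp_hz))
  pmax(env, 0)
}

#' Cut the analysis window around one repetition
#'
#' Extracts the segment running from `pad_s` seconds before the Start event
#' to `pad_s` seconds after the End event. The same rule applies to
#' kinematic and EMG signals at their own sampling rates.
#'
#' @param x signal vector sampled at `rate`, t = 0 at sample 1.
#' @param rate sampling rate, samples/s.
#' @param events an `sts_events` object.
#' @param pad_s padding on each side, default 0.5 s.
#' @return the windowed segment (length `round((duration + 2 pad) * rate)`).
#' @export
window_trial <- function(x, rate, events, pad_s = 0.5) {
  i0 <- round((events$start - pad_s) * rate) + 1L
  n <- round((movement_duration(events) + 2 * pad_s) * rate)
  if (i0 < 1L || i0 + n - 1L > length(x))
    stop("recording too short for the analysis window of repetition ",
         events$repetition_index, call. = FALSE)
  x[i0:(i0 + n - 1L)]
}

#' Time-normalize a segment to the movement cycle
#'
#' Resamples a windowed signal to `n` equally spaced nodes (0-100% of the
#' cycle) by nearest-neighbour selection: node `k` takes the input sample at
#' index `round(k/(n-1) * (L-1))`, rounding half away from zero. No
#' interpolation is performed, so every output value occurs in the input,
#' and the first and last nodes equal the first and last input samples.
#'
#' @param x segment vector of length >= 2.
#' @param n number of nodes, default 101.
#' @return numeric vector of length `n`.
#' @export
time_normalize <- function(x, n = 101L) {
  L <- length(x)
  if (L < 2L) stop("segment too short to time-normalize", call. = FALSE)
  k <- seq_len(n) - 1L
  idx <- floor(k / (n - 1) * (L - 1) + 0.5) + 1L
  x[idx]
}

#' Amplitude-normalize a participant's envelope curves
#'
#' Divides every curve by the single maximum envelope value observed across
#' all of that participant's data for one muscle and side (all conditions
#' and repetitions), so 1 marks the highest activity recorded for that
#' muscle. Alternative scopes divide by the median of the pooled values or
#' by the mean pre-movement baseline supplied per curve.
#'
#' @param curves list (or matrix, rows = curves) of envelope curves from one
#'   participant, one muscle, one side.
#' @param method `"max"` (default), `"median"`, or `"baseline"`.
#' @param baseline for `method = "baseline"`: numeric vector of per-curve
#'   baseline levels.
#' @return same structure as `curves`, rescaled.
#' @export
normalize_amplitude <- function(curves, method = c("max", "median", "baseline"),
                                baseline = NULL) {
  method <- match.arg(method)
  as_list <- is.list(curves)
  m <- if (as_list) do.call(rbind, curves) else as.matrix(curves)
  if (method == "baseline") {
    if (is.null(baseline) || length(baseline) != nrow(m) || any(baseline <= 0))
      stop("baseline normalization needs one positive level per curve",
           call. = FALSE)
    m <- m / baseline
  } else {
    ref <- if (method == "max") max(m) else stats::median(m)
    if (!is.finite(ref) || ref <= 0)
      stop("silent channel: normalization reference is not positive",
           call. = FALSE)
    m <- m / ref
  }
  if (as_list) {
    out <- lapply(seq_len(nrow(m)), function(i) m[i, ])
    names(out) <- names(curves)
    out
  } else m
}
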