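# Kinematic analysis of sit-to-stand recordings: marker smoothing,
# repetition splitting, event detection (Start / Lift-off / Stand / End),
# movement duration, trunk angles and planar lower-limb joint angles.

#' Smooth marker trajectories
#'
#' Low-pass filters every marker coordinate with a zero-phase (forward plus
#' backward) Butterworth filter. Zero-phase application is used so event
#' timing derived from the smoothed trajectories is not lag-biased.
#'
#' @param markers named list of n x 3 matrices (columns X/Y/Z, metres).
#' @param rate sampling rate in samples/s.
#' @param cutoff_hz filter cutoff, default 20 Hz.
#' @param order Butterworth order of the designed filter, default 4 (the
#'   forward-backward cascade doubles the effective roll-off).
#' @return markers in the same structure, smoothed; DC is preserved.
#' @export
smooth_markers <- function(markers, rate, cutoff_hz = 20, order = 4) {
  stopifnot(is.list(markers), rate > 0, cutoff_hz > 0, cutoff_hz < rate / 2)
  bw <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  pad <- ceiling(6 * rate / cutoff_hz)
  lapply(stats::setNames(nm = names(markers)), function(nm) {
    m <- markers[[nm]]
    if (nrow(m) <= 3L * order)
      stop("trajectory too short to smooth: marker '", nm, "'", call. = FALSE)
    apply(m, 2, function(col) zero_phase_filter(bw$b, bw$a, col, pad = pad))
  })
}

# indices of strict local maxima of y
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence of each candidate peak
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    lhs <- which(y[seq_len(p - 1)] > y[p])
    lmin <- if (length(lhs)) min(y[(max(lhs) + 1):p]) else min(y[1:p])
    rhs <- which(y[(p + 1):length(y)] > y[p])
    rmin <- if (length(rhs)) min(y[p:(p + min(rhs))]) else min(y[p:length(y)])
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Split a recording into repetition windows
#'
#' Identifies one window per sit-to-stand repetition from the standing peaks
#' of the C7 vertical position: local maxima qualify if their topographic
#' prominence reaches `min_prominence_frac` of the global vertical excursion
#' and they are at least `min_separation_s` apart (the higher peak wins a
#' conflict). Window boundaries are placed mid-way through the seated span
#' between consecutive peaks (samples where the averaged trochanter height
#' sits within 10% of its between-peak range) and at the recording edges;
#' the C7 minimum itself is unsuitable because deep trunk flexion lowers C7
#' below its seated height.
#'
#' @param markers smoothed markers (see [smooth_markers()]).
#' @param rate sampling rate in samples/s.
#' @param min_prominence_frac,min_separation_s peak-qualification knobs.
#' @return data.frame with one row per repetition: `i0`, `i1` (sample
#'   indices, inclusive) and `peak` (standing-peak index).
#' @export
split_repetitions <- function(markers, rate, min_prominence_frac = 0.3,
                              min_separation_s = 1) {
  y <- markers$c7[, "Y"]
  exc <- max(y) - min(y)
  pk <- local_maxima(y)
  if (length(pk)) {
    pk <- pk[peak_prominence(y, pk) >= min_prominence_frac * exc]
  }
  if (exc <= 0 || length(pk) == 0L)
    stop("no movement detected", call. = FALSE)
  # enforce minimum separation, keeping the higher peak
  pk <- pk[order(y[pk], decreasing = TRUE)]
  keep <- integer(0)
  for (p in pk)
    if (all(abs(p - keep) >= min_separation_s * rate)) keep <- c(keep, p)
  pk <- sort(keep)
  ty <- (markers$r_trochanter[, "Y"] + markers$l_trochanter[, "Y"]) / 2
  bounds <- vapply(seq_len(length(pk) - 1L), function(i) {
    seg <- pk[i]:pk[i + 1L]
    lo <- range(ty[seg])
    seated <- seg[ty[seg] <= lo[1] + 0.1 * (lo[2] - lo[1])]
    seated[ceiling(length(seated) / 2)]
  }, integer(1))
  i0 <- c(1L, bounds)
  i1 <- c(bounds, length(y))
  data.frame(i0 = i0, i1 = i1, peak = pk)
}

#' Detect the four sit-to-stand events in one repetition window
#'
#' Within the window, Start is the first instant the anteroposterior C7
#' speed reaches 10% of its in-window peak and End the last instant it is
#' still at or above that threshold; to reject residual marker-noise
#' excursions, only threshold crossings sustained for at least `hold_s`
#' count. Lift-off is the first instant (at or
#' after Start) the averaged greater-trochanter markers have risen by 10% of
#' their total vertical displacement; Stand is the C7 vertical maximum. A
#' seat-contact proxy (trochanter back within 10% of the seated baseline,
#' after Stand) is returned alongside to separate the lowering and final
#' phases. Speed is the absolute central-difference velocity of the smoothed
#' C7 X coordinate.
#'
#' @param markers smoothed markers.
#' @param rate sampling rate, samples/s.
#' @param window integer vector `c(i0, i1)` or a row of
#'   [split_repetitions()] output.
#' @param repetition_index stored in the result for bookkeeping.
#' @param hold_s minimum duration (s) a speed-threshold crossing must be
#'   sustained to count, default 0.1.
#' @return object of class `sts_events`: list with `start`, `liftoff`,
#'   `stand`, `seat_contact`, `end` (seconds from recording onset, t = 0 at
#'   sample 1) and `repetition_index`.
#' @export
detect_events <- function(markers, rate, window, repetition_index = 1L,
                          hold_s = 0.1) {
  if (is.data.frame(window)) window <- c(window$i0[1], window$i1[1])
  idx <- as.integer(window[1]):as.integer(window[2])
  c7x <- markers$c7[, "X"]; c7y <- markers$c7[, "Y"]
  ty <- (markers$r_trochanter[, "Y"] + markers$l_trochanter[, "Y"]) / 2
  n <- length(c7x)
  vx <- c(0, (c7x[3:n] - c7x[1:(n - 2)]) * rate / 2, 0)
  speed <- abs(vx)[idx]
  pk <- max(speed)
  if (pk <= 0)
    stop("segmentation failure: flat C7 speed in repetition ",
         repetition_index, call. = FALSE)
  runs <- rle(speed >= 0.1 * pk)
  rend <- cumsum(runs$lengths)
  ok <- which(runs$values & runs$lengths >= max(1L, round(hold_s * rate)))
  if (length(ok) == 0L)
    stop("segmentation failure: no sustained speed-threshold crossing in ",
         "repetition ", repetition_index, call. = FALSE)
  st <- idx[rend[ok[1]] - runs$lengths[ok[1]] + 1L]
  en <- idx[rend[ok[length(ok)]]]
  tyw <- ty[idx]
  ymin <- min(tyw); dispv <- max(tyw) - ymin
  cand <- which(idx >= st & tyw >= ymin + 0.1 * dispv)
  stand <- idx[which.max(c7y[idx])]
  post <- which(idx > stand & tyw <= ymin + 0.1 * dispv)
  if (length(cand) == 0L || length(post) == 0L)
    stop("segmentation failure: trochanter displacement threshold never ",
         "crossed in repetition ", repetition_index, call. = FALSE)
  ev <- list(start = (st - 1) / rate,
             liftoff = (idx[cand[1]] - 1) / rate,
             stand = (stand - 1) / rate,
             seat_contact = (idx[post[1]] - 1) / rate,
             end = (en - 1) / rate,
             repetition_index = repetition_index)
  if (!(ev$start < ev$liftoff && ev$liftoff < ev$stand && ev$stand < ev$end))
    stop("segmentation failure: events out of order in repetition ",
         repetition_index, call. = FALSE)
  class(ev) <- "sts_events"
  ev
}

#' @export
print.sts_events <- function(x, ...) {
  cat(sprintf("sts_events #%d: start %.3f | liftoff %.3f | stand %.3f | end %.3f s (duration %.3f s)\n",
              x$repetition_index, x$start, x$liftoff, x$stand, x$end,
              movement_duration(x)))
  invisible(x)
}

#' Movement duration of one repetition
#'
#' Time between the Start and End events, covering the full
#' stand-up-and-sit-down cycle.
#'
#' @param events an `sts_events` object.
#' @return duration in seconds.
#' @export
movement_duration <- function(events) events$end - events$start

#' Trunk inclination angles
#'
#' The trunk vector (C7 minus sacrum) is projected onto the sagittal (X-Y)
#' and frontal (Y-Z) planes; its inclination from the vertical is computed
#' with the two-argument arctangent: `theta_sag = atan2(X, Y)` and
#' `theta_front = atan2(Z, Y)`. Positive sagittal values mean forward
#' flexion; positive frontal values mean lateral flexion toward +Z (the
#' right, i.e. more-impaired, side).
#'
#' @param markers marker list containing `c7` and `sacrum`.
#' @return data.frame with `theta_sag` and `theta_front` in degrees.
#' @export
trunk_angles <- function(markers) {
  v <- markers$c7 - markers$sacrum
  if (any(rowSums(v^2) == 0))
    stop("zero-length trunk vector", call. = FALSE)
  data.frame(theta_sag = atan2(v[, "X"], v[, "Y"]) * 180 / pi,
             theta_front = atan2(v[, "Z"], v[, "Y"]) * 180 / pi)
}

# unsigned angle (degrees) between 2D vectors given as n x 2 matrices
angle2d <- function(a, b) {
  dt <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, dt))) * 180 / pi
}

#' Planar hip, knee and ankle angles per side
#'
#' Sagittal-plane joint angles from marker vector geometry: hip flexion is
#' the angle between the trunk segment (sacrum to C7) and the thigh
#' (trochanter to lateral femoral epicondyle), knee flexion the angle
#' between thigh and shank (epicondyle to lateral malleolus), and ankle
#' dorsiflexion the shank-foot (heel to fifth metatarsal) angle minus 90 so
#' neutral standing reads 0. All segments are projected onto the X-Y plane.
#' The right side is labelled more-impaired (`MI`), per right-hemiparesis
#' convention.
#'
#' @param markers marker list (smoothed or raw).
#' @return data.frame of class `sts_joint_angles` with columns
#'   `hip_MI`, `knee_MI`, `ankle_MI`, `hip_LI`, `knee_LI`, `ankle_LI`
#'   (degrees, one row per sample).
#' @export
planar_joint_angles <- function(markers) {
  need <- c("sacrum", "c7")
  out <- list()
  for (s in c(r = "r", l = "l")) {
    lab <- if (s == "r") "MI" else "LI"
    req <- paste0(s, "_", c("trochanter", "lat_epicondyle", "lat_malleolus",
                            "heel", "meta5"))
    miss <- setdiff(c(need, req), names(markers))
    if (length(miss))
      stop("missing marker(s) for side ", lab, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    xy <- function(nm) markers[[nm]][, c("X", "Y"), drop = FALSE]
    hip <- xy(paste0(s, "_trochanter")); knee <- xy(paste0(s, "_lat_epicondyle"))
    ank <- xy(paste0(s, "_lat_malleolus"))
    trunk <- xy("c7") - xy("sacrum")
    out[[paste0("hip_", lab)]] <- 180 - angle2d(trunk, knee - hip)
    out[[paste0("knee_", lab)]] <- 180 - angle2d(hip - knee, ank - knee)
    out[[paste0("ankle_", lab)]] <-
      90 - angle2d(knee - ank, xy(paste0(s, "_meta5")) - xy(paste0(s, "_heel")))
  }
  structure(as.data.frame(out), class = c("sts_joint_angles", "data.frame"))
}

#' Label the 101 cycle nodes with movement phases
#'
#' Assigns each node of a time-normalized curve to a phase: preparatory
#' (Start to Lift-off), rising (Lift-off to Stand), lowering (Stand to the
#' seat-contact proxy) and final (seat contact to End). Without a
#' seat-contact estimate the lowering label runs to End. Nodes that fall in
#' the padding outside Start-End (when `pad_s > 0`) are labelled `rest`.
#'
#' @param events an `sts_events` object.
#' @param n_nodes number of nodes, default 101.
#' @param pad_s padding (s) on each side of Start-End that the normalized
#'   window includes; 0 maps node 0 to Start and the last node to End.
#' @return character vector of length `n_nodes`.
#' @export
label_phases <- function(events, n_nodes = 101L, pad_s = 0) {
  w0 <- events$start - pad_s
  w1 <- events$end + pad_s
  frac <- seq(0, 1, length.out = n_nodes)
  tt <- w0 + frac * (w1 - w0)
  b <- function(tv) (tv - w0) / (w1 - w0)
  lab <- rep("lowering", n_nodes)
  lab[b(tt) < b(events$stand)] <- "rising"
  lab[b(tt) < b(events$liftoff)] <- "preparatory"
  if (!is.null(events$seat_contact) && is.finite(events$seat_contact))
    lab[b(tt) >= b(events$seat_contact)] <- "final"
  lab[tt < events$start | tt > events$end] <- "rest"
  lab
}
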