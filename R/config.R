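#' Muscle and marker naming conventions
#'
#' The EMG montage covers seven trunk/hip muscles recorded bilaterally:
#' latissimus dorsi (LD), erector spinae iliocostalis (ESI), erector spinae
#' longissimus (ESL), external oblique abdominis (OEA), multifidus (MF),
#' gluteus medius (GMED) and gluteus maximus (GMAX). Channels are labelled
#' `<muscle>_MI` (more-impaired side) and `<muscle>_LI` (less-impaired side);
#' with right hemiparesis the right side is the more impaired one.
#'
#' @return `sts_muscles()`: character vector of the 7 muscle codes.
#' @export
sts_muscles <- function() c("LD", "ESI", "ESL", "OEA", "MF", "GMED", "GMAX")

#' @rdname sts_muscles
#' @return `sts_emg_channels()`: the 14 channel names, muscle x side.
#' @export
sts_emg_channels <- function() {
  as.vector(t(outer(sts_muscles(), c("MI", "LI"), paste, sep = "_")))
}

#' @rdname sts_muscles
#' @return `sts_markers()`: the 28 marker names of the Davis lower-body
#'   protocol plus trunk/head/arm auxiliaries. Bilateral markers carry `r_` /
#'   `l_` prefixes.
#' @export
sts_markers <- function() {
  bilat <- c("acromion", "asis", "trochanter", "lat_epicondyle", "fibula_head",
             "lat_malleolus", "meta5", "heel", "thigh_bar", "shank_bar",
             "elbow", "wrist")
  c("sacrum", "c7", "sternum", "head",
    paste0("r_", bilat), paste0("l_", bilat))
}

#' Configuration for the synthetic sit-to-stand generator
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults reproduce the acquisition setup the analysis pipeline expects:
#' 100 Hz motion capture, 1 kHz bilateral EMG, five consecutive repetitions
#' per condition, cycle durations drawn per subject between 2 and 8 s, and
#' the four-phase kinematic structure (preparatory / rising / lowering /
#' final at 20/30/30/20% of the cycle) with trunk-muscle bursts peaking near
#' 30% and 70% of the cycle.
#'
#' @param n_subjects number of subjects in a cohort.
#' @param n_repetitions consecutive repetitions per condition (default 5).
#' @param conditions character subset of `c("crossed_arms", "free_arms")`.
#' @param kin_rate marker sampling rate, samples/s.
#' @param emg_rate EMG sampling rate, samples/s; must be >= `kin_rate`.
#' @param cycle_duration_s length-2 range (s) from which each subject's mean
#'   cycle duration is drawn uniformly, or a single fixed value.
#' @param phase_fractions four positive fractions summing to 1: preparatory,
#'   rising, lowering, final phase shares of the cycle.
#' @param angle_ranges named list of length-2 degree ranges sampled per
#'   subject: `trunk_flexion` (peak sagittal trunk flexion at lift-off),
#'   `hip_flexion_gain` (extra hip flexion built up in the preparatory
#'   phase), `ankle_dorsi` (peak dorsiflexion), `knee_seated` (initial knee
#'   flexion, approximately 90 deg).
#' @param emg_peak_locations cycle fractions of the major and minor envelope
#'   bursts (defaults 0.30 and 0.70).
#' @param side_asymmetry named list with per-muscle amplitude multipliers
#'   (`amp`) and burst-duration multipliers (`dur`) applied to the
#'   more-impaired side; all 1 = perfectly symmetric null.
#' @param surplus optional planted localized effect: a list
#'   `list(muscle=, lo=, hi=, magnitude=)` adding `magnitude` (relative
#'   amplitude units) to the more-impaired envelope over cycle fractions
#'   `[lo, hi]`, tapered by a raised cosine.
#' @param spike_rate artifact spikes per second injected into each raw EMG
#'   channel (Poisson counts).
#' @param spike_amplitude_factor spike height as a multiple of the channel's
#'   robust SD.
#' @param marker_noise_sd additive white marker noise SD in metres.
#' @param emg_noise_sd unmodulated EMG noise floor relative to the envelope
#'   peak.
#' @param rest_s seated rest (s) before, between and after repetitions;
#'   at least 1 s so repetition splitting and the 500 ms analysis padding
#'   are well defined.
#' @param seed integer root seed; all draws flow from it through named
#'   substreams so any subject/trial can be regenerated independently.
#' @return an object of class `sts_config` (a validated list).
#' @export
sts_config <- function(n_subjects = 7,
                       n_repetitions = 5,
                       conditions = c("crossed_arms", "free_arms"),
                       kin_rate = 100,
                       emg_rate = 1000,
                       cycle_duration_s = c(2, 8),
                       phase_fractions = c(0.20, 0.30, 0.30, 0.20),
                       angle_ranges = list(
                         trunk_flexion = c(20, 45),
                         hip_flexion_gain = c(10, 30),
                         ankle_dorsi = c(5, 15),
                         knee_seated = c(85, 95)),
                       emg_peak_locations = c(0.30, 0.70),
                       side_asymmetry = list(amp = NULL, dur = NULL),
                       surplus = NULL,
                       spike_rate = 0.05,
                       spike_amplitude_factor = 10,
                       marker_noise_sd = 2e-4,
                       emg_noise_sd = 0.05,
                       rest_s = 1.5,
                       seed = 1L) {
  conditions <- match.arg(conditions, c("crossed_arms", "free_arms"),
                          several.ok = TRUE)
  if (length(cycle_duration_s) == 1L)
    cycle_duration_s <- rep(cycle_duration_s, 2L)
  stopifnot(n_subjects >= 1, n_repetitions >= 1,
            length(cycle_duration_s) == 2L, all(cycle_duration_s > 0),
            cycle_duration_s[1] <= cycle_duration_s[2],
            rest_s >= 1)
  if (kin_rate <= 0 || emg_rate <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  if (emg_rate < kin_rate)
    stop("emg_rate must be >= kin_rate", call. = FALSE)
  if (length(phase_fractions) != 4L || any(phase_fractions <= 0) ||
      abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must be 4 positive fractions summing to 1",
         call. = FALSE)
  mus <- sts_muscles()
  amp <- rep(1, length(mus)); names(amp) <- mus
  dur <- amp
  if (!is.null(side_asymmetry$amp)) amp[names(side_asymmetry$amp)] <-
      side_asymmetry$amp
  if (!is.null(side_asymmetry$dur)) dur[names(side_asymmetry$dur)] <-
      side_asymmetry$dur
  if (!is.null(surplus)) {
    stopifnot(is.list(surplus), surplus$muscle %in% mus,
              surplus$lo >= 0, surplus$hi <= 1, surplus$lo < surplus$hi)
  }
  if (spike_rate < 0) stop("spike_rate must be >= 0", call. = FALSE)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_repetitions = as.integer(n_repetitions),
              conditions = conditions,
              kin_rate = kin_rate, emg_rate = emg_rate,
              cycle_duration_s = cycle_duration_s,
              phase_fractions = phase_fractions,
              angle_ranges = angle_ranges,
              emg_peak_locations = emg_peak_locations,
              side_asymmetry = list(amp = amp, dur = dur),
              surplus = surplus,
              spike_rate = spike_rate,
              spike_amplitude_factor = spike_amplitude_factor,
              marker_noise_sd = marker_noise_sd,
              emg_noise_sd = emg_noise_sd,
              rest_s = rest_s,
              seed = as.integer(seed))
  class(cfg) <- "sts_config"
  cfg
}

#' @export
print.sts_config <- function(x, ...) {
  cat("sts_config:", x$n_subjects, "subjects x",
      length(x$conditions), "condition(s) x", x$n_repetitions, "reps;",
      "kin", x$kin_rate, "Hz, emg", x$emg_rate, "Hz, seed", x$seed, "\n")
  invisible(x)
}

# deterministic substream seed derived from the root seed and a label;
# kept below 2^31 so it is a valid R integer
substream_seed <- function(root, ...) {
  lab <- paste(c(root, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# seed a substream and burn a few draws: Mersenne-Twister states seeded with
# nearby integers can yield correlated leading draws
seed_substream <- function(seed) {
  set.seed(seed)
  invisible(stats::runif(20))
}
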