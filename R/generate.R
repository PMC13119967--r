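# Synthetic sit-to-stand trial generator.
#
# A trial is modelled as a planar (sagittal) kinematic chain -- foot, shank,
# thigh, trunk -- embedded in 3D with a small frontal-plane trunk
# oscillation. Joint-angle commands are monotone cubic splines through
# phase-boundary keypoints; marker positions follow by forward kinematics.
# EMG is an envelope-modulated band-limited noise carrier. Ground-truth
# events, phase boundaries and planted side effects are recorded so every
# downstream stage can be validated without real recordings.

SEG_LEN <- c(shank = 0.40, thigh = 0.42, trunk = 0.48)
HIP_HALF_WIDTH <- 0.10   # m, hip joint lateral offset from midline
ANKLE_POS <- c(0, 0.07, 0)  # ankle joint in the sagittal plane, feet planted

# monotone cubic keypoint spline; flat (zero-velocity) entry/exit is obtained
# by duplicating the end values slightly inside the interval
keypoint_spline <- function(u_key, v_key) {
  stats::splinefun(u_key, v_key, method = "monoH.FC")
}

# commanded joint-angle curves (degrees) as functions of cycle fraction u.
# Trunk sagittal, knee and ankle are commanded; hip follows from the planar
# chain closure: hip = trunk_sag + knee - ankle.
command_curves <- function(pars, phase_fractions) {
  f <- cumsum(phase_fractions)     # liftoff, stand, seat-contact, 1
  eps <- 0.03
  trunk <- keypoint_spline(
    c(0, eps, f[1], f[2], f[2] + 0.6 * phase_fractions[3], f[3], 1 - eps, 1),
    c(pars$trunk0, pars$trunk0, pars$trunk_peak, pars$trunk_stand,
      0.8 * pars$trunk_peak, 0.7 * pars$trunk_peak, pars$trunk0, pars$trunk0))
  knee <- keypoint_spline(
    c(0, eps, f[1], f[2], f[3], 1 - eps, 1),
    c(pars$knee_seated, pars$knee_seated, pars$knee_seated + 2, pars$knee_stand,
      pars$knee_seated, pars$knee_seated, pars$knee_seated))
  ankle <- keypoint_spline(
    c(0, eps, f[1], f[2], f[2] + 0.6 * phase_fractions[3], f[3], 1 - eps, 1),
    c(pars$ankle0, pars$ankle0, pars$ankle_peak, 2,
      0.85 * pars$ankle_peak, pars$ankle0 + 1, pars$ankle0, pars$ankle0))
  front <- function(u) pars$front_amp * sin(2 * pi * u) * sin(pi * u)^2
  list(trunk = trunk, knee = knee, ankle = ankle, front = front,
       hip = function(u) trunk(u) + knee(u) - ankle(u))
}

# forward kinematics: angle curves at cycle fractions u -> marker matrices
forward_kinematics <- function(curves, u) {
  d2r <- pi / 180
  ts <- curves$trunk(u) * d2r
  tf <- curves$front(u) * d2r
  kn <- curves$knee(u) * d2r
  an <- curves$ankle(u) * d2r
  n <- length(u)
  mk <- list()
  sides <- c(r = +1, l = -1)
  row3 <- function(dx, dy, dz) matrix(c(dx, dy, dz), n, 3, byrow = TRUE)
  hip_xy <- vector("list", 2L); names(hip_xy) <- names(sides)
  for (s in names(sides)) {
    z <- sides[[s]] * HIP_HALF_WIDTH
    sg <- an                      # shank forward lean = dorsiflexion
    tau <- kn - sg                # thigh (knee->hip) angle from vertical
    ankle <- cbind(ANKLE_POS[1], ANKLE_POS[2], z + numeric(n))
    knee <- ankle + SEG_LEN["shank"] * cbind(sin(sg), cos(sg), 0)
    hip <- knee + SEG_LEN["thigh"] * cbind(-sin(tau), cos(tau), 0)
    hip_xy[[s]] <- hip
    off <- function(dx, dy, dz) row3(dx, dy, sides[[s]] * dz)
    shank_dir <- cbind(sin(sg), cos(sg), 0)
    mk[[paste0(s, "_trochanter")]] <- hip + off(0, 0, 0.03)
    mk[[paste0(s, "_asis")]] <- hip + off(0.10, 0.05, -0.02)
    mk[[paste0(s, "_lat_epicondyle")]] <- knee + off(0, 0, 0.05)
    mk[[paste0(s, "_fibula_head")]] <-
      knee - 0.08 * SEG_LEN["shank"] * shank_dir + off(0, 0, 0.045)
    mk[[paste0(s, "_lat_malleolus")]] <- ankle + off(0, 0, 0.04)
    mk[[paste0(s, "_meta5")]] <- ankle + off(0.12, -0.04, 0.03)
    mk[[paste0(s, "_heel")]] <- ankle + off(-0.05, -0.04, 0.01)
    mk[[paste0(s, "_thigh_bar")]] <- knee + 0.5 * (hip - knee) + off(0, 0, 0.07)
    mk[[paste0(s, "_shank_bar")]] <- ankle + 0.5 * (knee - ankle) + off(0, 0, 0.06)
  }
  hip_mid <- (hip_xy$r + hip_xy$l) / 2
  sacrum <- hip_mid + row3(-0.05, 0.04, 0)
  # trunk direction chosen so atan2(X, Y) and atan2(Z, Y) recover the
  # commanded sagittal/frontal angles exactly
  dir <- cbind(tan(ts), 1, tan(tf))
  dir <- dir / sqrt(rowSums(dir^2))
  c7 <- sacrum + SEG_LEN["trunk"] * dir
  mk$sacrum <- sacrum
  mk$c7 <- c7
  mk$sternum <- sacrum + 0.6 * SEG_LEN["trunk"] * dir + row3(0.08, 0, 0)
  mk$head <- c7 + 0.20 * dir
  for (s in names(sides)) {
    acr <- c7 + row3(-0.01, -0.02, sides[[s]] * 0.18)
    mk[[paste0(s, "_acromion")]] <- acr
    elb <- acr + row3(0.03, -0.28, sides[[s]] * 0.02)
    mk[[paste0(s, "_elbow")]] <- elb
    mk[[paste0(s, "_wrist")]] <- elb + row3(0.05, -0.24, 0)
  }
  lapply(mk[sts_markers()], function(m) {
    colnames(m) <- c("X", "Y", "Z"); m
  })
}

# per-subject morphology / timing / EMG parameters from a named substream
draw_subject_params <- function(config, subject_id) {
  seed_substream(substream_seed(config$seed, "subject", subject_id))
  ar <- config$angle_ranges
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  mus <- sts_muscles()
  list(cycle_s = runif1(config$cycle_duration_s),
       trunk0 = stats::runif(1, 1, 4),
       trunk_peak = runif1(ar$trunk_flexion),
       trunk_stand = stats::runif(1, 1, 4),
       knee_seated = runif1(ar$knee_seated),
       knee_stand = stats::runif(1, 2, 6),
       ankle0 = stats::runif(1, 3, 6),
       ankle_peak = runif1(ar$ankle_dorsi),
       front_amp = stats::runif(1, 1, 5),
       muscle_gain = stats::setNames(exp(stats::rnorm(length(mus), 0, 0.15)), mus),
       peak_shift = stats::runif(1, -0.02, 0.02))
}

# clean (noise-free) EMG envelope of one muscle/side at cycle fractions u,
# in relative units (main burst peak ~ 1 before side multipliers)
envelope_model <- function(u, muscle, side, config, pars) {
  centers <- config$emg_peak_locations + pars$peak_shift
  amps <- c(1, 0.45)[seq_along(centers)]
  w <- 0.07
  if (side == "MI") w <- w * config$side_asymmetry$dur[[muscle]]
  e <- numeric(length(u))
  for (j in seq_along(centers))
    e <- e + amps[j] * exp(-(u - centers[j])^2 / (2 * w^2))
  if (side == "MI") {
    e <- e * config$side_asymmetry$amp[[muscle]]
    sp <- config$surplus
    if (!is.null(sp) && sp$muscle == muscle) {
      inw <- u >= sp$lo & u <= sp$hi
      e[inw] <- e[inw] + sp$magnitude * sin(pi * (u[inw] - sp$lo) / (sp$hi - sp$lo))^2
    }
  }
  e
}

# ground-truth events from the clean kinematic signals: the event definitions
# (10% C7 speed, 10% trochanter rise, C7 vertical max) applied per repetition
truth_events <- function(markers, rep_bounds, kin_rate) {
  c7x <- markers$c7[, "X"]; c7y <- markers$c7[, "Y"]
  ty <- (markers$r_trochanter[, "Y"] + markers$l_trochanter[, "Y"]) / 2
  n <- length(c7x)
  vx <- c(0, (c7x[3:n] - c7x[1:(n - 2)]) * kin_rate / 2, 0)
  speed <- abs(vx)
  out <- NULL
  for (r in seq_len(nrow(rep_bounds))) {
    i0 <- max(1L, floor(rep_bounds$w0[r] * kin_rate) + 1L)
    i1 <- min(n, ceiling(rep_bounds$w1[r] * kin_rate) + 1L)
    idx <- i0:i1
    pk <- max(speed[idx]); thr <- 0.1 * pk
    st <- idx[which(speed[idx] >= thr)[1]]
    en <- idx[rev(which(speed[idx] >= thr))[1]]
    ymin <- min(ty[idx]); dispv <- max(ty[idx]) - ymin
    lo <- idx[which(idx >= st & ty[idx] >= ymin + 0.1 * dispv)[1]]
    stand <- idx[which.max(c7y[idx])]
    post <- idx[idx > stand]
    sc <- post[which(ty[post] <= ymin + 0.1 * dispv)[1]]
    out <- rbind(out, data.frame(
      repetition = r,
      start = (st - 1) / kin_rate, liftoff = (lo - 1) / kin_rate,
      stand = (stand - 1) / kin_rate, seat_contact = (sc - 1) / kin_rate,
      end = (en - 1) / kin_rate))
  }
  out
}

#' Generate one synthetic sit-to-stand trial
#'
#' Builds a hardware-synchronized pair of recordings for one subject and one
#' condition: 28 marker trajectories at `kin_rate` and 14 bilateral EMG
#' channels at `emg_rate`, containing `n_repetitions` consecutive
#' stand-up-and-sit-down cycles separated by seated rest. Ground-truth event
#' times, phase boundaries and planted side differences are attached under
#' `$truth`.
#'
#' @param config an [sts_config()] object.
#' @param subject_id subject identifier (integer or string).
#' @param condition `"crossed_arms"` or `"free_arms"`.
#' @param seed optional integer overriding the substream seed derived from
#'   `config$seed`, the subject and the condition.
#' @return an object of class `sts_trial`: a list with elements `subject_id`,
#'   `condition`, `kin_rate`, `emg_rate`, `markers` (named list of n x 3
#'   matrices, columns X/Y/Z in metres; X forward, Y up, Z right), `emg`
#'   (matrix, one column per channel `<muscle>_<MI|LI>`), and `truth`.
#' @export
generate_trial <- function(config, subject_id, condition = config$conditions[1],
                           seed = NULL) {
  stopifnot(inherits(config, "sts_config"))
  condition <- match.arg(condition, c("crossed_arms", "free_arms"))
  pars <- draw_subject_params(config, subject_id)
  if (is.null(seed))
    seed <- substream_seed(config$seed, "trial", subject_id, condition)
  seed_substream(seed)

  nrep <- config$n_repetitions
  rep_dur <- pars$cycle_s * stats::runif(nrep, 0.95, 1.05)
  rest <- config$rest_s
  t0 <- rest + cumsum(c(0, rep_dur[-nrep] + rest))
  total_s <- rest + sum(rep_dur + rest)
  tk <- seq(0, total_s, by = 1 / config$kin_rate)

  # cycle fraction at each kinematic sample (0 while seated)
  u <- numeric(length(tk))
  for (r in seq_len(nrep)) {
    inr <- tk >= t0[r] & tk <= t0[r] + rep_dur[r]
    u[inr] <- (tk[inr] - t0[r]) / rep_dur[r]
  }
  curves <- command_curves(pars, config$phase_fractions)
  markers <- forward_kinematics(curves, u)

  rep_bounds <- data.frame(w0 = t0 - rest / 2, w1 = t0 + rep_dur + rest / 2)
  events <- truth_events(markers, rep_bounds, config$kin_rate)

  if (config$marker_noise_sd > 0)
    markers <- lapply(markers, function(m)
      m + stats::rnorm(length(m), 0, config$marker_noise_sd))

  # --- EMG ---
  te <- seq(0, total_s, by = 1 / config$emg_rate)
  ue <- numeric(length(te)); inrep <- logical(length(te))
  for (r in seq_len(nrep)) {
    inr <- te >= t0[r] & te <= t0[r] + rep_dur[r]
    ue[inr] <- (te[inr] - t0[r]) / rep_dur[r]
    inrep <- inrep | inr
  }
  bp <- signal::butter(4, c(80, 300) / (config$emg_rate / 2), type = "pass")
  channels <- sts_emg_channels()
  emg <- matrix(0, length(te), length(channels),
                dimnames = list(NULL, channels))
  planted <- list(); clean_env <- list()
  ugrid <- seq(0, 1, length.out = 101L)
  for (m in sts_muscles()) {
    gain <- pars$muscle_gain[[m]]
    clean_env[[paste0(m, "_MI")]] <- gain * envelope_model(ugrid, m, "MI", config, pars)
    clean_env[[paste0(m, "_LI")]] <- gain * envelope_model(ugrid, m, "LI", config, pars)
    planted[[m]] <- clean_env[[paste0(m, "_MI")]] - clean_env[[paste0(m, "_LI")]]
    for (side in c("MI", "LI")) {
      env <- envelope_model(ue, m, side, config, pars) * gain
      env[!inrep] <- 0
      env <- env + 0.02 * gain             # resting tone
      carrier <- zero_phase_filter(bp$b, bp$a,
                                   stats::rnorm(length(te)), pad = 200L)
      carrier <- carrier / stats::sd(carrier)
      x <- env * carrier +
        config$emg_noise_sd * gain * stats::rnorm(length(te))
      if (config$spike_rate > 0)
        x <- inject_spikes(x, rate = config$spike_rate,
                           amplitude_factor = config$spike_amplitude_factor,
                           sample_rate = config$emg_rate,
                           seed = substream_seed(seed, "spikes", m, side))
      emg[, paste0(m, "_", side)] <- x
    }
  }

  structure(list(subject_id = subject_id, condition = condition,
                 kin_rate = config$kin_rate, emg_rate = config$emg_rate,
                 markers = markers, emg = emg,
                 truth = list(events = events, rep_durations = rep_dur,
                              rep_onsets = t0, planted_diff = planted,
                              clean_envelopes = clean_env,
                              subject_params = pars)),
            class = "sts_trial")
}

#' @export
print.sts_trial <- function(x, ...) {
  cat("sts_trial: subject", x$subject_id, "|", x$condition, "|",
      length(x$markers), "markers @", x$kin_rate, "Hz |",
      ncol(x$emg), "EMG channels @", x$emg_rate, "Hz |",
      nrow(x$truth$events), "repetitions\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` x `|conditions|` trials (each holding
#' `n_repetitions` cycles) with per-subject parameters drawn reproducibly
#' from the root seed, plus a manifest indexing every trial.
#'
#' @param config an [sts_config()] object.
#' @return an object of class `sts_cohort`: list with `trials` (list of
#'   [generate_trial()] outputs), `manifest` (data.frame: subject, condition,
#'   n_repetitions, trial list index), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sts_config"))
  trials <- list(); rows <- NULL
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (cond in config$conditions) {
      k <- k + 1L
      trials[[k]] <- generate_trial(config, subject_id = s, condition = cond)
      rows <- rbind(rows, data.frame(subject = s, condition = cond,
                                     n_repetitions = config$n_repetitions,
                                     trial = k))
    }
  }
  structure(list(trials = trials, manifest = rows, config = config),
            class = "sts_cohort")
}

#' @export
print.sts_cohort <- function(x, ...) {
  cat("sts_cohort:", length(x$trials), "trials (",
      x$config$n_subjects, "subjects x",
      length(x$config$conditions), "conditions )\n")
  invisible(x)
}

#' Inject high-amplitude artifact spikes into an EMG channel
#'
#' Plants a Poisson number of isolated spikes at uniformly random times; each
#' spike replaces one sample with `amplitude_factor` times the channel's
#' robust SD (1.4826 x median absolute deviation), with random polarity.
#' Spike indices are recorded in the `"spike_idx"` attribute so the clipping
#' stage can be validated against them.
#'
#' @param x numeric channel vector.
#' @param rate expected spikes per second; 0 returns `x` unchanged.
#' @param amplitude_factor spike magnitude in robust SD units (> 1).
#' @param sample_rate samples per second of `x`.
#' @param seed optional integer seed.
#' @return `x` with spikes planted and attribute `spike_idx`.
#' @export
inject_spikes <- function(x, rate, amplitude_factor = 10,
                          sample_rate = 1000, seed = NULL) {
  if (rate < 0) stop("spike rate must be >= 0", call. = FALSE)
  if (amplitude_factor <= 1) stop("amplitude_factor must exceed 1", call. = FALSE)
  if (!is.null(seed)) seed_substream(seed)
  if (rate == 0) return(x)
  dur <- length(x) / sample_rate
  nsp <- stats::rpois(1, rate * dur)
  if (nsp == 0) { attr(x, "spike_idx") <- integer(0); return(x) }
  idx <- sort(sample.int(length(x), nsp))
  rsd <- 1.4826 * stats::mad(x, constant = 1)
  x[idx] <- sample(c(-1, 1), nsp, replace = TRUE) * amplitude_factor * rsd
  attr(x, "spike_idx") <- idx
  x
}
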