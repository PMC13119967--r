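make_sine_markers <- function(f, n = 1000, rate = 100, amp = 1) {
  list(c7 = cbind(X = amp * sin(2 * pi * f * (0:(n - 1)) / rate),
                  Y = numeric(n), Z = numeric(n)))
}

test_that("the 20 Hz smoother preserves DC and slow motion, kills fast noise", {
  n <- 500
  const <- list(c7 = cbind(X = rep(0.3, n), Y = rep(1.2, n), Z = rep(-0.1, n)))
  sm <- smooth_markers(const, rate = 100)
  expect_lt(max(abs(sm$c7 - const$c7)), 1e-9)

  slow <- smooth_markers(make_sine_markers(1), rate = 100)
  mid <- 300:700   # away from edges
  expect_gt(max(abs(slow$c7[mid, "X"])), 0.99)

  fast <- smooth_markers(make_sine_markers(40), rate = 100)
  expect_lt(max(abs(fast$c7[mid, "X"])), 0.05)  # >= 95% attenuation
})

test_that("too-short trajectories are refused by marker name", {
  short <- list(bad_marker = cbind(X = 1:5, Y = 1:5, Z = 1:5))
  expect_error(smooth_markers(short, rate = 100), "bad_marker")
})

test_that("repetition splitting brackets every ground-truth cycle", {
  cfg <- quiet_config(n_repetitions = 5)
  tr <- generate_trial(cfg, 1)
  sm <- smooth_markers(tr$markers, cfg$kin_rate)
  w <- split_repetitions(sm, cfg$kin_rate)
  expect_identical(nrow(w), 5L)
  ev <- tr$truth$events
  t0 <- (w$i0 - 1) / cfg$kin_rate
  t1 <- (w$i1 - 1) / cfg$kin_rate
  expect_true(all(t0 <= ev$start & ev$end <= t1))

  one <- generate_trial(quiet_config(n_repetitions = 1), 1)
  sm1 <- smooth_markers(one$markers, 100)
  expect_identical(nrow(split_repetitions(sm1, 100)), 1L)
})

test_that("motionless markers raise 'no movement detected'", {
  n <- 400
  flat <- list(c7 = cbind(X = rep(0.2, n), Y = rep(1.3, n), Z = numeric(n)),
               r_trochanter = cbind(X = numeric(n), Y = rep(0.8, n), Z = numeric(n)),
               l_trochanter = cbind(X = numeric(n), Y = rep(0.8, n), Z = numeric(n)))
  expect_error(split_repetitions(flat, 100), "no movement detected")
})

test_that("noise-free trials recover ground-truth events within 2 samples", {
  for (seed in c(21, 22)) {
    cfg <- quiet_config(n_repetitions = 3, seed = seed)
    tr <- generate_trial(cfg, 1)
    sm <- smooth_markers(tr$markers, cfg$kin_rate)
    w <- split_repetitions(sm, cfg$kin_rate)
    for (r in seq_len(nrow(w))) {
      ev <- detect_events(sm, cfg$kin_rate, w[r, ], r)
      tru <- tr$truth$events[r, ]
      for (f in c("start", "liftoff", "stand", "end"))
        expect_lt(abs(ev[[f]] - tru[[f]]), 0.021)
    }
  }
})

test_that("events stay within 5 samples under default marker noise", {
  cfg <- sts_config(n_subjects = 1, n_repetitions = 3,
                    conditions = "free_arms", spike_rate = 0, seed = 31)
  tr <- generate_trial(cfg, 1)
  sm <- smooth_markers(tr$markers, cfg$kin_rate)
  w <- split_repetitions(sm, cfg$kin_rate)
  expect_identical(nrow(w), 3L)
  for (r in seq_len(nrow(w))) {
    ev <- detect_events(sm, cfg$kin_rate, w[r, ], r)
    tru <- tr$truth$events[r, ]
    for (f in c("start", "liftoff", "stand", "end"))
      expect_lt(abs(ev[[f]] - tru[[f]]), 0.051)
  }
})

test_that("segmentation is invariant to global translation and scaling", {
  cfg <- quiet_config(n_repetitions = 2, seed = 12)
  tr <- generate_trial(cfg, 1)
  sm <- smooth_markers(tr$markers, cfg$kin_rate)
  base <- detect_events(sm, 100, split_repetitions(sm, 100)[1, ], 1)
  shifted <- lapply(sm, function(m) m + 3.7)
  scaled <- lapply(sm, function(m) m * 2.5)
  for (variant in list(shifted, scaled)) {
    ev <- detect_events(variant, 100, split_repetitions(variant, 100)[1, ], 1)
    expect_identical(ev$start, base$start)
    expect_identical(ev$liftoff, base$liftoff)
    expect_identical(ev$stand, base$stand)
    expect_identical(ev$end, base$end)
  }
})

test_that("time-reversing a repetition mirrors Start and End", {
  cfg <- quiet_config(n_repetitions = 1, seed = 8)
  tr <- generate_trial(cfg, 1)
  sm <- smooth_markers(tr$markers, 100)
  n <- nrow(sm$c7)
  ev <- detect_events(sm, 100, c(1, n), 1)
  rev_m <- lapply(sm, function(m) m[n:1, , drop = FALSE])
  evr <- detect_events(rev_m, 100, c(1, n), 1)
  total <- (n - 1) / 100
  expect_lt(abs(evr$start - (total - ev$end)), 0.011)
  expect_lt(abs(evr$end - (total - ev$start)), 0.011)
})

test_that("a flat speed profile is reported as a segmentation failure", {
  n <- 300
  mk <- list(c7 = cbind(X = rep(1, n), Y = seq(1, 1.3, length.out = n),
                        Z = numeric(n)),
             r_trochanter = cbind(X = numeric(n),
                                  Y = seq(0.8, 1, length.out = n),
                                  Z = numeric(n)))
  mk$l_trochanter <- mk$r_trochanter
  expect_error(detect_events(mk, 100, c(1, n), 1), "segmentation failure")
})

test_that("movement duration is End minus Start", {
  ev <- fake_events(1.0, 2.0, 3.0, 5.2)
  expect_equal(movement_duration(ev), 4.2)
  tr <- generate_trial(quiet_config(seed = 19), 1)
  sm <- smooth_markers(tr$markers, 100)
  ev1 <- detect_events(sm, 100, split_repetitions(sm, 100)[1, ], 1)
  tru <- tr$truth$events[1, ]
  expect_equal(movement_duration(ev1), tru$end - tru$start, tolerance = 0.011)
})

test_that("trunk angles follow the atan2 projection convention", {
  mk1 <- list(sacrum = cbind(X = 0, Y = 0, Z = 0),
              c7 = cbind(X = 0, Y = 1, Z = 0))
  a <- trunk_angles(mk1)
  expect_equal(c(a$theta_sag, a$theta_front), c(0, 0))
  mk2 <- list(sacrum = cbind(X = 0, Y = 0, Z = 0),
              c7 = cbind(X = 1, Y = 1, Z = 0))
  expect_equal(trunk_angles(mk2)$theta_sag, 45)
  expect_equal(trunk_angles(mk2)$theta_front, 0)
  mk3 <- list(sacrum = cbind(X = 0, Y = 0, Z = 0),
              c7 = cbind(X = 0, Y = 1, Z = 1))
  expect_equal(trunk_angles(mk3)$theta_front, 45)
  expect_equal(trunk_angles(mk3)$theta_sag, 0)
  mk0 <- list(sacrum = cbind(X = 0, Y = 0, Z = 0),
              c7 = cbind(X = 0, Y = 0, Z = 0))
  expect_error(trunk_angles(mk0), "zero-length")
})

pose_markers <- function(hip, knee, ankle_joint, c7, sacrum, side = "r") {
  mk <- list(sacrum = rbind(sacrum), c7 = rbind(c7))
  colnames(mk$sacrum) <- colnames(mk$c7) <- c("X", "Y", "Z")
  add <- function(nm, p) {
    m <- rbind(p); colnames(m) <- c("X", "Y", "Z")
    mk[[paste0(side, "_", nm)]] <<- m
  }
  add("trochanter", hip); add("lat_epicondyle", knee)
  add("lat_malleolus", ankle_joint)
  add("heel", ankle_joint + c(-0.05, -0.04, 0))
  add("meta5", ankle_joint + c(0.12, -0.04, 0))
  mk
}

test_that("planar joint angles read 0 in neutral standing and 90/90 seated", {
  stand <- c(pose_markers(hip = c(0, 0.8, 0.1), knee = c(0, 0.4, 0.1),
                          ankle_joint = c(0, 0.05, 0.1),
                          c7 = c(0, 1.3, 0), sacrum = c(0, 0.85, 0)),
             pose_markers(hip = c(0, 0.8, -0.1), knee = c(0, 0.4, -0.1),
                          ankle_joint = c(0, 0.05, -0.1),
                          c7 = c(0, 1.3, 0), sacrum = c(0, 0.85, 0),
                          side = "l"))
  ja <- planar_joint_angles(stand)
  expect_equal(ja$hip_MI, 0, tolerance = 1e-8)
  expect_equal(ja$knee_MI, 0, tolerance = 1e-8)
  expect_equal(ja$ankle_MI, 0, tolerance = 1e-8)

  seated <- c(pose_markers(hip = c(-0.4, 0.45, 0.1), knee = c(0, 0.45, 0.1),
                           ankle_joint = c(0, 0.05, 0.1),
                           c7 = c(-0.4, 0.95, 0), sacrum = c(-0.4, 0.5, 0)),
              pose_markers(hip = c(-0.4, 0.45, -0.1), knee = c(0, 0.45, -0.1),
                           ankle_joint = c(0, 0.05, -0.1),
                           c7 = c(-0.4, 0.95, 0), sacrum = c(-0.4, 0.5, 0),
                           side = "l"))
  js <- planar_joint_angles(seated)
  expect_equal(js$hip_MI, 90, tolerance = 1e-8)
  expect_equal(js$knee_MI, 90, tolerance = 1e-8)
})

test_that("recovered knee angle matches the generator command within 2 deg RMS", {
  cfg <- quiet_config(n_repetitions = 1, seed = 14)
  tr <- generate_trial(cfg, 1)
  ja <- planar_joint_angles(tr$markers)
  p <- tr$truth$subject_params
  # full-curve agreement against the commanded spline over the cycle
  t0 <- tr$truth$rep_onsets[1]; D <- tr$truth$rep_durations[1]
  i <- (ceiling(t0 * 100):floor((t0 + D) * 100)) + 1L
  u <- ((i - 1) / 100 - t0) / D
  cmd <- stsmap:::command_curves(p, cfg$phase_fractions)$knee(u)
  expect_lt(abs(max(ja$knee_MI[i]) - max(cmd)), 2)
  expect_lt(abs(min(ja$knee_MI[i]) - min(cmd)), 2)
  rms <- sqrt(mean((ja$knee_MI[i] - cmd)^2))
  expect_lt(rms, 2)
})

test_that("joint angles are invariant to global marker translation", {
  tr <- generate_trial(quiet_config(seed = 6), 1)
  ja <- planar_joint_angles(tr$markers)
  moved <- lapply(tr$markers, function(m) m + 1.23)
  expect_equal(planar_joint_angles(moved), ja, tolerance = 1e-10)
})

test_that("a missing marker is reported with marker and side", {
  tr <- generate_trial(quiet_config(), 1)
  mk <- tr$markers
  mk$l_heel <- NULL
  expect_error(planar_joint_angles(mk), "l_heel")
  expect_error(planar_joint_angles(mk), "LI")
})

test_that("phase labels partition the 101 nodes at the event boundaries", {
  ev <- fake_events(0, 2, 5, 10)   # events at 0/20/50/100% of the window
  lab <- label_phases(ev)
  expect_length(lab, 101L)
  expect_identical(as.integer(table(lab)[c("preparatory", "rising", "lowering")]),
                   c(20L, 30L, 51L))
  expect_identical(lab[20], "preparatory")
  expect_identical(lab[21], "rising")   # node 20, 0-based
  expect_identical(lab[51], "lowering") # node 50
  # contiguity
  expect_identical(rle(lab)$values, c("preparatory", "rising", "lowering"))

  ev2 <- fake_events(0, 2, 5, 10, seat_contact = 8)
  lab2 <- label_phases(ev2)
  expect_identical(rle(lab2)$values,
                   c("preparatory", "rising", "lowering", "final"))
  expect_length(lab2, 101L)
})

test_that("generator defaults put the Stand boundary near node 50", {
  tr <- generate_trial(quiet_config(seed = 23), 1)
  sm <- smooth_markers(tr$markers, 100)
  ev <- detect_events(sm, 100, split_repetitions(sm, 100)[1, ], 1)
  lab <- label_phases(ev)
  boundary <- max(which(lab == "rising"))  # last rising node, 1-based
  expect_gte(boundary, 47)
  expect_lte(boundary, 53)
})
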