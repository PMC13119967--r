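# Independent brute-force enumerator for the paired sign-flip SPM test.
# Written as a plain loop over the 2^n sign assignments (bit masks), with its
# own t computation and run scanning, sharing no code with the package.
oracle_spm <- function(D, alpha = 0.05) {
  n <- nrow(D); q <- ncol(D); M <- 2L^n
  signs_of <- function(k) {
    s <- numeric(n)
    for (i in seq_len(n))
      s[i] <- if (bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L) -1 else 1
    s
  }
  tcurve <- function(X) {
    vapply(seq_len(q), function(j) {
      d <- X[, j]; m <- mean(d); s <- stats::sd(d)
      if (s == 0) { if (m == 0) 0 else sign(m) * Inf } else m / (s / sqrt(n))
    }, numeric(1))
  }
  tmats <- lapply(0:(M - 1L), function(k) tcurve(D * signs_of(k)))
  maxabs <- vapply(tmats, function(tt) max(abs(tt)), numeric(1))
  crit <- sort(maxabs)[ceiling((1 - alpha) * M)]
  longest <- function(flag) {
    best <- 0L; cur <- 0L
    for (f in flag) { if (f) { cur <- cur + 1L; best <- max(best, cur) } else cur <- 0L }
    best
  }
  Lpos <- vapply(tmats, function(tt) longest(tt > crit), integer(1))
  Lneg <- vapply(tmats, function(tt) longest(tt < -crit), integer(1))
  tobs <- tmats[[1]]
  clusters <- NULL
  i <- 1L
  while (i <= q) {
    if (abs(tobs[i]) > crit) {
      j <- i
      while (j < q && abs(tobs[j + 1L]) > crit) j <- j + 1L
      ext <- j - i + 1L
      cnt <- if (sign(tobs[i]) >= 0) sum(Lpos >= ext) else sum(Lneg >= ext)
      clusters <- rbind(clusters,
                        data.frame(node_start = i - 1L, node_end = j - 1L,
                                   extent = ext, p = cnt / M))
      i <- j + 1L
    } else i <- i + 1L
  }
  list(crit = crit, clusters = clusters)
}

# quick noise-free generator configuration used across kinematics tests
quiet_config <- function(n_repetitions = 2, seed = 42, ...) {
  sts_config(n_subjects = 1, n_repetitions = n_repetitions,
             conditions = "free_arms", marker_noise_sd = 0, spike_rate = 0,
             seed = seed, ...)
}

# events object without running detection (for windowing/labelling tests)
fake_events <- function(start, liftoff, stand, end, seat_contact = NA,
                        repetition_index = 1L) {
  structure(list(start = start, liftoff = liftoff, stand = stand,
                 seat_contact = seat_contact, end = end,
                 repetition_index = repetition_index),
            class = "sts_events")
}

# calibrated planted-surplus magnitude for effect-recovery simulations,
# fixed by a pilot power sweep (recovery saturates from ~0.25 upward)
SURPLUS_MAGNITUDE <- 0.25
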