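# End-to-end orchestration: segment every trial, compute angle and envelope
# curves, average repetitions per subject, run side-vs-side permutation SPM
# per variable and apply BH-FDR within each condition.

#' Average a subject's repetition curves
#'
#' Pointwise arithmetic mean of the time-normalized repetition curves,
#' giving the single representative curve per subject, side, variable and
#' condition that enters group-level testing.
#'
#' @param curves matrix (rows = repetitions) or list of equal-length curves.
#' @return numeric vector (one representative curve).
#' @export
average_subject_curves <- function(curves) {
  m <- if (is.list(curves)) do.call(rbind, curves) else as.matrix(curves)
  if (nrow(m) == 0L) stop("no repetition curves to average", call. = FALSE)
  colMeans(m)
}

# process one trial: returns list(meta=data.frame, curves=matrix,
# events=data.frame, skipped=character)
process_trial <- function(trial, n_nodes = 101L, pad_s = 0.5,
                          muscles = sts_muscles()) {
  sm <- smooth_markers(trial$markers, trial$kin_rate)
  wins <- split_repetitions(sm, trial$kin_rate)
  angles <- planar_joint_angles(sm)
  envs <- NULL
  has_emg <- !is.null(trial[["emg"]])
  if (has_emg) {
    chans <- as.vector(t(outer(muscles, c("MI", "LI"), paste, sep = "_")))
    envs <- sapply(chans, function(ch) {
      emg_envelope(clip_spikes(trial[["emg"]][, ch], trial$emg_rate),
                   trial$emg_rate)
    })
  }
  meta <- NULL; curves <- NULL; evrows <- NULL; skipped <- character(0)
  for (r in seq_len(nrow(wins))) {
    ev <- tryCatch(detect_events(sm, trial$kin_rate, wins[r, ],
                                 repetition_index = r),
                   error = function(e) conditionMessage(e))
    if (is.character(ev)) { skipped <- c(skipped, ev); next }
    evrows <- rbind(evrows, data.frame(
      subject = trial$subject_id, condition = trial$condition, repetition = r,
      start = ev$start, liftoff = ev$liftoff, stand = ev$stand,
      end = ev$end, duration = movement_duration(ev)))
    add <- function(varname, family, side, sig, rate) {
      seg <- tryCatch(window_trial(sig, rate, ev, pad_s = pad_s),
                      error = function(e) NULL)
      if (is.null(seg)) {
        skipped <<- c(skipped, paste0("window unavailable: rep ", r, " ",
                                      varname, "_", side))
        return(invisible(NULL))
      }
      meta <<- rbind(meta, data.frame(
        subject = trial$subject_id, condition = trial$condition,
        repetition = r, family = family, variable = varname, side = side))
      curves <<- rbind(curves, time_normalize(seg, n_nodes))
    }
    for (v in c("hip", "knee", "ankle"))
      for (side in c("MI", "LI"))
        add(v, "kinematics", side, angles[[paste0(v, "_", side)]],
            trial$kin_rate)
    if (has_emg)
      for (m in muscles)
        for (side in c("MI", "LI"))
          add(m, "emg", side, envs[, paste0(m, "_", side)], trial$emg_rate)
  }
  list(meta = meta, curves = curves, events = evrows, skipped = skipped)
}

#' Run the full sit-to-stand analysis on a cohort
#'
#' For every trial: smooths markers, splits repetitions, detects events,
#' computes planar joint angles and EMG envelopes, windows each repetition
#' (500 ms padding by default) and time-normalizes it to `n_nodes` nodes.
#' Envelopes are then amplitude-normalized per participant, muscle and side
#' across all of that participant's data; repetitions are averaged into one
#' representative curve per subject, side, variable and condition; each
#' variable is tested side-vs-side with the exhaustive sign-flip permutation
#' SPM; and Benjamini-Hochberg FDR is applied across variables within each
#' condition, separately for the kinematic and EMG families. Trials or
#' repetitions that fail a stage are flagged and excluded; a subject missing
#' a modality in one condition drops out of that comparison only.
#'
#' @param cohort an `sts_cohort` (or a list with `trials`).
#' @param alpha significance level, default 0.05.
#' @param counting permutation counting convention, see
#'   [spm_paired_permutation()].
#' @param norm_method envelope amplitude normalization scope, see
#'   [normalize_amplitude()].
#' @param n_nodes nodes per normalized curve, default 101.
#' @param pad_s analysis-window padding in seconds, default 0.5.
#' @param muscles muscles to analyse (default all seven).
#' @return object of class `sts_report`: list with `results` (one row per
#'   condition x variable: n, permutations, minimum cluster p, FDR flag),
#'   `clusters` (every supra-threshold cluster), `events`, `durations`,
#'   `skipped`, `subject_curves` and `settings`.
#' @export
run_pipeline <- function(cohort, alpha = 0.05, counting = "directional",
                         norm_method = "max", n_nodes = 101L, pad_s = 0.5,
                         muscles = sts_muscles()) {
  trials <- cohort$trials
  meta <- NULL; curves <- NULL; events <- NULL; skipped <- character(0)
  for (tr in trials) {
    pt <- tryCatch(process_trial(tr, n_nodes = n_nodes, pad_s = pad_s,
                                 muscles = muscles),
                   error = function(e) conditionMessage(e))
    if (is.character(pt)) {
      skipped <- c(skipped, paste0("trial subject ", tr$subject_id, " ",
                                   tr$condition, ": ", pt))
      next
    }
    meta <- rbind(meta, pt$meta)
    curves <- rbind(curves, pt$curves)
    events <- rbind(events, pt$events)
    skipped <- c(skipped, pt$skipped)
  }
  if (is.null(meta)) stop("no trial could be processed", call. = FALSE)

  # amplitude normalization: per subject x muscle x side over everything
  emg_rows <- which(meta$family == "emg")
  if (length(emg_rows)) {
    key <- interaction(meta$subject[emg_rows], meta$variable[emg_rows],
                       meta$side[emg_rows], drop = TRUE)
    for (g in split(emg_rows, key)) {
      curves[g, ] <- normalize_amplitude(curves[g, , drop = FALSE],
                                         method = norm_method)
    }
  }

  # representative curve per subject x condition x variable x side
  rep_key <- interaction(meta$subject, meta$condition, meta$family,
                         meta$variable, meta$side, drop = TRUE)
  groups <- split(seq_len(nrow(meta)), rep_key)
  sub_meta <- NULL; sub_curves <- NULL
  for (g in groups) {
    sub_meta <- rbind(sub_meta, meta[g[1],
      c("subject", "condition", "family", "variable", "side")])
    sub_curves <- rbind(sub_curves,
                        average_subject_curves(curves[g, , drop = FALSE]))
  }

  results <- NULL; cl_all <- NULL
  conds <- unique(sub_meta$condition)
  for (cond in conds) {
    for (fam in unique(sub_meta$family)) {
      sel <- sub_meta$condition == cond & sub_meta$family == fam
      vars <- unique(sub_meta$variable[sel])
      pmin_v <- stats::setNames(rep(NA_real_, length(vars)), vars)
      rows <- NULL
      for (v in vars) {
        mi <- sel & sub_meta$variable == v & sub_meta$side == "MI"
        li <- sel & sub_meta$variable == v & sub_meta$side == "LI"
        subs <- intersect(sub_meta$subject[mi], sub_meta$subject[li])
        if (length(subs) < 2L) {
          rows <- rbind(rows, data.frame(
            condition = cond, family = fam, variable = v, n = length(subs),
            n_permutations = NA_integer_, crit = NA_real_,
            min_cluster_p = NA_real_, testable = FALSE))
          next
        }
        a <- curves_for(sub_meta, sub_curves, mi, subs)
        b <- curves_for(sub_meta, sub_curves, li, subs)
        spm <- spm_paired_permutation(a - b, alpha = alpha,
                                      counting = counting)
        pmin <- if (nrow(spm$clusters)) min(spm$clusters$p) else 1
        pmin_v[v] <- pmin
        if (nrow(spm$clusters))
          cl_all <- rbind(cl_all, cbind(
            data.frame(condition = cond, family = fam, variable = v),
            spm$clusters))
        rows <- rbind(rows, data.frame(
          condition = cond, family = fam, variable = v, n = length(subs),
          n_permutations = spm$n_permutations, crit = spm$crit,
          min_cluster_p = pmin, testable = TRUE))
      }
      ok <- !is.na(pmin_v)
      rows$fdr_reject <- NA
      if (any(ok)) {
        dec <- bh_fdr(pmin_v[ok], alpha = alpha)
        rows$fdr_reject[match(dec$variable, rows$variable)] <- dec$reject
      }
      results <- rbind(results, rows)
    }
  }
  durations <- stats::aggregate(duration ~ subject + condition, events, mean)
  structure(list(results = results, clusters = cl_all, events = events,
                 durations = durations, skipped = skipped,
                 subject_curves = list(meta = sub_meta, curves = sub_curves),
                 settings = list(alpha = alpha, counting = counting,
                                 norm_method = norm_method,
                                 n_nodes = n_nodes, pad_s = pad_s)),
            class = "sts_report")
}

# stack one curve per subject (in `subs` order) from a logical row filter
curves_for <- function(meta, curves, filter, subs) {
  idx <- which(filter)
  idx <- idx[match(subs, meta$subject[idx])]
  curves[idx, , drop = FALSE]
}

#' @export
print.sts_report <- function(x, ...) {
  cat("sts_report:", nrow(x$results), "comparisons,",
      if (is.null(x$clusters)) 0 else nrow(x$clusters),
      "supra-threshold clusters,",
      sum(x$results$fdr_reject, na.rm = TRUE), "FDR-rejected\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}
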