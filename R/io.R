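# Plain-text exchange formats: trial TSV pair (markers + EMG), cohort
# manifest (YAML), and the analysis report (JSON). Numeric columns are
# written with 17 significant digits so write -> read round-trips doubles
# exactly.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_tsv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) fmt_num(col) else col), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write / read a trial in the TSV exchange schema
#'
#' A trial is stored as two wide tables sharing `t = 0`:
#' `<stem>_markers.tsv` with columns `time_s` and `<marker>_{X,Y,Z}`, and
#' `<stem>_emg.tsv` with `time_s` and `<muscle>_{MI,LI}`, plus
#' `<stem>_meta.yaml` holding subject, condition, rates and (for synthetic
#' trials) the ground truth. `read_trial(write_trial(x))` reproduces every
#' array exactly.
#'
#' @param trial an `sts_trial`.
#' @param stem file path prefix (directories must exist).
#' @return `write_trial`: `stem`, invisibly. `read_trial`: an `sts_trial`.
#' @export
write_trial <- function(trial, stem) {
  mk <- trial$markers
  n <- nrow(mk[[1]])
  mdf <- data.frame(time_s = (seq_len(n) - 1) / trial$kin_rate)
  for (nm in names(mk))
    for (cc in c("X", "Y", "Z"))
      mdf[[paste0(nm, "_", cc)]] <- mk[[nm]][, cc]
  write_tsv_exact(mdf, paste0(stem, "_markers.tsv"))
  if (!is.null(trial[["emg"]])) {
    ne <- nrow(trial[["emg"]])
    edf <- data.frame(time_s = (seq_len(ne) - 1) / trial$emg_rate)
    for (ch in colnames(trial[["emg"]])) edf[[ch]] <- trial[["emg"]][, ch]
    write_tsv_exact(edf, paste0(stem, "_emg.tsv"))
  }
  meta <- list(subject_id = trial$subject_id, condition = trial$condition,
               kin_rate = trial$kin_rate, emg_rate = trial$emg_rate,
               has_emg = !is.null(trial[["emg"]]))
  if (!is.null(trial$truth))
    meta$truth_events <- lapply(
      split(trial$truth$events, seq_len(nrow(trial$truth$events))),
      as.list)
  yaml::write_yaml(meta, paste0(stem, "_meta.yaml"))
  invisible(stem)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  mpath <- paste0(stem, "_markers.tsv")
  if (!file.exists(mpath)) stop("missing file: ", mpath, call. = FALSE)
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  mdf <- utils::read.table(mpath, sep = "\t", header = TRUE,
                           check.names = FALSE)
  markers <- list()
  for (nm in sts_markers()) {
    cols <- paste0(nm, "_", c("X", "Y", "Z"))
    if (!all(cols %in% names(mdf)))
      stop("file ", mpath, " lacks column(s) ",
           paste(setdiff(cols, names(mdf)), collapse = ", "), call. = FALSE)
    m <- as.matrix(mdf[, cols]); colnames(m) <- c("X", "Y", "Z")
    markers[[nm]] <- m
  }
  emg <- NULL
  if (isTRUE(meta$has_emg)) {
    epath <- paste0(stem, "_emg.tsv")
    edf <- utils::read.table(epath, sep = "\t", header = TRUE,
                             check.names = FALSE)
    chans <- sts_emg_channels()
    if (!all(chans %in% names(edf)))
      stop("file ", epath, " lacks channel(s) ",
           paste(setdiff(chans, names(edf)), collapse = ", "), call. = FALSE)
    emg <- as.matrix(edf[, chans])
  }
  truth <- NULL
  if (!is.null(meta$truth_events))
    truth <- list(events = do.call(rbind, lapply(meta$truth_events,
                                                 as.data.frame)))
  structure(list(subject_id = meta$subject_id, condition = meta$condition,
                 kin_rate = meta$kin_rate, emg_rate = meta$emg_rate,
                 markers = markers, emg = emg, truth = truth),
            class = "sts_trial")
}

#' Write / read a cohort directory
#'
#' Writes every trial of a cohort under `dir` (stems `trial_<k>`) plus a
#' `manifest.yaml` naming subjects, conditions, repetition counts and file
#' stems.
#'
#' @param cohort an `sts_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: an `sts_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$stem <- sprintf("trial_%03d", man$trial)
  for (i in seq_len(nrow(man)))
    write_trial(cohort$trials[[man$trial[i]]], file.path(dir, man$stem[i]))
  yaml::write_yaml(lapply(split(man, seq_len(nrow(man))), as.list),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- do.call(rbind, lapply(yaml::read_yaml(file.path(dir, "manifest.yaml")),
                               as.data.frame))
  trials <- lapply(man$stem, function(s) read_trial(file.path(dir, s)))
  structure(list(trials = trials,
                 manifest = man[, c("subject", "condition", "n_repetitions",
                                    "trial")],
                 config = NULL),
            class = "sts_cohort")
}

#' Serialize an analysis report
#'
#' Writes the group-comparison report to JSON (and the per-comparison table
#' to TSV alongside). `read_report` restores the tables.
#'
#' @param report an `sts_report`.
#' @param path output JSON path; the TSV twin replaces the extension.
#' @return `write_report`: `path`, invisibly. `read_report`: list of tables.
#' @export
write_report <- function(report, path) {
  obj <- list(results = report$results, clusters = report$clusters,
              events = report$events, durations = report$durations,
              skipped = report$skipped, settings = report$settings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_tsv_exact(report$results,
                  paste0(sub("\\.json$", "", path), "_results.tsv"))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
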