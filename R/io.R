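#' Write / read a session recording as plain text
#'
#' A recording is serialized as a directory: `meta.yaml` (sampling rate,
#' session/day, protocol, channel list, data kind), `data.csv` (one
#' column per channel x chromophore or channel x wavelength, full
#' precision), and `schedule.tsv` (onset/duration/label). The reader
#' reconstructs an identical `nirs_recording` (cue onsets are re-derived
#' from the phase list).
#'
#' @param recording A `nirs_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "nirs_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kind <- if (!is.null(recording$concentrations)) "concentrations" else "intensities"
  arr <- recording[[kind]]
  planes <- dimnames(arr)[[3]]
  meta <- list(fs = recording$fs, kind = kind,
               session_id = recording$schedule$session_id,
               day_index = recording$schedule$day_index,
               protocol = recording$schedule$protocol,
               channels = dimnames(arr)[[2]], planes = planes)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  flat <- matrix(arr, nrow = dim(arr)[1])
  colnames(flat) <- as.vector(outer(dimnames(arr)[[2]], planes, paste,
                                    sep = "|"))
  utils::write.csv(format(as.data.frame(flat), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   file.path(dir, "data.csv"), row.names = FALSE,
                   quote = FALSE)
  write_schedule(recording$schedule, file.path(dir, "schedule.tsv"))
  if (!is.null(recording$truth)) {
    eff <- recording$truth$effective
    yaml::write_yaml(list(day_index = recording$truth$day_index,
                          amplitudes = lapply(seq_len(nrow(eff)), function(i)
                            list(channel = eff$channel[i], task = eff$task[i],
                                 chromophore = eff$chromophore[i],
                                 value = eff$value[i]))),
                     file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path))
    stop_invalid("not a recording directory (no meta.yaml): ", dir)
  meta <- yaml::read_yaml(meta_path)
  dat <- utils::read.csv(file.path(dir, "data.csv"), check.names = FALSE)
  sched <- read_schedule(file.path(dir, "schedule.tsv"), fs = meta$fs,
                         protocol = meta$protocol,
                         session_id = meta$session_id,
                         day_index = meta$day_index)
  channels <- meta$channels
  planes <- meta$planes
  arr <- array(NA_real_, c(nrow(dat), length(channels), length(planes)),
               dimnames = list(NULL, channels, planes))
  for (p in seq_along(planes))
    arr[, , p] <- as.matrix(dat[, paste(channels, planes[p], sep = "|")])
  rec <- list(concentrations = NULL, intensities = NULL, fs = meta$fs,
              schedule = sched, channels = channels, truth = NULL)
  rec[[meta$kind]] <- arr
  structure(rec, class = "nirs_recording")
}

#' Write a simulated cohort to disk
#'
#' Materializes every session of a [build_paper_like_cohort()] cohort as
#' a recording directory under `dir/<subject>/session_<id>/`, plus a
#' per-subject `subject.yaml` with group, lesion side, session/day
#' mapping and clinical scores.
#'
#' @param cohort Cohort list.
#' @param dir Output root.
#' @param montages Named montage list (see [fit_cohort()]).
#' @param keep_truth Write the planted-amplitude sidecars.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir,
                         montages = list(clinical28 = load_montage("clinical28"),
                                         healthy33 = load_montage("healthy33")),
                         keep_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    sdir <- file.path(dir, subj$meta$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    yaml::write_yaml(list(subject_id = subj$meta$subject_id,
                          group = subj$meta$group,
                          lesion_side = subj$meta$lesion_side,
                          handedness = subj$meta$handedness,
                          montage = subj$montage, protocol = subj$protocol,
                          sessions = lapply(seq_len(nrow(subj$sessions)),
                                            function(i) as.list(subj$sessions[i, ])),
                          clinical = subj$meta$clinical),
                    file.path(sdir, "subject.yaml"))
    montage <- montages[[subj$montage]]
    for (i in seq_len(nrow(subj$sessions))) {
      ses <- subj$sessions[i, ]
      sched <- build_schedule(subj$protocol, n_blocks = ses$n_blocks,
                              seed = child_seed(subj$scenario$seed, 301,
                                                ses$session_id),
                              session_id = ses$session_id,
                              day_index = ses$day_index)
      rec <- simulate_session(montage, sched, subj$scenario)
      if (!keep_truth) rec$truth <- NULL
      write_recording(rec, file.path(sdir, sprintf("session_%02d",
                                                   ses$session_id)))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()`: list of subject entries with `meta`,
#'   `montage` (name), and `recordings` (list of `nirs_recording`).
#' @export
read_cohort <- function(dir) {
  sdirs <- list.dirs(dir, recursive = FALSE)
  sdirs <- sdirs[file.exists(file.path(sdirs, "subject.yaml"))]
  if (!length(sdirs)) stop_invalid("no subject directories under ", dir)
  lapply(sdirs, function(sdir) {
    sy <- yaml::read_yaml(file.path(sdir, "subject.yaml"))
    sessions <- dplyr::bind_rows(lapply(sy$sessions, tibble::as_tibble))
    meta <- subject_meta(sy$subject_id, sy$group, sy$lesion_side,
                         handedness = sy$handedness %||% "right",
                         sessions = sessions[, c("session_id", "day_index")],
                         clinical = sy$clinical)
    recs <- lapply(sort(list.dirs(sdir, recursive = FALSE)), function(d)
      if (file.exists(file.path(d, "meta.yaml"))) read_recording(d))
    list(meta = meta, montage = sy$montage,
         recordings = Filter(Negate(is.null), recs))
  })
}
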