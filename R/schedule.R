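#' Build a session event schedule
#'
#' Lays out the timed phases of one motor-imagery BCI session. A trial is a
#' rest phase followed by a motor-imagery phase; each phase starts with a
#' preparation cue and continues with the execution period. Under the
#' clinical protocol both phases last 17 s (2 s preparation + 15 s
#' execution) at 15.6 Hz; under the healthy protocol, 23 s (3 s + 20 s) at
#' 3.9 Hz. Every block holds 4 trials: 2 left-hand and 2 right-hand
#' motor-imagery trials in seed-determined random order. Trials are tiled
#' back-to-back with no inter-trial gap. A visual cue onset is recorded at
#' the start of every non-preparatory instruction (rest execution and task
#' execution). Phase onsets are rounded to the nearest sample at `fs`.
#'
#' @param protocol `"clinical"` or `"healthy"`.
#' @param n_blocks Number of blocks; defaults to 4 (clinical) or
#'   3 (healthy). The standard counts are 4 or 6 for clinical and 3 for
#'   healthy; other positive values are allowed but flagged non-standard.
#' @param seed Integer seed determining the trial order.
#' @param fs Sampling rate in Hz; defaults to the protocol's rate.
#' @param session_id,day_index Integers recorded in the schedule.
#' @return A `nirs_schedule` object: list with `phases` (tibble: `onset`,
#'   `duration`, `label`, `block`, `trial`), `cues` (tibble: `onset`,
#'   `label`), `fs`, `duration`, `protocol`, `session_id`, `day_index`.
#'   Labels are `rest`, `prep_rest`, `prep_task`, `mi_left`, `mi_right`.
#' @examples
#' s <- build_schedule("clinical", n_blocks = 4, seed = 1)
#' sum(s$phases$label == "mi_left")  # 8
#' @export
build_schedule <- function(protocol = c("clinical", "healthy"),
                           n_blocks = NULL, seed = 1L, fs = NULL,
                           session_id = 1L, day_index = 1L) {
  protocol <- match.arg(protocol)
  defaults <- list(
    clinical = list(n_blocks = 4L, fs = 15.6, prep = 2, task = 15,
                    standard_blocks = c(4L, 6L)),
    healthy = list(n_blocks = 3L, fs = 3.9, prep = 3, task = 20,
                   standard_blocks = 3L)
  )[[protocol]]
  n_blocks <- n_blocks %||% defaults$n_blocks
  if (!is.numeric(n_blocks) || n_blocks < 1 || n_blocks != round(n_blocks))
    stop_invalid("n_blocks must be a positive integer")
  n_blocks <- as.integer(n_blocks)
  if (!n_blocks %in% defaults$standard_blocks)
    message("note: ", n_blocks, " blocks is non-standard for the ",
            protocol, " protocol")
  fs <- fs %||% defaults$fs
  if (fs <= 0) stop_invalid("fs must be positive")

  orders <- with_seed(seed, lapply(seq_len(n_blocks), function(b)
    sample(c("mi_left", "mi_left", "mi_right", "mi_right"))))

  prep <- defaults$prep; task <- defaults$task
  phase_len <- prep + task
  snap <- function(t) round(t * fs) / fs

  mi <- unlist(orders)
  n_tr <- length(mi)
  trial_start <- (seq_len(n_tr) - 1) * 2 * phase_len
  onset <- snap(rep(trial_start, each = 4) +
                  c(0, prep, phase_len, phase_len + prep))
  labels <- as.vector(rbind("prep_rest", "rest", "prep_task", mi))
  phases <- tibble::tibble(
    onset = onset,
    duration = rep(c(prep, task, prep, task), n_tr),
    label = labels,
    block = rep(rep(seq_len(n_blocks), each = 4L), each = 4L),
    trial = rep(seq_len(n_tr), each = 4L))
  exec <- phases$label %in% c("rest", "mi_left", "mi_right")
  structure(list(phases = phases,
                 cues = tibble::tibble(onset = phases$onset[exec],
                                       label = phases$label[exec]),
                 fs = fs, duration = n_tr * 2 * phase_len,
                 protocol = protocol,
                 session_id = as.integer(session_id),
                 day_index = as.integer(day_index)),
            class = "nirs_schedule")
}

#' @export
print.nirs_schedule <- function(x, ...) {
  cat("<nirs_schedule> ", x$protocol, ": ", nrow(x$phases), " phases over ",
      x$duration, " s at ", x$fs, " Hz (session ", x$session_id,
      ", day ", x$day_index, ")\n", sep = "")
  invisible(x)
}

n_samples <- function(schedule) round(schedule$duration * schedule$fs)

#' Write / read a schedule as a 3-column TSV
#'
#' Serializes the phase list as `onset`, `duration`, `label` (seconds).
#' Cue onsets are recoverable from the phase list and are re-derived on
#' read.
#'
#' @param schedule A `nirs_schedule`.
#' @param path Output TSV path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule$phases[, c("onset", "duration", "label")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param fs,protocol,session_id,day_index Metadata not carried by the TSV.
#' @export
read_schedule <- function(path, fs, protocol = "clinical",
                          session_id = 1L, day_index = 1L) {
  ph <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ph <- tibble::as_tibble(ph)
  exec <- ph$label %in% c("rest", "mi_left", "mi_right")
  n_tr <- sum(ph$label %in% c("mi_left", "mi_right"))
  ph$trial <- cumsum(ph$label == "prep_rest")
  ph$block <- (ph$trial - 1L) %/% 4L + 1L
  structure(list(phases = ph,
                 cues = tibble::tibble(onset = ph$onset[exec],
                                       label = ph$label[exec]),
                 fs = fs, duration = max(ph$onset + ph$duration),
                 protocol = protocol, session_id = as.integer(session_id),
                 day_index = as.integer(day_index)),
            class = "nirs_schedule")
}
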