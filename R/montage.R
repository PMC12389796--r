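#' Optode montage
#'
#' A montage describes the recording channels (emitter-detector pairs), the
#' hemisphere each channel samples, and the homotopic (mirror-symmetric)
#' channel pairs used for interhemispheric contrasts. Two defaults are
#' bundled: `"clinical28"` (28 channels, 14 symmetric pairs, motor cortex,
#' 15.6 Hz protocol) and `"healthy33"` (33 channels, 7 analyzed symmetric
#' pairs, 3.9 Hz protocol).
#'
#' @param x A bundled montage name (`"clinical28"` or `"healthy33"`) or a
#'   path to a montage YAML file with fields `name`, `channels`
#'   (id/emitter/detector/hemisphere) and `symmetric_pairs`.
#' @return A `nirs_montage` object: list with `name`, `channels` (tibble:
#'   `channel`, `emitter`, `detector`, `hemisphere`), `pairs` (tibble:
#'   `pair`, `left_channel`, `right_channel`), and `fs_default`.
#' @examples
#' m <- load_montage("clinical28")
#' nrow(m$channels)  # 28
#' nrow(m$pairs)     # 14
#' @export
load_montage <- function(x) {
  bundled <- c(clinical28 = "montage_clinical28.yaml",
               healthy33 = "montage_healthy33.yaml")
  path <- if (x %in% names(bundled)) {
    system.file("extdata", bundled[[x]], package = "nirsasym", mustWork = TRUE)
  } else {
    if (!file.exists(x)) stop_invalid("montage '", x, "' is neither a bundled name nor a file")
    x
  }
  cfg <- yaml::read_yaml(path)
  ch <- dplyr::bind_rows(lapply(cfg$channels, tibble::as_tibble))
  ch <- tibble::tibble(channel = ch$id, emitter = ch$emitter,
                       detector = ch$detector, hemisphere = ch$hemisphere)
  pairs <- tibble::tibble(
    pair = sprintf("P%02d", seq_along(cfg$symmetric_pairs)),
    left_channel = vapply(cfg$symmetric_pairs, `[[`, "", 1L),
    right_channel = vapply(cfg$symmetric_pairs, `[[`, "", 2L)
  )
  new_montage(cfg$name %||% x, ch, pairs, fs_default = cfg$fs_default)
}

#' Construct and validate a montage
#'
#' @param name Montage label.
#' @param channels Tibble with columns `channel`, `emitter`, `detector`,
#'   `hemisphere` (`"left"` or `"right"`).
#' @param pairs Tibble with columns `left_channel`, `right_channel` (and
#'   optionally `pair` ids); members of a pair must lie in opposite
#'   hemispheres and no channel may appear in more than one pair.
#' @param fs_default Default sampling rate (Hz) of the protocol this montage
#'   is used with.
#' @export
new_montage <- function(name, channels, pairs, fs_default = NULL) {
  stopifnot(all(c("channel", "hemisphere") %in% names(channels)))
  if (anyDuplicated(channels$channel))
    stop_invalid("duplicate channel ids in montage")
  if (!all(channels$hemisphere %in% c("left", "right")))
    stop_invalid("hemisphere must be 'left' or 'right'")
  if (!"pair" %in% names(pairs))
    pairs$pair <- sprintf("P%02d", seq_len(nrow(pairs)))
  members <- c(pairs$left_channel, pairs$right_channel)
  if (!all(members %in% channels$channel))
    stop_invalid("symmetric pair references unknown channel")
  if (anyDuplicated(members))
    stop_invalid("a channel appears in more than one symmetric pair")
  hemi <- setNames(channels$hemisphere, channels$channel)
  bad <- hemi[pairs$left_channel] != "left" | hemi[pairs$right_channel] != "right"
  if (any(bad))
    stop_invalid("symmetric pair members must lie in opposite hemispheres: ",
                 paste(pairs$pair[bad], collapse = ", "))
  structure(list(name = name, channels = channels, pairs = pairs,
                 fs_default = fs_default),
            class = "nirs_montage")
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat("<nirs_montage> ", x$name, ": ", nrow(x$channels), " channels, ",
      nrow(x$pairs), " symmetric pairs\n", sep = "")
  invisible(x)
}

# channel -> pair id (NA if unpaired) and pair-mate lookup helpers
pair_of_channel <- function(montage) {
  p <- montage$pairs
  setNames(c(p$pair, p$pair), c(p$left_channel, p$right_channel))
}

mate_of_channel <- function(montage) {
  p <- montage$pairs
  setNames(c(p$right_channel, p$left_channel), c(p$left_channel, p$right_channel))
}

#' Subject metadata
#'
#' @param subject_id Identifier.
#' @param group `"patient"` or `"healthy"`.
#' @param lesion_side `"left"`, `"right"`, or `"none"`; must be `"none"`
#'   exactly when `group = "healthy"`.
#' @param handedness Reported handedness (metadata only).
#' @param sessions Tibble with columns `session_id`, `day_index`
#'   (`day_index` non-decreasing).
#' @param clinical Optional list with `baseline_arat`, `outcome_arat`,
#'   `improvement` (percent).
#' @return A `subject_meta` list.
#' @export
subject_meta <- function(subject_id, group = c("patient", "healthy"),
                         lesion_side = c("left", "right", "none"),
                         handedness = "right", sessions = NULL,
                         clinical = NULL) {
  group <- match.arg(group)
  lesion_side <- match.arg(lesion_side)
  if ((lesion_side == "none") != (group == "healthy"))
    stop_invalid("lesion_side must be 'none' iff group is 'healthy'")
  if (!is.null(sessions)) {
    stopifnot(all(c("session_id", "day_index") %in% names(sessions)))
    if (is.unsorted(sessions$day_index))
      stop_invalid("day_index must be non-decreasing over sessions")
  }
  structure(list(subject_id = subject_id, group = group,
                 lesion_side = lesion_side, handedness = handedness,
                 sessions = sessions, clinical = clinical),
            class = "subject_meta")
}

#' Mirror channels and relabel tasks to the lesion-referenced frame
#'
#' For right-lesioned patients, swaps the response values of each homotopic
#' channel pair so that left-side channel labels always denote the lesioned
#' hemisphere across the cohort; for left-lesioned patients the channels are
#' untouched. In both cases motor-imagery task labels are re-expressed as
#' `"affected"`/`"intact"` hands. Healthy subjects pass through unchanged
#' (no mirroring, tasks stay `mi_left`/`mi_right`).
#'
#' The operation is an involution on the value assignment: applying it twice
#' restores the original channel-value mapping.
#'
#' @param responses Tibble of response amplitudes with columns `channel`,
#'   `task` (`mi_left`/`mi_right`), and value columns; extra columns pass
#'   through.
#' @param meta A [subject_meta()].
#' @param montage A [load_montage()] montage.
#' @return Tibble with the same columns; for patients, `task` relabeled to
#'   `affected`/`intact`. Channels carrying data but absent from any
#'   symmetric pair are dropped with a warning for mirrored subjects.
#' @export
mirror_responses <- function(responses, meta, montage) {
  stopifnot(inherits(meta, "subject_meta"))
  out <- responses
  if (meta$group == "healthy") return(out)
  affected_task <- if (meta$lesion_side == "left") "mi_right" else "mi_left"
  if ("task" %in% names(out)) {
    out$task <- ifelse(out$task == affected_task, "affected",
                       ifelse(out$task %in% c("mi_left", "mi_right"),
                              "intact", out$task))
  }
  if (meta$lesion_side == "right") {
    mate <- mate_of_channel(montage)
    unpaired <- setdiff(unique(out$channel), names(mate))
    if (length(unpaired)) {
      warning("dropping unpaired channel(s) for right-lesion mirroring: ",
              paste(unpaired, collapse = ", "), call. = FALSE)
      out <- out[!out$channel %in% unpaired, , drop = FALSE]
    }
    out$channel <- unname(mate[out$channel])
  }
  out
}
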