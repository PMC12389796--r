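#' Physiological noise specification
#'
#' Additive noise model for synthetic concentration series: white Gaussian
#' noise, a random-walk drift, and three sinusoidal physiological
#' confounds - Mayer waves (~0.1 Hz), respiration (~0.25 Hz) and cardiac
#' pulsation (~1.1 Hz) - each with an independent random phase per channel
#' and chromophore. All components except part of the Mayer wave lie
#' outside the 0.005-0.09 Hz analysis passband; the cardiac line aliases
#' at the 3.9 Hz healthy-protocol rate, as it does in real acquisition
#' (components are generated in continuous time and sampled, with no
#' anti-alias filter). Amplitudes are in the same units as the planted
#' response amplitudes (uM). The default white-noise level is calibrated
#' so that the GLM task-coefficient standard error is about 0.1 of a
#' unit planted amplitude under the default clinical protocol.
#'
#' @param white_sd White noise SD per sample.
#' @param drift_sd Random-walk increment SD per sample.
#' @param mayer_amp,resp_amp,cardiac_amp Sinusoid amplitudes.
#' @param mayer_hz,resp_hz,cardiac_hz Sinusoid frequencies (Hz).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(white_sd = 0.65, drift_sd = 0.004,
                       mayer_amp = 0.06, resp_amp = 0.04, cardiac_amp = 0.08,
                       mayer_hz = 0.1, resp_hz = 0.25, cardiac_hz = 1.1) {
  amps <- c(white_sd, drift_sd, mayer_amp, resp_amp, cardiac_amp)
  if (any(amps < 0)) stop_invalid("noise amplitudes must be >= 0")
  structure(list(white_sd = white_sd, drift_sd = drift_sd,
                 mayer_amp = mayer_amp, resp_amp = resp_amp,
                 cardiac_amp = cardiac_amp, mayer_hz = mayer_hz,
                 resp_hz = resp_hz, cardiac_hz = cardiac_hz),
            class = "noise_spec")
}

#' Planted-response scenario
#'
#' Ground truth for a synthetic subject: the GLM coefficient planted for
#' each channel x task x chromophore, an optional per-day additive drift
#' of those amplitudes, and the noise model. If `amplitudes` carries only
#' HbO rows, HbR amplitudes default to -1/3 of the HbO values (the
#' typical inversion of the deoxyhemoglobin response).
#'
#' @param amplitudes Tibble with columns `channel`, `task`,
#'   `chromophore`, `amplitude` (uM).
#' @param daily_slope Optional tibble with columns `channel`, `task`,
#'   `chromophore`, `slope` (uM per day), added as
#'   `amplitude + day_index * slope`.
#' @param noise A [noise_spec()].
#' @param cue_amp Amplitude planted on the visual-cue regressor.
#' @param seed Base seed; per-session noise streams are derived from it.
#' @return A `response_scenario` list.
#' @export
response_scenario <- function(amplitudes, daily_slope = NULL,
                              noise = noise_spec(), cue_amp = 0, seed = 1L) {
  stopifnot(all(c("channel", "task", "chromophore", "amplitude") %in%
                  names(amplitudes)))
  if (any(!is.finite(amplitudes$amplitude)))
    stop_invalid("planted amplitudes must be finite")
  if (!"HbR" %in% amplitudes$chromophore) {
    hbr <- amplitudes[amplitudes$chromophore == "HbO", ]
    hbr$chromophore <- "HbR"
    hbr$amplitude <- -hbr$amplitude / 3
    amplitudes <- dplyr::bind_rows(amplitudes, hbr)
  }
  structure(list(amplitudes = amplitudes, daily_slope = daily_slope,
                 noise = noise, cue_amp = cue_amp, seed = as.integer(seed)),
            class = "response_scenario")
}

#' Ipsi/contra amplitude ratio yielding a target index value
#'
#' Closed-form inverse of the bounded asymmetry index for the ratio
#' parameterization `(a, b) = (1, c)`: returns `c` such that
#' `trac(1, c) = tau`. Valid for `|tau| < 1/sqrt(2)`.
#'
#' @param tau Target index value.
#' @return The ratio `c`.
#' @export
amplitude_ratio <- function(tau) {
  if (any(abs(tau) >= 1 / sqrt(2)))
    stop_invalid("target must satisfy |tau| < 1/sqrt(2) for a positive pair")
  q <- 1 - 2 * tau^2
  (1 - sign(tau) * sqrt(1 - q^2)) / q
}

#' Planted amplitude tables for patients and controls
#'
#' `patient_amplitudes()` plants a differential task response in the
#' lesioned hemisphere: on lesioned-hemisphere channels the
#' contralateral(affected)-hand HbO response is `contra_amp` and the
#' ipsilateral-hand response is scaled so the analytic HbO TRAC equals
#' `lesioned_trac` (default +0.2); intact-hemisphere channels likewise
#' target `intact_trac` (default -0.05). HbR is -1/3 of HbO, so the HbR
#' TRAC pattern is inverted. `healthy_amplitudes()` plants the same
#' contralateral-dominant but hemisphere-symmetric response
#' (ipsi/contra ratio `ipsi_ratio`) on both sides.
#'
#' @param montage Montage supplying channels and hemispheres.
#' @param lesion_side `"left"` or `"right"`.
#' @param contra_amp Contralateral-hand HbO amplitude (uM).
#' @param lesioned_trac,intact_trac Analytic HbO TRAC targets.
#' @param ipsi_ratio Healthy ipsi/contra amplitude ratio.
#' @return Amplitude tibble for [response_scenario()].
#' @export
patient_amplitudes <- function(montage, lesion_side,
                               contra_amp = 1, lesioned_trac = 0.2,
                               intact_trac = -0.05) {
  stopifnot(lesion_side %in% c("left", "right"))
  ch <- montage$channels
  lesioned <- ch$hemisphere == lesion_side
  # task controlled by the lesioned hemisphere = affected hand
  affected <- if (lesion_side == "left") "mi_right" else "mi_left"
  intact_task <- setdiff(c("mi_left", "mi_right"), affected)
  ratio_les <- amplitude_ratio(lesioned_trac)
  ratio_int <- amplitude_ratio(intact_trac)
  rows <- list(
    # lesioned hemisphere: contra task = affected hand
    tibble::tibble(channel = ch$channel[lesioned], task = affected,
                   amplitude = contra_amp),
    tibble::tibble(channel = ch$channel[lesioned], task = intact_task,
                   amplitude = contra_amp * ratio_les),
    # intact hemisphere: contra task = intact hand
    tibble::tibble(channel = ch$channel[!lesioned], task = intact_task,
                   amplitude = contra_amp),
    tibble::tibble(channel = ch$channel[!lesioned], task = affected,
                   amplitude = contra_amp * ratio_int))
  amp <- dplyr::bind_rows(rows)
  amp$chromophore <- "HbO"
  amp[, c("channel", "task", "chromophore", "amplitude")]
}

#' @rdname patient_amplitudes
#' @export
healthy_amplitudes <- function(montage, contra_amp = 1, ipsi_ratio = 0.8) {
  ch <- montage$channels
  contra_task <- ifelse(ch$hemisphere == "left", "mi_right", "mi_left")
  ipsi_task <- ifelse(ch$hemisphere == "left", "mi_left", "mi_right")
  amp <- dplyr::bind_rows(
    tibble::tibble(channel = ch$channel, task = contra_task,
                   amplitude = contra_amp),
    tibble::tibble(channel = ch$channel, task = ipsi_task,
                   amplitude = contra_amp * ipsi_ratio))
  amp$chromophore <- "HbO"
  amp[, c("channel", "task", "chromophore", "amplitude")]
}

#' Simulate one session recording
#'
#' Forward model: the concentration series of each channel and
#' chromophore is the HRF-convolved design matrix times the planted
#' amplitudes (shifted by `day_index` times the daily slope) plus the
#' scenario's noise. Deterministic given the scenario seed, session id
#' and day index.
#'
#' @param montage Montage; scenario channels must be a subset of its
#'   channels.
#' @param schedule Session schedule ([build_schedule()]).
#' @param scenario A [response_scenario()].
#' @param day_index Day number applied to the daily slope; defaults to
#'   the schedule's.
#' @return A `nirs_recording`: list with `concentrations` (time x channel
#'   x chromophore array, uM), `fs`, `schedule`, `channels`, and `truth`
#'   (the scenario plus the effective per-day amplitudes).
#' @export
simulate_session <- function(montage, schedule, scenario,
                             day_index = NULL) {
  stopifnot(inherits(scenario, "response_scenario"),
            inherits(schedule, "nirs_schedule"))
  if (schedule$fs <= 0) stop_invalid("fs must be positive")
  day_index <- day_index %||% schedule$day_index
  amp <- scenario$amplitudes
  if (!all(amp$channel %in% montage$channels$channel))
    stop_invalid("scenario channels must be a subset of montage channels")
  design <- build_design(schedule)
  n <- design$n
  channels <- montage$channels$channel
  chroms <- c("HbO", "HbR")
  tasks <- design$tasks

  eff <- amp
  eff$value <- eff$amplitude
  if (!is.null(scenario$daily_slope)) {
    sl <- scenario$daily_slope
    key <- paste(sl$channel, sl$task, sl$chromophore)
    add <- sl$slope[match(paste(eff$channel, eff$task, eff$chromophore), key)]
    eff$value <- eff$value + day_index * ifelse(is.na(add), 0, add)
  }

  # coefficient matrix: regressors x (channel, chromophore)
  B <- matrix(0, nrow = ncol(design$X), ncol = length(channels) * 2,
              dimnames = list(colnames(design$X), NULL))
  col_of <- function(ch, cr)
    match(ch, channels) + (match(cr, chroms) - 1L) * length(channels)
  keep <- eff$task %in% tasks
  B[cbind(match(eff$task[keep], rownames(B)),
          col_of(eff$channel[keep], eff$chromophore[keep]))] <- eff$value[keep]
  if ("cue" %in% rownames(B)) B["cue", ] <- scenario$cue_amp
  conc <- design$X %*% B

  ns <- scenario$noise
  seed <- child_seed(scenario$seed, schedule$session_id, day_index)
  conc <- conc + noise_matrix(n, ncol(conc), ns$white_sd, ns$drift_sd,
                              c(ns$mayer_amp, ns$resp_amp, ns$cardiac_amp),
                              c(ns$mayer_hz, ns$resp_hz, ns$cardiac_hz),
                              schedule$fs, seed)
  dim(conc) <- c(n, length(channels), 2)
  dimnames(conc) <- list(NULL, channels, chroms)
  structure(list(concentrations = conc, intensities = NULL,
                 fs = schedule$fs, schedule = schedule, channels = channels,
                 truth = list(scenario = scenario, day_index = day_index,
                              effective = eff)),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  kind <- if (!is.null(x$concentrations)) "concentrations" else "intensities"
  d <- dim(x[[kind]])
  cat("<nirs_recording> ", kind, ": ", d[1], " samples x ", d[2],
      " channels at ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Convert a concentration recording to raw intensities
#'
#' Applies the forward modified Beer-Lambert law per channel and emits
#' dual-wavelength intensities `I = I0 * 10^(-dOD)` around a constant
#' baseline. Round-trips through [concentrations_from_intensity()] to
#' within numerical precision.
#'
#' @param recording A `nirs_recording` with concentrations.
#' @param baseline_intensity Baseline intensity `I0` (> 0, a.u.).
#' @param extinction An [extinction_table()].
#' @return The recording with an `intensities` array (time x channel x
#'   wavelength) and concentrations removed.
#' @export
to_intensities <- function(recording, baseline_intensity = 1,
                           extinction = extinction_table()) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (baseline_intensity <= 0) stop_invalid("baseline_intensity must be > 0")
  conc <- recording$concentrations
  if (is.null(conc)) stop_invalid("recording has no concentrations")
  od <- od_from_concentrations(conc[, , "HbO"], conc[, , "HbR"], extinction)
  inten <- array(NA_real_, c(dim(conc)[1:2], 2),
                 dimnames = list(NULL, dimnames(conc)[[2]],
                                 as.character(extinction$wavelengths)))
  inten[, , 1] <- baseline_intensity * 10^(-od$od1)
  inten[, , 2] <- baseline_intensity * 10^(-od$od2)
  if (any(inten <= 0 | !is.finite(inten))) {
    bad <- which(apply(inten <= 0 | !is.finite(inten), 2, any))
    stop_invalid("concentration excursion drives intensity <= 0 on ",
                 "channel(s): ",
                 paste(dimnames(conc)[[2]][bad], collapse = ", "))
  }
  out <- recording
  out$intensities <- inten
  out$concentrations <- NULL
  out
}

#' Recover concentrations from a raw-intensity recording
#'
#' Optical-density conversion followed by the inverse modified
#' Beer-Lambert law, per channel.
#'
#' @inheritParams to_intensities
#' @param baseline Baseline statistic for [optical_density()].
#' @return The recording with a `concentrations` array.
#' @export
concentrations_from_intensity <- function(recording,
                                          extinction = extinction_table(),
                                          baseline = "mean") {
  stopifnot(inherits(recording, "nirs_recording"))
  inten <- recording$intensities
  if (is.null(inten)) stop_invalid("recording has no intensities")
  od1 <- optical_density(inten[, , 1], baseline = baseline, fs = recording$fs)
  od2 <- optical_density(inten[, , 2], baseline = baseline, fs = recording$fs)
  cc <- concentrations_from_od(od1, od2, extinction)
  conc <- array(NA_real_, c(dim(inten)[1:2], 2),
                dimnames = list(NULL, dimnames(inten)[[2]], c("HbO", "HbR")))
  conc[, , 1] <- cc$HbO
  conc[, , 2] <- cc$HbR
  out <- recording
  out$concentrations <- conc
  out
}

# Printed per-patient clinical fixture metadata used for the default
# 15-patient cohort: lesion side, baseline/outcome ARAT and relative
# improvement (%).
clinical_fixture <- function() {
  tibble::tibble(
    subject_id = sprintf("S%d", 1:15),
    lesion_side = c("right", "left", "right", "left", "left", "left",
                    "right", "left", "left", "left", "right", "left",
                    "right", "right", "right"),
    baseline_arat = c(35, 44, 35, 39, 52, 1, 49, 38, 42, 10, 6, 24, 46, 4, 19),
    outcome_arat = c(55, 50, 41, 43, 57, 1, 57, 45, 46, 10, 16, 29, 50, 9, 28),
    improvement = c(57, 14, 17, 10, 10, 0, 16, 18, 10, 0, 167, 21, 9, 125, 47))
}

#' Generate a study-like synthetic cohort
#'
#' Builds subject metadata, planted-response scenarios and session/day
#' layouts emulating the clinical protocol (1-2 sessions per day over
#' 7-15 days, at most 24 sessions, 4 or 6 blocks per session, 15.6 Hz)
#' and the healthy protocol (one 3-block session per day over up to 11
#' days, 3.9 Hz). For 15 patients the lesion sides and clinical scores
#' are the study's printed per-patient values (8 left- and 7
#' right-hemisphere lesions); other sizes alternate lesion sides and
#' resample those scores. Patient scenarios plant a greater differential
#' task response in the lesioned hemisphere (positive HbO TRAC, negative
#' HbR TRAC there); healthy scenarios are hemisphere-symmetric.
#'
#' @param n_patients,n_healthy Cohort sizes (either may be 0).
#' @param seed Integer seed; all layouts and noise streams derive from
#'   it.
#' @param lesioned_trac,intact_trac Analytic HbO TRAC targets planted in
#'   the two hemispheres of patients.
#' @param recovering Indices (into the patients) given a negative daily
#'   drift of the affected-hand response amplitude, emulating subjects
#'   with substantial motor recovery.
#' @param recovery_slope Amplitude drift (uM/day) for those subjects.
#' @param noise A [noise_spec()] shared by all subjects.
#' @param days_range Range the number of training days is drawn from
#'   (patients).
#' @param sessions_per_day Candidate sessions-per-day counts (patients).
#' @param blocks Candidate blocks-per-session counts (patients).
#' @param max_sessions Cap on total sessions per patient.
#' @param montage_patient,montage_healthy Montages (defaults bundled).
#' @return List of subject entries, each a list with `meta`
#'   ([subject_meta()]), `scenario` ([response_scenario()]), `sessions`
#'   (tibble: `session_id`, `day_index`, `n_blocks`), `protocol`, and
#'   `montage` name.
#' @export
build_paper_like_cohort <- function(n_patients = 15, n_healthy = 9,
                                    seed = 1L,
                                    lesioned_trac = 0.2,
                                    intact_trac = -0.05,
                                    recovering = integer(0),
                                    recovery_slope = -0.05,
                                    noise = noise_spec(),
                                    days_range = c(7L, 15L),
                                    sessions_per_day = c(1L, 2L),
                                    blocks = c(4L, 6L),
                                    max_sessions = 24L,
                                    montage_patient = load_montage("clinical28"),
                                    montage_healthy = load_montage("healthy33")) {
  if (n_patients < 0 || n_healthy < 0 || n_patients + n_healthy < 1)
    stop_invalid("need at least one subject")
  fx <- clinical_fixture()
  sides <- if (n_patients == 15) {
    fx$lesion_side
  } else {
    rep(c("left", "right"), length.out = n_patients)
  }
  subjects <- list()
  for (i in seq_len(n_patients)) {
    sid <- sprintf("S%d", i)
    layout <- with_seed(child_seed(seed, 101, i), {
      pick <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
      n_days <- pick(seq(days_range[1], days_range[2]), 1)
      per_day <- pick(sessions_per_day, n_days)
      day <- rep(seq_len(n_days), per_day)
      if (length(day) > max_sessions) day <- day[seq_len(max_sessions)]
      tibble::tibble(session_id = seq_along(day), day_index = day,
                     n_blocks = pick(blocks, length(day)))
    })
    clin <- if (n_patients == 15) {
      as.list(fx[i, c("baseline_arat", "outcome_arat", "improvement")])
    } else {
      j <- with_seed(child_seed(seed, 102, i), sample(15, 1))
      as.list(fx[j, c("baseline_arat", "outcome_arat", "improvement")])
    }
    amp <- patient_amplitudes(montage_patient, sides[i],
                              lesioned_trac = lesioned_trac,
                              intact_trac = intact_trac)
    slope <- NULL
    if (i %in% recovering) {
      # declining response to affected-hand imagery on every channel:
      # lesioned-hemisphere TRAC drifts down, intact-hemisphere TRAC up
      affected <- if (sides[i] == "left") "mi_right" else "mi_left"
      slope <- tibble::tibble(channel = montage_patient$channels$channel,
                              task = affected, chromophore = "HbO",
                              slope = recovery_slope)
      slope_hbr <- slope
      slope_hbr$chromophore <- "HbR"
      slope_hbr$slope <- -recovery_slope / 3
      slope <- dplyr::bind_rows(slope, slope_hbr)
    }
    meta <- subject_meta(sid, "patient", sides[i],
                         sessions = layout[, c("session_id", "day_index")],
                         clinical = clin)
    subjects[[length(subjects) + 1L]] <- list(
      meta = meta,
      scenario = response_scenario(amp, daily_slope = slope, noise = noise,
                                   seed = child_seed(seed, 103, i)),
      sessions = layout, protocol = "clinical",
      montage = montage_patient$name)
  }
  for (i in seq_len(n_healthy)) {
    sid <- sprintf("H%d", i)
    layout <- with_seed(child_seed(seed, 201, i), {
      n_days <- sample(5:11, 1)
      tibble::tibble(session_id = seq_len(n_days),
                     day_index = seq_len(n_days),
                     n_blocks = 3L)
    })
    meta <- subject_meta(sid, "healthy", "none",
                         sessions = layout[, c("session_id", "day_index")])
    subjects[[length(subjects) + 1L]] <- list(
      meta = meta,
      scenario = response_scenario(healthy_amplitudes(montage_healthy),
                                   noise = noise,
                                   seed = child_seed(seed, 203, i)),
      sessions = layout, protocol = "healthy",
      montage = montage_healthy$name)
  }
  subjects
}
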