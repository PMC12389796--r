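#' Build the GLM design matrix for one session
#'
#' One boxcar regressor per motor-imagery task spanning its execution
#' windows, one shared delta-train regressor over all non-preparatory
#' visual cue onsets, all convolved with the canonical HRF, plus an
#' intercept. Rest execution is deliberately left unmodeled: the resting
#' state is the GLM baseline. A preparation regressor (boxcars over the
#' preparation periods of both rest and task phases) is constructed and
#' its post-convolution correlation with the cue regressor is reported,
#' but it is excluded from the fitted model because the two are nearly
#' collinear at these short preparation durations.
#'
#' @param schedule A [build_schedule()] schedule.
#' @param hrf An [hrf_spec()]; defaults to the canonical HRF at the
#'   schedule's sampling rate.
#' @param cue_regressor Include the shared cue delta-train column.
#' @return A `design_matrix` object: list with `X` (time-by-regressor
#'   matrix; task columns, optional `cue`, then `intercept`), `fs`, `n`,
#'   and `prep_cue_correlation` (the collinearity diagnostic for the
#'   excluded preparation regressor).
#' @export
build_design <- function(schedule, hrf = NULL, cue_regressor = TRUE) {
  stopifnot(inherits(schedule, "nirs_schedule"))
  if (nrow(schedule$phases) == 0) stop_invalid("schedule is empty")
  fs <- schedule$fs
  hrf <- hrf %||% hrf_spec(dt = 1 / fs)
  if (abs(hrf$dt - 1 / fs) > 1e-9)
    stop_invalid("hrf dt (", hrf$dt, ") does not match the schedule fs (", fs, ")")
  # memoize: simulating and then fitting a session builds the same design
  key <- paste(fs, cue_regressor, paste(unlist(hrf), collapse = ","),
               paste(schedule$phases$label, collapse = ""),
               paste(round(schedule$phases$onset * fs), collapse = ","))
  hit <- design_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- n_samples(schedule)
  kern <- canonical_hrf(hrf)

  nk <- length(kern)
  # Each regressor is a sum of shifted copies of one convolved template
  # (boxcar-of-given-length * kernel), so build it by snippet placement
  # instead of full-length convolution.
  snippets <- new.env(parent = emptyenv())
  snippet_for <- function(len) {
    key <- as.character(len)
    if (is.null(snippets[[key]])) {
      y <- stats::filter(c(rep(0, nk - 1), rep(1, len), rep(0, nk - 1)),
                         kern, method = "convolution", sides = 1)
      snippets[[key]] <- as.numeric(y[-seq_len(nk - 1)])
    }
    snippets[[key]]
  }
  add_at <- function(x, snip, from) {
    to <- min(n, from + length(snip) - 1L)
    if (from <= n)
      x[from:to] <- x[from:to] + snip[seq_len(to - from + 1L)]
    x
  }
  hrf_boxcar <- function(labels) {
    x <- numeric(n)
    ph <- schedule$phases[schedule$phases$label %in% labels, ]
    for (i in seq_len(nrow(ph)))
      x <- add_at(x, snippet_for(round(ph$duration[i] * fs)),
                  round(ph$onset[i] * fs) + 1L)
    x
  }

  tasks <- intersect(c("mi_left", "mi_right", "affected", "intact"),
                     unique(schedule$phases$label))
  cols <- lapply(tasks, hrf_boxcar)
  names(cols) <- tasks

  cue_col <- numeric(n)
  for (on in schedule$cues$onset)
    cue_col <- add_at(cue_col, kern, round(on * fs) + 1L)
  prep_col <- hrf_boxcar(c("prep_rest", "prep_task"))
  prep_cor <- suppressWarnings(stats::cor(prep_col, cue_col))

  if (cue_regressor) cols$cue <- cue_col
  cols$intercept <- rep(1, n)
  X <- do.call(cbind, cols)
  out <- structure(list(X = X, fs = fs, n = n, tasks = tasks,
                        prep_cue_correlation = prep_cor),
                   class = "design_matrix")
  if (length(ls(design_cache)) > 16) rm(list = ls(design_cache),
                                        envir = design_cache)
  design_cache[[key]] <- out
  out
}

design_cache <- new.env(parent = emptyenv())

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$n, " samples x ", ncol(x$X), " regressors (",
      paste(colnames(x$X), collapse = ", "), ")\n", sep = "")
  cat("  prep/cue post-convolution correlation: ",
      round(x$prep_cue_correlation, 3), " (preparation excluded)\n", sep = "")
  invisible(x)
}
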