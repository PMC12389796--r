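#' Fit the session GLM
#'
#' Ordinary least squares of each data series on the design matrix. When a
#' filter is supplied, the data and every non-intercept design column are
#' band-pass filtered identically before fitting, which preserves
#' noise-free coefficient recovery (matched filtering) and avoids the
#' attenuation bias of filtering only one side of the regression.
#'
#' @param Y Numeric matrix, time by series (e.g. channels x chromophores
#'   stacked), or a vector.
#' @param design A [build_design()] design matrix.
#' @param filter Optional [filter_spec()] applied to both sides.
#' @param fs Sampling rate, required when `filter` is given and `design`
#'   is absent of one.
#' @return A `glm_fit` list: `coefficients` (regressor x series), `se`
#'   (same shape), `r2`, `sigma` (residual SD) per series, and the column
#'   names fitted.
#' @export
fit_glm <- function(Y, design, filter = NULL, fs = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(Y)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop_invalid("design rows (", nrow(X), ") != series length (", nrow(Y), ")")
  if (!is.null(filter)) {
    fs <- fs %||% design$fs
    keep <- colnames(X) != "intercept"
    X[, keep] <- bandpass(X[, keep, drop = FALSE], fs, filter)
    Y <- bandpass(Y, fs, filter)
  }
  xtx <- crossprod(X)
  R <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps) * max(diag(R))) {
    qx <- qr(X)
    bad <- if (qx$rank < ncol(X))
      colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    else "(near-singular normal equations)"
    stop_invalid("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, Y)))
  rownames(beta) <- colnames(X)
  res <- Y - X %*% beta
  dfres <- nrow(Y) - ncol(X)
  sigma <- sqrt(colSums(res^2) / dfres)
  se <- outer(sqrt(diag(chol2inv(R))), sigma)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- 1 - colSums(res^2) / ifelse(tss > 0, tss, NA_real_)
  rownames(se) <- rownames(beta)
  structure(list(coefficients = beta, se = se, r2 = r2, sigma = sigma,
                 regressors = colnames(X)),
            class = "glm_fit")
}

#' Estimate task response amplitudes for one session recording
#'
#' The full single-session chain: (optionally) modified Beer-Lambert
#' conversion of raw intensities, zero-phase band-pass filtering, and the
#' canonical-HRF GLM. The motor-imagery task coefficients are the
#' quantitative response amplitudes used by the asymmetry indices.
#'
#' @param recording A `nirs_recording` (see [simulate_session()] /
#'   [read_recording()]) holding concentrations or intensities.
#' @param filter A [filter_spec()]; `NULL` skips filtering.
#' @param hrf Optional [hrf_spec()] override.
#' @param extinction [extinction_table()] used when only intensities are
#'   present.
#' @return Tibble with one row per channel x task x chromophore:
#'   `session_id`, `day_index`, `channel`, `task`, `chromophore`,
#'   `coefficient`, `se`, `r2`, `resid_sd`. The excluded preparation
#'   regressor's correlation with the cue regressor is attached as
#'   attribute `"prep_cue_correlation"`.
#' @export
fit_session <- function(recording, filter = filter_spec(), hrf = NULL,
                        extinction = extinction_table()) {
  stopifnot(inherits(recording, "nirs_recording"))
  rec <- recording
  if (is.null(rec$concentrations))
    rec <- concentrations_from_intensity(rec, extinction)
  conc <- rec$concentrations  # time x channel x chromophore
  dn <- dimnames(conc)
  n_ch <- dim(conc)[2]
  chroms <- dn[[3]]
  Y <- matrix(conc, nrow = dim(conc)[1])
  design <- build_design(rec$schedule, hrf = hrf)
  fit <- fit_glm(Y, design, filter = filter, fs = rec$fs)
  tasks <- design$tasks
  nt <- length(tasks)
  nser <- ncol(Y)  # channel-major, chromophore-slowest column order
  ch <- rep(dn[[2]], times = length(chroms))
  cr <- rep(chroms, each = n_ch)
  out <- tibble::tibble(
    session_id = rec$schedule$session_id,
    day_index = rec$schedule$day_index,
    channel = rep(ch, nt),
    task = rep(tasks, each = nser),
    chromophore = rep(cr, nt),
    coefficient = as.vector(t(fit$coefficients[tasks, , drop = FALSE])),
    se = as.vector(t(fit$se[tasks, , drop = FALSE])),
    r2 = rep(unname(fit$r2), nt),
    resid_sd = rep(unname(fit$sigma), nt))
  attr(out, "prep_cue_correlation") <- design$prep_cue_correlation
  out
}
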