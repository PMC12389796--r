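#' Canonical hemodynamic response function specification
#'
#' Parameters of the canonical double-gamma HRF (the SPM `spm_hrf`
#' parameterization): a gamma-density response peak minus a scaled
#' gamma-density undershoot. Defaults are the canonical ones: peak delay
#' 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6,
#' zero onset, 32 s kernel.
#'
#' @param dt Sampling interval in seconds (1/fs).
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions
#'   (scale parameters, seconds).
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude.
#' @param onset Response onset shift in seconds.
#' @param kernel_length Kernel support in seconds.
#' @return An `hrf_spec` list.
#' @export
hrf_spec <- function(dt, peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, onset = 0,
                     kernel_length = 32) {
  if (dt <= 0) stop_invalid("dt must be positive")
  if (dt > kernel_length) stop_invalid("dt must not exceed kernel_length")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop_invalid("dispersions must be positive")
  structure(list(dt = dt, peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 onset = onset, kernel_length = kernel_length),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (shape = delay/dispersion, scale =
#' dispersion) sampled at `dt` over the kernel length and normalized to
#' unit sum, so convolving a sustained boxcar approaches a plateau of the
#' boxcar's height. With the defaults the kernel peaks near 5 s (the mode
#' `(shape - 1) * scale` of the peak gamma) and has a single late
#' undershoot.
#'
#' @param spec An [hrf_spec()].
#' @return Numeric kernel of length `kernel_length / dt + 1`.
#' @export
canonical_hrf <- function(spec) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$kernel_length, by = spec$dt) - spec$onset
  k <- dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
              scale = spec$peak_dispersion) -
    dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
           scale = spec$undershoot_dispersion) / spec$peak_undershoot_ratio
  k / sum(k)
}
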