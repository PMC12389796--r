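#' Extinction coefficients and optical constants for the MBLL
#'
#' Bundles the molar extinction coefficients, differential pathlength
#' factors (DPF) and source-detector separation used by the modified
#' Beer-Lambert law. Defaults: a standard published extinction table for
#' 760/850 nm, DPF 6.0 at both wavelengths, 3 cm separation. The asymmetry
#' indices computed downstream are scale-free ratios, so absolute
#' calibration of these constants does not affect them.
#'
#' @param wavelengths Two wavelengths in nm.
#' @param eps 2x2 matrix of molar extinction coefficients in 1/(mM*cm);
#'   rows = wavelengths, columns = `HbO`, `HbR`.
#' @param dpf Differential pathlength factor per wavelength
#'   (dimensionless).
#' @param distance Source-detector separation in cm.
#' @return An `extinction_table` list; `attr(, "condition_number")` holds
#'   the condition number of the 2x2 system.
#' @export
extinction_table <- function(wavelengths = c(760, 850),
                             eps = NULL, dpf = c(6, 6), distance = 3) {
  if (is.null(eps)) {
    eps <- matrix(c(1.4866, 3.8437,
                    2.5264, 1.7986),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(as.character(wavelengths),
                                  c("HbO", "HbR")))
  }
  stopifnot(is.matrix(eps), all(dim(eps) == c(2, 2)))
  if (length(dpf) == 1) dpf <- rep(dpf, 2)
  # pathlength-weighted system mapping mM concentrations to OD
  M <- eps * dpf * distance
  kappa <- kappa(M, exact = TRUE)
  if (!is.finite(kappa) || abs(det(M)) < 1e-12)
    stop_invalid("extinction system is singular for these wavelengths")
  structure(list(wavelengths = wavelengths, eps = eps, dpf = dpf,
                 distance = distance, M = M),
            class = "extinction_table", condition_number = kappa)
}

#' Optical density change from raw intensities
#'
#' `dOD(t) = -log10(I(t) / I0)` with `I0` a per-channel baseline statistic.
#'
#' @param intensity Numeric vector or time-by-channel matrix of strictly
#'   positive raw intensities (arbitrary units).
#' @param baseline `"mean"` (whole-recording mean, the default) or
#'   `"first_n_seconds"`.
#' @param fs Sampling rate, required for `"first_n_seconds"`.
#' @param n_seconds Baseline window length for `"first_n_seconds"`.
#' @return Optical density change, same shape as the input.
#' @export
optical_density <- function(intensity, baseline = c("mean", "first_n_seconds"),
                            fs = NULL, n_seconds = 30) {
  baseline <- match.arg(baseline)
  x <- as.matrix(intensity)
  if (any(!is.finite(x)) || any(x <= 0)) {
    idx <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)[1, ]
    stop_invalid("non-positive intensity at time index ", idx[1],
                 ", channel ", idx[2])
  }
  i0 <- if (baseline == "mean") {
    colMeans(x)
  } else {
    if (is.null(fs)) stop_invalid("fs required for first_n_seconds baseline")
    colMeans(x[seq_len(min(nrow(x), round(fs * n_seconds))), , drop = FALSE])
  }
  od <- -log10(sweep(x, 2, i0, "/"))
  if (is.matrix(intensity)) od else drop(od)
}

#' Relative hemoglobin concentrations from optical density
#'
#' Inverts the pathlength-weighted extinction system per time point:
#' `(dHbO, dHbR) = 1000 * M^-1 (dOD_l1, dOD_l2)` with `M = eps * dpf *
#' distance`. Concentrations come out in uM given extinction coefficients
#' in 1/(mM*cm). The map is linear in its input.
#'
#' @param od1,od2 Optical density change at the first and second wavelength
#'   (vectors or time-by-channel matrices of matching shape).
#' @param table An [extinction_table()].
#' @return List with elements `HbO` and `HbR`, same shape as the inputs.
#' @export
concentrations_from_od <- function(od1, od2, table = extinction_table()) {
  stopifnot(inherits(table, "extinction_table"))
  Minv <- solve(table$M)
  list(HbO = 1000 * (Minv[1, 1] * od1 + Minv[1, 2] * od2),
       HbR = 1000 * (Minv[2, 1] * od1 + Minv[2, 2] * od2))
}

#' Forward MBLL: optical density from concentration changes
#'
#' Exact inverse of [concentrations_from_od()]; used by the synthetic
#' generator to emit raw-intensity recordings.
#'
#' @param hbo,hbr Concentration changes in uM (vector or matrix).
#' @inheritParams concentrations_from_od
#' @return List with `od1`, `od2`.
#' @export
od_from_concentrations <- function(hbo, hbr, table = extinction_table()) {
  M <- table$M / 1000
  list(od1 = M[1, 1] * hbo + M[1, 2] * hbr,
       od2 = M[2, 1] * hbo + M[2, 2] * hbr)
}
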