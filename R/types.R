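#' @keywords internal
"_PACKAGE"

## Gyromagnetic ratio of the proton, gamma/2pi, in Hz per microtesla.
GAMMA_HZ_PER_UT <- 42.5775

#' Convert a saturation amplitude in microtesla to rad/s
#'
#' Uses the proton gyromagnetic ratio gamma/2pi = 42.5775 Hz/uT, so 1 uT
#' corresponds to 267.52 rad/s.
#'
#' @param uT saturation amplitude B1 in microtesla.
#' @return angular nutation frequency omega1 in rad/s.
#' @export
omega1_rads <- function(uT) {
  if (any(uT < 0)) stop("saturation amplitude must be >= 0")
  2 * pi * GAMMA_HZ_PER_UT * uT
}

#' Convert frequency offsets from ppm to rad/s
#'
#' @param ppm offsets in ppm (positive downfield of water).
#' @param hz_per_ppm field-dependent conversion; 400 Hz/ppm reproduces the
#'   9.4 T acquisition grid in which 250 ppm corresponds to 100 kHz.
#' @return offsets in rad/s.
#' @export
ppm_to_rads <- function(ppm, hz_per_ppm = 400) 2 * pi * hz_per_ppm * ppm

#' Exchanging/coupling pool parameters
#'
#' One solute pool of the multi-pool exchange model: its size relative to
#' water, exchange rate towards water, chemical-shift offset, and intrinsic
#' relaxation rates.
#'
#' @param name pool label, e.g. "amide".
#' @param fs pool-size fraction relative to water (dimensionless, >= 0).
#' @param ksw solute-to-water exchange rate in 1/s (>= 0).
#' @param delta resonance offset from water in ppm (amide +3.5, NOE -3.5).
#' @param R1s solute longitudinal relaxation rate in 1/s (> 0).
#' @param R2s solute transverse relaxation rate in 1/s (> 0).
#' @return an object of class \code{cest_pool}.
#' @export
cest_pool <- function(name, fs, ksw, delta, R1s = 1, R2s) {
  stopifnot(is.character(name), length(name) == 1L)
  if (fs < 0) stop("fs must be >= 0")
  if (ksw < 0) stop("ksw must be >= 0")
  if (R1s <= 0 || R2s <= 0) stop("relaxation rates must be > 0")
  structure(list(name = name, fs = fs, ksw = ksw, delta = delta,
                 R1s = R1s, R2s = R2s), class = "cest_pool")
}

#' Bulk tissue state for Z-spectrum composition
#'
#' Holds the water and semisolid relaxation parameters and the two scaling
#' factors that modulate measured amine and semisolid-MT components when
#' composing partially synthetic Z-spectra.
#'
#' @param R1obs observed water longitudinal rate (1/s); if \code{NULL} it is
#'   derived from \code{R1w}, \code{R1M}, \code{fm} and \code{r_MT} via
#'   \code{\link{r1obs_from_components}}.
#' @param R1w intrinsic water longitudinal rate (1/s).
#' @param R2w water transverse rate (1/s).
#' @param R1M semisolid (MT) longitudinal rate (1/s).
#' @param fm semisolid pool-size ratio (dimensionless, 0 to 0.3).
#' @param r_amines scaling factor applied to the measured amine component.
#' @param r_MT scaling factor applied to the measured MT component.
#' @return an object of class \code{cest_tissue}.
#' @export
cest_tissue <- function(R1obs = NULL, R1w, R2w, R1M = 1, fm,
                        r_amines = 1, r_MT = 1) {
  if (R1w <= 0 || R2w <= 0 || R1M <= 0) stop("relaxation rates must be > 0")
  if (fm < 0 || fm > 0.3) stop("fm must lie in [0, 0.3]")
  if (r_amines < 0 || r_MT < 0) stop("scaling factors must be >= 0")
  if (is.null(R1obs)) R1obs <- r1obs_from_components(R1w, R1M, fm, r_MT)
  if (R1obs <= 0) stop("R1obs must be > 0")
  structure(list(R1obs = R1obs, R1w = R1w, R2w = R2w, R1M = R1M, fm = fm,
                 r_amines = r_amines, r_MT = r_MT), class = "cest_tissue")
}

#' Continuous-wave CEST acquisition parameters
#'
#' The default reproduces a 9.4 T acquisition: 5 s rectangular saturation at
#' 1 uT, an 87-point offset grid (+-4000, +-3500, +-3000 Hz and -2000 to
#' 2000 Hz in 50 Hz steps, i.e. +-10, +-8.75, +-7.5 and -5 to 5 ppm in
#' 0.125 ppm steps at 400 Hz/ppm) and a 250 ppm control offset for S0.
#'
#' @param B0 field strength in tesla (metadata only).
#' @param hz_per_ppm Hz per ppm used for all unit conversions.
#' @param b1_uT saturation amplitude in microtesla.
#' @param t_sat saturation duration in seconds.
#' @param TR repetition time in seconds (metadata only).
#' @param offsets ordered offset grid in ppm.
#' @param control_offset offset used for the unsaturated control image, in
#'   ppm; must be at least 100 ppm from water.
#' @return an object of class \code{cest_acquisition}.
#' @export
cest_acquisition <- function(B0 = 9.4, hz_per_ppm = 400, b1_uT = 1,
                             t_sat = 5, TR = 7,
                             offsets = default_offset_grid(),
                             control_offset = 250) {
  if (b1_uT < 0) stop("b1_uT must be >= 0")
  if (t_sat <= 0) stop("t_sat must be > 0")
  if (is.unsorted(offsets, strictly = TRUE))
    stop("offsets must be strictly increasing")
  if (abs(control_offset) < 100)
    stop("control offset must be |offset| >= 100 ppm")
  structure(list(B0 = B0, hz_per_ppm = hz_per_ppm, b1_uT = b1_uT,
                 omega1 = omega1_rads(b1_uT), t_sat = t_sat, TR = TR,
                 offsets = offsets, control_offset = control_offset),
            class = "cest_acquisition")
}

#' Default 87-point offset grid (ppm)
#'
#' Sparse far offsets at +-10, +-8.75, +-7.5 ppm plus a dense -5 to 5 ppm
#' segment in 0.125 ppm steps.
#'
#' @return numeric vector of 87 strictly increasing offsets in ppm.
#' @export
default_offset_grid <- function() {
  sort(c(-10, -8.75, -7.5, seq(-5, 5, by = 0.125), 7.5, 8.75, 10))
}

#' Z-spectrum container
#'
#' @param offsets offsets in ppm.
#' @param values normalized signals S/S0; values slightly above 1 are
#'   tolerated to accommodate noise.
#' @param meta named list of provenance metadata (source, seed, generating
#'   parameters).
#' @return an object of class \code{zspectrum}.
#' @export
zspectrum <- function(offsets, values, meta = list()) {
  stopifnot(length(offsets) == length(values))
  if (any(!is.finite(values))) stop("Z-spectrum values must be finite")
  if (any(values < 0) || any(values > 1.05))
    stop("Z-spectrum values must lie in [0, 1.05]")
  structure(list(offsets = as.numeric(offsets), values = as.numeric(values),
                 meta = meta), class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("Z-spectrum: %d offsets in [%.3g, %.3g] ppm, S/S0 in [%.4f, %.4f]\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              min(x$values), max(x$values)))
  if (!is.null(x$meta$source)) cat("  source:", x$meta$source, "\n")
  invisible(x)
}

#' @export
plot.zspectrum <- function(x, ...) {
  graphics::plot(x$offsets, x$values, type = "o", pch = 16, cex = 0.4,
                 xlim = rev(range(x$offsets)),
                 xlab = expression(Delta * omega ~ "(ppm)"),
                 ylab = expression(S / S[0]), ...)
  invisible(x)
}

.check_same_grid <- function(a, b, what = "spectra") {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-9)
    stop(what, " must share the same offset grid")
  invisible(TRUE)
}
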