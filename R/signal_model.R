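#' Lorentzian line
#'
#' \code{A / (1 + (x - center)^2 / (W/2)^2)}: peak amplitude \code{A} at
#' \code{center}, full width at half maximum \code{W}.
#'
#' @param A peak amplitude (dimensionless).
#' @param W full width at half maximum, in ppm.
#' @param center central frequency offset, in ppm.
#' @param offsets offsets at which to evaluate, in ppm.
#' @return numeric vector, the line evaluated at \code{offsets}.
#' @export
lorentzian_line <- function(A, W, center, offsets) {
  if (W <= 0) stop("W must be > 0")
  A / (1 + (offsets - center)^2 / (0.5 * W)^2)
}

#' Exchange-dependent relaxation R_ex for a slow-exchanging pool
#'
#' Closed-form rotating-frame relaxation contribution of a dilute pool in
#' the slow-exchange regime (amide, NOE):
#' \deqn{R_{ex}(\Delta\omega) = \frac{f_s k_{sw} \omega_1^2}
#'   {\omega_1^2 + (R_{2s}+k_{sw})k_{sw} +
#'    (\Delta\omega-\Delta)^2 k_{sw}/(R_{2s}+k_{sw})}}
#' with all frequencies in rad/s.
#'
#' @param pool a \code{\link{cest_pool}}.
#' @param omega1 saturation amplitude in rad/s (>= 0).
#' @param offsets offsets in ppm.
#' @param hz_per_ppm ppm-to-Hz conversion.
#' @return R_ex spectrum in 1/s on \code{offsets}.
#' @export
rex_slow <- function(pool, omega1, offsets, hz_per_ppm = 400) {
  stopifnot(inherits(pool, "cest_pool"))
  if (omega1 < 0) stop("omega1 must be >= 0")
  if (pool$ksw <= 0 || pool$R2s <= 0) stop("pool ksw and R2s must be > 0")
  dw <- ppm_to_rads(offsets, hz_per_ppm)
  dp <- ppm_to_rads(pool$delta, hz_per_ppm)
  k <- pool$ksw
  r2 <- pool$R2s
  pool$fs * k * omega1^2 /
    (omega1^2 + (r2 + k) * k + (dw - dp)^2 * k / (r2 + k))
}

#' Effective water relaxation rate in the rotating frame
#'
#' \code{R_eff = R1obs cos^2(theta) + R2w sin^2(theta)} with
#' \code{cos^2(theta) = dw^2 / (omega1^2 + dw^2)} (dw in rad/s), describing
#' direct water saturation.
#'
#' @param tissue a \code{\link{cest_tissue}}.
#' @inheritParams rex_slow
#' @return R_eff spectrum in 1/s.
#' @export
reff <- function(tissue, omega1, offsets, hz_per_ppm = 400) {
  stopifnot(inherits(tissue, "cest_tissue"))
  th <- sat_angle_terms(omega1, offsets, hz_per_ppm)
  tissue$R1obs * th$cos2 + tissue$R2w * th$sin2
}

sat_angle_terms <- function(omega1, offsets, hz_per_ppm = 400) {
  dw <- ppm_to_rads(offsets, hz_per_ppm)
  denom <- omega1^2 + dw^2
  list(cos2 = dw^2 / denom, sin2 = omega1^2 / denom)
}

#' Observed water longitudinal rate from water and semisolid rates
#'
#' \code{R1obs = (R1w + r_MT fm R1M) / (1 + r_MT fm)}: the pool-size-weighted
#' mean of the water and semisolid longitudinal rates, with the semisolid
#' fraction modulated by its scaling factor.
#'
#' @param R1w intrinsic water longitudinal rate (1/s).
#' @param R1M semisolid longitudinal rate (1/s).
#' @param fm semisolid pool-size ratio.
#' @param r_MT MT scaling factor.
#' @return R1obs in 1/s.
#' @export
r1obs_from_components <- function(R1w, R1M, fm, r_MT = 1) {
  if (R1w <= 0 || R1M <= 0) stop("rates must be > 0")
  if (fm < 0) stop("fm must be >= 0")
  (R1w + r_MT * fm * R1M) / (1 + r_MT * fm)
}

#' Compose a Z-spectrum by inverse summation of rotating-frame components
#'
#' The steady-state Z-spectrum of a multi-pool system is the inverse sum of
#' its rotating-frame relaxation components:
#' \deqn{S/S_0 = \frac{R_{1obs}\cos^2\theta}
#'  {R_{eff} + \frac{R_{ex}^{APT} + R_{ex}^{NOE} + r_{am} R_{ex}^{am}}
#'             {1 + r_{MT} f_m} + r_{MT} R_{ex}^{MT}}}
#' Any mixture of simulated and measured (Lorentzian-fitted) components can
#' be supplied, which is what makes partially synthetic data possible.
#'
#' @param components named list with numeric spectra \code{Reff},
#'   \code{Rex_apt}, \code{Rex_noe}, \code{Rex_amines}, \code{Rex_mt}, all on
#'   \code{offsets}; missing components default to zero.
#' @param tissue a \code{\link{cest_tissue}} supplying \code{R1obs},
#'   \code{fm} and the scaling factors.
#' @inheritParams rex_slow
#' @return a \code{\link{zspectrum}} whose \code{meta$R1rho} holds the full
#'   rotating-frame denominator (used by \code{\link{transient_signal}}).
#' @export
compose_zspectrum <- function(components, tissue, omega1, offsets,
                              hz_per_ppm = 400) {
  stopifnot(inherits(tissue, "cest_tissue"))
  n <- length(offsets)
  get_comp <- function(nm) {
    v <- components[[nm]]
    if (is.null(v)) return(rep(0, n))
    if (length(v) != n) stop("component '", nm, "' is not on the offset grid")
    v
  }
  Reff_ <- get_comp("Reff")
  dilut <- 1 + tissue$r_MT * tissue$fm
  r1rho <- Reff_ +
    get_comp("Rex_apt") / dilut +
    get_comp("Rex_noe") / dilut +
    tissue$r_amines * get_comp("Rex_amines") / dilut +
    tissue$r_MT * get_comp("Rex_mt")
  if (any(r1rho <= 0))
    stop("non-positive rotating-frame denominator: unphysical component set")
  th <- sat_angle_terms(omega1, offsets, hz_per_ppm)
  vals <- tissue$R1obs * th$cos2 / r1rho
  zspectrum(offsets, pmin(vals, 1.05),
            meta = list(source = "composed", R1rho = r1rho))
}

#' CESTR metric
#'
#' Reference-minus-label difference \code{S_ref/S0 - S_lab/S0}.
#'
#' @param s_ref,s_lab normalized reference and label spectra on a common grid.
#' @param offsets optional common grid (used only for validation).
#' @return CESTR spectrum (dimensionless).
#' @export
cestr <- function(s_ref, s_lab, offsets = NULL) {
  if (length(s_ref) != length(s_lab))
    stop("S_ref and S_lab must share the same offset grid")
  s_ref - s_lab
}

#' AREX metric
#'
#' Inverse difference with T1 normalization,
#' \code{(S0/S_lab - S0/S_ref) R1obs (1 + fm)}, which approximates the
#' rotating-frame exchange rate R_ex of the labelled pool while removing
#' spillover and T1 shine-through.
#'
#' @param s_ref,s_lab normalized (S/S0) reference and label spectra.
#' @param R1obs observed water longitudinal rate (1/s).
#' @param fm semisolid pool-size ratio.
#' @return AREX spectrum in 1/s.
#' @export
arex <- function(s_ref, s_lab, R1obs, fm) {
  if (length(s_ref) != length(s_lab))
    stop("S_ref and S_lab must share the same offset grid")
  if (any(s_ref <= 0) || any(s_lab <= 0))
    stop("AREX undefined where the normalized signal is zero")
  (1 / s_lab - 1 / s_ref) * R1obs * (1 + fm)
}

#' Non-steady-state signal from a steady-state Z-spectrum
#'
#' Mono-exponential approach of the saturated signal to its steady state:
#' \code{S_nss/S0 = (1 - S/S0) exp(-R1rho t_p) + S/S0}, where \code{R1rho}
#' is the full rotating-frame denominator of the composed spectrum.
#'
#' @param z a \code{\link{zspectrum}} at steady state.
#' @param R1rho rotating-frame relaxation spectrum (1/s), e.g.
#'   \code{z$meta$R1rho} from \code{\link{compose_zspectrum}}.
#' @param t_p total saturation time in seconds (>= 0).
#' @return a \code{\link{zspectrum}} after \code{t_p} of saturation.
#' @export
transient_signal <- function(z, R1rho = z$meta$R1rho, t_p) {
  stopifnot(inherits(z, "zspectrum"))
  if (t_p < 0) stop("t_p must be >= 0")
  if (is.null(R1rho) || any(R1rho <= 0)) stop("R1rho must be > 0")
  .check_same_grid(seq_along(R1rho), seq_along(z$values), "R1rho and spectrum")
  vals <- (1 - z$values) * exp(-R1rho * t_p) + z$values
  zspectrum(z$offsets, vals, meta = c(z$meta, list(t_p = t_p)))
}
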