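#' Assemble a multi-pool system
#'
#' A pool set is one water pool plus any number of solute pools, each
#' exchanging with water only (star topology). The default seven-pool brain
#' model holds amide (+3.5 ppm), amine (+3 ppm), guanidinium (+2 ppm),
#' water, NOE(-1.6), NOE(-3.5) and a semisolid MT pool.
#'
#' @param water a \code{\link{cest_pool}} with \code{fs = 1} describing
#'   water relaxation (its \code{ksw} is ignored).
#' @param ... solute \code{\link{cest_pool}} objects with unique names.
#' @return an object of class \code{pool_set}.
#' @export
pool_set <- function(water, ...) {
  solutes <- list(...)
  if (length(solutes) == 1L && is.list(solutes[[1]]) &&
      !inherits(solutes[[1]], "cest_pool"))
    solutes <- solutes[[1]]
  stopifnot(inherits(water, "cest_pool"))
  if (abs(water$fs - 1) > 1e-12) stop("water pool must have fs = 1")
  nms <- vapply(solutes, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("solute pool names must be unique")
  names(solutes) <- nms
  structure(list(water = water, solutes = solutes), class = "pool_set")
}

#' @export
print.pool_set <- function(x, ...) {
  cat(sprintf("pool_set: water + %d solute pool(s)\n", length(x$solutes)))
  for (p in x$solutes)
    cat(sprintf("  %-12s fs=%.2e ksw=%.3g /s delta=%+.2f ppm T2s=%.3g s\n",
                p$name, p$fs, p$ksw, p$delta, 1 / p$R2s))
  invisible(x)
}

## Build the constant part of the Bloch-McConnell generator dM/dt = A M + b.
## State order: (x, y, z) per pool, water first. Offset-dependent entries
## (the +-theta precession terms) are patched per offset in the solver.
.bm_system <- function(pools) {
  all_pools <- c(list(pools$water), unname(pools$solutes))
  n <- length(all_pools)
  fs <- vapply(all_pools, function(p) p$fs, numeric(1))
  ksw <- vapply(all_pools, function(p) p$ksw, numeric(1))
  ksw[1] <- 0
  kws <- fs * ksw                      # water -> solute, detailed balance
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  ix <- function(i) 3 * (i - 1) + 1    # x row of pool i
  for (i in seq_len(n)) {
    p <- all_pools[[i]]
    kout <- if (i == 1) sum(kws) else ksw[i]
    xi <- ix(i)
    A[xi, xi] <- -p$R2s - kout
    A[xi + 1, xi + 1] <- -p$R2s - kout
    A[xi + 2, xi + 2] <- -p$R1s - kout
    b[xi + 2] <- p$R1s * fs[i]
    if (i > 1) {                       # exchange with water, componentwise
      for (c in 0:2) {
        A[xi + c, 1 + c] <- kws[i]
        A[1 + c, xi + c] <- ksw[i]
      }
    }
  }
  list(A = A, b = b, n = n,
       delta = vapply(all_pools, function(p) p$delta, numeric(1)),
       M0 = fs)
}

## Solve one offset. theta_i = 2*pi*hz*(delta_i - offset) enters the x/y
## precession block; omega1 couples y and z of every pool.
.bm_solve_offset <- function(sys, offset_ppm, omega1, hz_per_ppm, mode,
                             t_sat) {
  A <- sys$A
  n <- sys$n
  theta <- 2 * pi * hz_per_ppm * (sys$delta - offset_ppm)
  for (i in seq_len(n)) {
    xi <- 3 * (i - 1) + 1
    A[xi, xi + 1] <- A[xi, xi + 1] + theta[i]
    A[xi + 1, xi] <- A[xi + 1, xi] - theta[i]
    A[xi + 1, xi + 2] <- A[xi + 1, xi + 2] + omega1
    A[xi + 2, xi + 1] <- A[xi + 2, xi + 1] - omega1
  }
  mss <- tryCatch(solve(A, -sys$b),
                  error = function(e) stop("singular Bloch-McConnell system: ",
                                           conditionMessage(e)))
  if (mode == "steady") return(mss[3])
  m0 <- numeric(3 * n)
  m0[seq(3, 3 * n, by = 3)] <- sys$M0
  mt <- mss + as.numeric(Matrix::expm(A * t_sat) %*% (m0 - mss))
  mt[3]
}

#' Simulate a Z-spectrum with the Bloch-McConnell equations
#'
#' Propagates the coupled magnetization of all pools under constant
#' rectangular saturation. The constant-coefficient affine system is solved
#' exactly: steady mode solves the stationarity condition directly, while
#' transient mode uses the matrix exponential of the homogenized system,
#' starting from thermal equilibrium. The signal is the water longitudinal
#' magnetization at the end of saturation, normalized by the same simulation
#' at the control offset.
#'
#' @param pools a \code{\link{pool_set}}.
#' @param acq a \code{\link{cest_acquisition}}.
#' @param mode \code{"steady"} (default) or \code{"transient"}.
#' @return a \code{\link{zspectrum}}.
#' @export
simulate_zspectrum <- function(pools, acq, mode = c("steady", "transient")) {
  stopifnot(inherits(pools, "pool_set"), inherits(acq, "cest_acquisition"))
  mode <- match.arg(mode)
  sys <- .bm_system(pools)
  sig <- vapply(acq$offsets, function(off)
    .bm_solve_offset(sys, off, acq$omega1, acq$hz_per_ppm, mode, acq$t_sat),
    numeric(1))
  s0 <- .bm_solve_offset(sys, acq$control_offset, acq$omega1, acq$hz_per_ppm,
                         mode, acq$t_sat)
  vals <- sig / s0
  zspectrum(acq$offsets, pmin(pmax(vals, 0), 1.05),
            meta = list(source = "bloch-simulated", mode = mode))
}

#' Ground-truth APT spectrum by paired simulation
#'
#' The ground-truth CESTR-quantified APT spectrum is the difference between
#' two simulated Z-spectra, without and with the amide pool. Its amplitude
#' \code{A_true} is read at the amide resonance and its width \code{W_true}
#' as the full width at half maximum by linear interpolation of the half-max
#' crossings adjacent to the peak.
#'
#' @param pools a \code{\link{pool_set}} containing a pool named
#'   \code{amide_pool}.
#' @param acq a \code{\link{cest_acquisition}}.
#' @param amide_pool name of the amide entry (default "amide").
#' @param mode simulation mode passed to \code{\link{simulate_zspectrum}}.
#' @return list with \code{offsets}, \code{spectrum} (CESTR), \code{A_true},
#'   \code{W_true} (ppm) and the two underlying spectra \code{z_lab},
#'   \code{z_ref}.
#' @export
ground_truth_apt <- function(pools, acq, amide_pool = "amide",
                             mode = "steady") {
  if (!amide_pool %in% names(pools$solutes))
    stop("pool set has no '", amide_pool, "' pool")
  z_lab <- simulate_zspectrum(pools, acq, mode)
  pools_ref <- pools
  pools_ref$solutes[[amide_pool]]$fs <- 0
  pools_ref$solutes[[amide_pool]]$ksw <- max(pools_ref$solutes[[amide_pool]]$ksw,
                                             1e-9)
  z_ref <- simulate_zspectrum(pools_ref, acq, mode)
  spec <- cestr(z_ref$values, z_lab$values)
  center <- pools$solutes[[amide_pool]]$delta
  aw <- peak_amplitude_width(acq$offsets, spec, center)
  list(offsets = acq$offsets, spectrum = spec,
       A_true = aw$A, W_true = aw$W, z_lab = z_lab, z_ref = z_ref)
}

#' Peak amplitude and FWHM of a sampled spectrum
#'
#' Amplitude is the spectrum value at the grid point nearest \code{center};
#' the width is obtained from the two half-maximum crossings adjacent to the
#' peak, each located by linear interpolation between neighbouring grid
#' points. When a crossing lies beyond the grid the nearest grid edge is
#' used, which truncates very broad peaks.
#'
#' @param offsets grid in ppm.
#' @param spectrum sampled spectrum.
#' @param center nominal peak position in ppm.
#' @return list with \code{A}, \code{W} (ppm; 0 when \code{A <= 0}) and the
#'   index of the peak sample.
#' @export
peak_amplitude_width <- function(offsets, spectrum, center = 3.5) {
  i0 <- which.min(abs(offsets - center))
  A <- spectrum[i0]
  if (!is.finite(A) || A <= 0)
    return(list(A = max(A, 0), W = 0, index = i0))
  half <- A / 2
  n <- length(offsets)
  left <- offsets[1]
  for (i in seq(i0, 2)) {
    if (spectrum[i - 1] < half && spectrum[i] >= half) {
      f <- (half - spectrum[i - 1]) / (spectrum[i] - spectrum[i - 1])
      left <- offsets[i - 1] + f * (offsets[i] - offsets[i - 1])
      break
    }
  }
  right <- offsets[n]
  for (i in seq(i0, n - 1)) {
    if (spectrum[i + 1] < half && spectrum[i] >= half) {
      f <- (spectrum[i] - half) / (spectrum[i] - spectrum[i + 1])
      right <- offsets[i] + f * (offsets[i + 1] - offsets[i])
      break
    }
  }
  list(A = A, W = right - left, index = i0)
}

#' Default physiological parameter ranges for the seven-pool brain model
#'
#' Literature-plausible 9.4 T ranges used both by the tissue-mimicking
#' sampler and (for the simulated components) by the partially synthetic
#' builder. Each entry is a \code{c(min, max)} pair; times in seconds.
#'
#' @return nested named list of ranges.
#' @export
default_pool_ranges <- function() {
  list(
    water = list(T1 = c(1.5, 2.2), T2 = c(0.030, 0.070)),
    amide = list(fs = c(0.2e-3, 3e-3), ksw = c(10, 150),
                 T2s = c(0.005, 0.030), delta = 3.5),
    amine = list(fs = c(0.5e-3, 5e-3), ksw = c(1000, 6000),
                 T2s = c(0.004, 0.010), delta = 3.0),
    guanidinium = list(fs = c(0.2e-3, 2e-3), ksw = c(100, 1000),
                       T2s = c(0.005, 0.020), delta = 2.0),
    noe16 = list(fs = c(0.2e-3, 2e-3), ksw = c(10, 50),
                 T2s = c(0.001, 0.005), delta = -1.6),
    noe35 = list(fs = c(2e-3, 20e-3), ksw = c(10, 50),
                 T2s = c(0.0002, 0.001), delta = -3.5),
    mt = list(fm = c(0.03, 0.15), ksw = c(20, 60),
              T2s = c(5e-6, 15e-6), delta = -2.3, R1M = 1)
  )
}

## One uniform draw per scalar parameter; range entries of length 1 are
## constants, length-2 entries are (min, max).
.draw_ranges <- function(ranges) {
  rapply(ranges, function(r) {
    if (length(r) == 1L) r
    else if (length(r) == 2L) stats::runif(1, r[1], r[2])
    else stop("range entries must have length 1 or 2")
  }, how = "replace")
}

#' Draw parameter sets from a range configuration
#'
#' @param ranges nested list of \code{c(min, max)} ranges (scalars are held
#'   fixed), e.g. \code{\link{default_pool_ranges}}.
#' @param n number of independent draws (>= 1).
#' @param seed integer seed; the draw sequence is fully reproducible.
#' @return list of \code{n} nested parameter lists.
#' @export
draw_parameters <- function(ranges, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (length(ranges) == 0) stop("empty parameter ranges")
  set.seed(seed)
  lapply(seq_len(n), function(i) .draw_ranges(ranges))
}

## Build the seven-pool set for one parameter draw. drop_amide removes the
## amide pool (used for the paired ground-truth simulation).
.pools_from_draw <- function(par) {
  water <- cest_pool("water", 1, 0, 0, R1s = 1 / par$water$T1,
                     R2s = 1 / par$water$T2)
  mk <- function(nm, p) cest_pool(nm, p$fs, p$ksw, p$delta, R1s = 1,
                                  R2s = 1 / p$T2s)
  mt <- cest_pool("mt", par$mt$fm, par$mt$ksw, par$mt$delta,
                  R1s = par$mt$R1M, R2s = 1 / par$mt$T2s)
  pool_set(water,
           mk("amide", par$amide), mk("amine", par$amine),
           mk("guanidinium", par$guanidinium),
           mk("noe16", par$noe16), mk("noe35", par$noe35), mt)
}

#' Sample tissue-mimicking Z-spectra with ground truth
#'
#' Draws \code{n} seven-pool parameter sets uniformly within \code{ranges},
#' simulates each with the Bloch-McConnell equations under \code{acq}, and
#' pairs every spectrum with its ground-truth APT spectrum (paired
#' simulation with/without the amide pool).
#'
#' @inheritParams draw_parameters
#' @param acq a \code{\link{cest_acquisition}}.
#' @param mode simulation mode.
#' @return list of records, each with \code{z} (zspectrum), \code{truth}
#'   (see \code{\link{ground_truth_apt}}), \code{tissue}
#'   (a \code{\link{cest_tissue}} with \code{R1obs} from the draw) and
#'   \code{params} (the generating draw).
#' @export
sample_tissue_mimicking <- function(ranges = default_pool_ranges(), n,
                                    seed = 1L, acq = cest_acquisition(),
                                    mode = "steady") {
  draws <- draw_parameters(ranges, n, seed)
  lapply(draws, function(par) {
    pools <- .pools_from_draw(par)
    gt <- ground_truth_apt(pools, acq, mode = mode)
    tissue <- cest_tissue(R1w = 1 / par$water$T1, R2w = 1 / par$water$T2,
                          R1M = par$mt$R1M, fm = par$mt$fm)
    list(z = gt$z_lab, truth = gt, tissue = tissue, params = par)
  })
}
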