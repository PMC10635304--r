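#' Default parameter ranges for partially synthetic training data
#'
#' Ranges of the simulated components (amide, the two NOE pools, water
#' relaxation), the amplitude scaling factors applied to the measured amine
#' and MT components, and the Gaussian noise level added to training
#' features. The simulated-component ranges coincide with
#' \code{\link{default_pool_ranges}} so the training corpus covers the
#' tissue-mimicking test bed.
#'
#' @return nested named list of \code{c(min, max)} ranges.
#' @export
default_synth_ranges <- function() {
  pr <- default_pool_ranges()
  list(water = pr$water, amide = pr$amide, noe16 = pr$noe16,
       noe35 = pr$noe35,
       r_amines = c(0.2, 3), r_MT = c(0.2, 3),
       R1M = 1, noise_sd = 0.01)
}

## Compose one label/reference pair from a parameter draw plus measured
## amine/MT spectra; returns the training record.
.compose_record <- function(par, measured, acq, loss_window = c(2, 5)) {
  tissue <- cest_tissue(R1w = 1 / par$water$T1, R2w = 1 / par$water$T2,
                        R1M = par$R1M, fm = measured$fm,
                        r_amines = par$r_amines, r_MT = par$r_MT)
  mk <- function(p) cest_pool("p", p$fs, p$ksw, p$delta, R2s = 1 / p$T2s)
  rex_apt <- rex_slow(mk(par$amide), acq$omega1, acq$offsets, acq$hz_per_ppm)
  rex_noe <- rex_slow(mk(par$noe16), acq$omega1, acq$offsets, acq$hz_per_ppm) +
    rex_slow(mk(par$noe35), acq$omega1, acq$offsets, acq$hz_per_ppm)
  comps <- list(Reff = reff(tissue, acq$omega1, acq$offsets, acq$hz_per_ppm),
                Rex_apt = rex_apt, Rex_noe = rex_noe,
                Rex_amines = measured$Rex_amines,
                Rex_mt = measured$Rex_mt)
  z_lab <- compose_zspectrum(comps, tissue, acq$omega1, acq$offsets,
                             acq$hz_per_ppm)
  comps$Rex_apt <- NULL
  z_ref <- compose_zspectrum(comps, tissue, acq$omega1, acq$offsets,
                             acq$hz_per_ppm)
  truth <- cestr(z_ref$values, z_lab$values)
  aw <- peak_amplitude_width(acq$offsets, truth, par$amide$delta)
  win <- acq$offsets >= loss_window[1] & acq$offsets <= loss_window[2]
  list(features = z_lab$values, z_ref = z_ref$values,
       target_A = aw$A, target_W = aw$W,
       truth_offsets = acq$offsets[win], truth_spectrum = truth[win],
       truth_full = truth, gen_params = par)
}

#' Build partially synthetic training records
#'
#' Each record combines simulated amide/NOE/direct-saturation components
#' (drawn from \code{ranges}) with the measured amine and MT components via
#' the inverse-summation composer. The ground-truth APT spectrum is the
#' CESTR of the label/reference pair composed with/without the amide
#' component; targets are its amplitude at the amide resonance and its
#' FWHM.
#'
#' @param measured a \code{\link{extract_measured_components}} result whose
#'   grid matches \code{acq}.
#' @param ranges range configuration, see
#'   \code{\link{default_synth_ranges}}.
#' @param acq a \code{\link{cest_acquisition}}.
#' @param n number of records.
#' @param seed integer seed.
#' @param loss_window ppm window over which the stored truth spectrum is
#'   retained (the full spectrum is recomputable from \code{gen_params}).
#' @return object of class \code{training_set}: list of records, with
#'   attributes \code{offsets}, \code{seed}, \code{ranges}.
#' @export
build_partial_synthetic <- function(measured, ranges = default_synth_ranges(),
                                    acq = cest_acquisition(), n, seed = 1L,
                                    loss_window = c(2, 5)) {
  stopifnot(inherits(measured, "measured_components"))
  .check_same_grid(measured$offsets, acq$offsets, "measured components")
  draws <- draw_parameters(ranges, n, seed)
  recs <- lapply(draws, .compose_record, measured = measured, acq = acq,
                 loss_window = loss_window)
  structure(recs, class = "training_set", offsets = acq$offsets,
            seed = seed, kind = "partial")
}

#' Build fully synthetic training records
#'
#' Bloch-McConnell-simulated records over the seven-pool model. Variant
#' \code{"type1"} ties the amine and MT pool sizes to the scaling factors
#' (amine \code{fs = 0.003 r_amine}, MT \code{fs = 0.1 r_MT}) so the corpus
#' is size-matched with a partially synthetic one; \code{"type2"}
#' additionally triples the corpus by re-simulating each draw with
#' re-drawn guanidinium pool sizes.
#'
#' @param ranges range configuration as in
#'   \code{\link{default_pool_ranges}} plus \code{r_amines}/\code{r_MT}
#'   entries (see \code{\link{default_synth_ranges}}).
#' @inheritParams build_partial_synthetic
#' @param variant \code{"type1"} or \code{"type2"}.
#' @return a \code{training_set} (length \code{n} for type1, \code{3n} for
#'   type2).
#' @export
build_fully_synthetic <- function(ranges = default_full_synth_ranges(),
                                  acq = cest_acquisition(), n, seed = 1L,
                                  variant = c("type1", "type2"),
                                  loss_window = c(2, 5)) {
  variant <- match.arg(variant)
  draws <- draw_parameters(ranges, n, seed)
  draws <- lapply(draws, function(par) {
    par$amine$fs <- 0.003 * par$r_amines
    par$mt$fm <- 0.1 * par$r_MT
    par
  })
  if (variant == "type2") {
    guan_range <- ranges$guanidinium$fs
    extra <- unlist(lapply(seq_along(draws), function(i) {
      set.seed(seed + 104729L + i)
      lapply(1:2, function(j) {
        par <- draws[[i]]
        par$guanidinium$fs <- stats::runif(1, guan_range[1], guan_range[2])
        par
      })
    }), recursive = FALSE)
    draws <- c(draws, extra)
  }
  win_fun <- function(par) {
    pools <- .pools_from_draw(par)
    gt <- ground_truth_apt(pools, acq)
    win <- acq$offsets >= loss_window[1] & acq$offsets <= loss_window[2]
    list(features = gt$z_lab$values, z_ref = gt$z_ref$values,
         target_A = gt$A_true, target_W = gt$W_true,
         truth_offsets = acq$offsets[win], truth_spectrum = gt$spectrum[win],
         truth_full = gt$spectrum, gen_params = par)
  }
  recs <- lapply(draws, win_fun)
  structure(recs, class = "training_set", offsets = acq$offsets,
            seed = seed, kind = paste0("full-", variant))
}

#' Default ranges for fully synthetic data
#'
#' Seven-pool ranges plus scaling-factor ranges used by
#' \code{\link{build_fully_synthetic}}.
#'
#' @return nested named list.
#' @export
default_full_synth_ranges <- function() {
  pr <- default_pool_ranges()
  pr$r_amines <- c(0.2, 3)
  pr$r_MT <- c(0.2, 3)
  pr$noise_sd <- 0.01
  pr
}

#' @export
`[.training_set` <- function(x, i) {
  out <- unclass(x)[i]
  attributes(out) <- c(attributes(out),
                       attributes(x)[c("class", "offsets", "seed", "kind")])
  out
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set (%s): %d records, %d-point grid, seed %s\n",
              attr(x, "kind"), length(x), length(attr(x, "offsets")),
              attr(x, "seed")))
  a <- vapply(x, function(r) r$target_A, numeric(1))
  cat(sprintf("  target A in [%.4g, %.4g], W in [%.3g, %.3g] ppm\n",
              min(a), max(a),
              min(vapply(x, function(r) r$target_W, numeric(1))),
              max(vapply(x, function(r) r$target_W, numeric(1)))))
  invisible(x)
}

#' Add Gaussian noise to the feature spectra of a training set
#'
#' Noise is applied to the features (label Z-spectra) only; targets and
#' truth spectra are untouched, emulating measurement noise on top of
#' noise-free ground truth.
#'
#' @param records a \code{training_set}.
#' @param sd noise standard deviation (>= 0); 0 returns the input
#'   bit-identically.
#' @param seed integer seed.
#' @return the training set with noisy features.
#' @export
add_noise <- function(records, sd = 0.01, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(records)
  set.seed(seed)
  out <- lapply(records, function(r) {
    r$features <- r$features + stats::rnorm(length(r$features), 0, sd)
    r
  })
  attributes(out) <- attributes(records)
  out
}

#' Pair-averaging augmentation
#'
#' Expands a set of k Z-spectra by the arithmetic mean of every unordered
#' pair, yielding k(k-1)/2 additional spectra alongside the originals.
#'
#' @param spectra list of \code{\link{zspectrum}} objects (or plain numeric
#'   vectors) on a common grid; at least 2.
#' @return list with \code{originals} and \code{averages}; total size
#'   \code{k + k(k-1)/2}.
#' @export
augment_pair_average <- function(spectra) {
  k <- length(spectra)
  if (k < 2) stop("need at least 2 spectra")
  vals <- lapply(spectra, function(s) if (inherits(s, "zspectrum")) s$values else s)
  len <- lengths(vals)
  if (any(len != len[1])) stop("spectra must share the same offset grid")
  idx <- utils::combn(k, 2)
  averages <- lapply(seq_len(ncol(idx)), function(j)
    (vals[[idx[1, j]]] + vals[[idx[2, j]]]) / 2)
  list(originals = vals, averages = averages)
}

#' Number of pair averages produced by augmentation
#'
#' @param k number of input spectra.
#' @return \code{k(k-1)/2}.
#' @export
pair_average_count <- function(k) as.numeric(k) * (k - 1) / 2

#' Feature and target matrices of a training set
#'
#' @param records a \code{training_set}.
#' @return list with \code{X} (n x p feature matrix on the full grid),
#'   \code{Y} (n x 2 matrix of A and W) and \code{offsets}.
#' @export
training_matrices <- function(records) {
  X <- do.call(rbind, lapply(records, function(r) r$features))
  Y <- cbind(A = vapply(records, function(r) r$target_A, numeric(1)),
             W = vapply(records, function(r) r$target_W, numeric(1)))
  list(X = X, Y = Y, offsets = attr(records, "offsets"))
}
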