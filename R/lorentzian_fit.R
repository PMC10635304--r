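#' Default starts and bounds for the six-pool Lorentzian fit
#'
#' One row per pool (amide, amine, water, NOE(-1.6), NOE(-3.5), MT) with
#' starting value, lower and upper bound for the amplitude \code{A},
#' width \code{W} (ppm) and center \code{delta} (ppm). The amine pool lumps
#' amine, guanidinium and hydroxyl protons into a single line near 2 ppm;
#' the semisolid MT line is allowed widths of 20-100 ppm.
#'
#' @return data.frame with columns \code{pool, A0, A_lo, A_hi, W0, W_lo,
#'   W_hi, d0, d_lo, d_hi}.
#' @export
lorentzian_fit_config <- function() {
  data.frame(
    pool = c("amide", "amine", "water", "noe16", "noe35", "mt"),
    A0  = c(0.025, 0.10, 0.80, 0.02, 0.10, 0.10),
    A_lo = c(0, 0, 0.2, 0, 0, 0),
    A_hi = c(0.2, 0.3, 1.0, 0.2, 0.3, 0.5),
    W0  = c(1.5, 4, 2, 2, 4, 40),
    W_lo = c(0.5, 1, 0.5, 0.5, 2, 20),
    W_hi = c(3, 10, 4, 4, 8, 100),
    d0  = c(3.5, 2.0, 0.0, -1.6, -3.5, -2.3),
    d_lo = c(3.4, 1.5, -0.1, -1.8, -3.8, -3.3),
    d_hi = c(3.6, 2.5, 0.1, -1.4, -3.2, -1.3),
    stringsAsFactors = FALSE
  )
}

.multipool_model <- function(theta, offsets) {
  ## theta: (A1,W1,d1, A2,W2,d2, ...) in config row order
  m <- matrix(theta, nrow = 3)
  s <- rep(1, length(offsets))
  for (j in seq_len(ncol(m)))
    s <- s - lorentzian_line(m[1, j], m[2, j], m[3, j], offsets)
  s
}

## Analytic Jacobian of the residual r = data - (1 - sum L): dr/dtheta = dL.
.multipool_jacobian <- function(theta, offsets) {
  m <- matrix(theta, nrow = 3)
  J <- matrix(0, length(offsets), length(theta))
  for (j in seq_len(ncol(m))) {
    A <- m[1, j]; W <- m[2, j]; d <- m[3, j]
    u <- (offsets - d) / (0.5 * W)
    den <- (1 + u^2)
    J[, 3 * j - 2] <- 1 / den
    J[, 3 * j - 1] <- A * 2 * u^2 / W / den^2
    J[, 3 * j] <- A * 2 * u / (0.5 * W) / den^2
  }
  J
}

#' Fit a six-pool Lorentzian model to a Z-spectrum
#'
#' Least-squares decomposition of a Z-spectrum as
#' \code{S/S0 = 1 - sum_i L_i} with one Lorentzian line per pool
#' (amide, amine, water, NOE(-1.6), NOE(-3.5), MT). The bounded
#' Levenberg-Marquardt solver minimizes the RMS residual; the fit is
#' deterministic given the data and configuration.
#'
#' @param z a \code{\link{zspectrum}} covering both sides of water, or a
#'   list/data.frame with \code{offsets} and \code{values}.
#' @param config starts/bounds table, see
#'   \code{\link{lorentzian_fit_config}}; rows may be given in any order.
#' @param max_rms error if the converged RMS residual exceeds this ceiling
#'   (\code{Inf} disables the check).
#' @return an object of class \code{lorentzian_fit} with elements
#'   \code{components} (data.frame pool/A/W/delta), \code{rms_residual},
#'   \code{offsets}, \code{data}, \code{fitted}, \code{config}.
#' @export
fit_multipool <- function(z, config = lorentzian_fit_config(),
                          max_rms = Inf) {
  offsets <- z$offsets
  values <- z$values
  if (length(offsets) < 24)
    stop("need at least 24 points to fit 18 parameters")
  canonical <- c("amide", "amine", "water", "noe16", "noe35", "mt")
  if (!setequal(config$pool, canonical))
    stop("config must contain exactly the six pools: ",
         paste(canonical, collapse = ", "))
  config <- config[match(canonical, config$pool), ]
  inside <- config$d0 >= min(offsets) & config$d0 <= max(offsets)
  if (!all(inside))
    stop("spectrum does not cover pool center(s): ",
         paste(config$pool[!inside], collapse = ", "))
  start <- as.numeric(t(config[, c("A0", "W0", "d0")]))
  lower <- as.numeric(t(config[, c("A_lo", "W_lo", "d_lo")]))
  upper <- as.numeric(t(config[, c("A_hi", "W_hi", "d_hi")]))
  res_fn <- function(theta) values - .multipool_model(theta, offsets)
  jac_fn <- function(theta) .multipool_jacobian(theta, offsets)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = res_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, gtol = 0,
                              maxiter = 1000, maxfev = 20000))
  theta <- fit$par
  fitted <- .multipool_model(theta, offsets)
  rms <- sqrt(mean((values - fitted)^2))
  if (fit$info == 0 || fit$info == 9)
    stop("six-pool fit failed to converge (info=", fit$info,
         ", rms=", signif(rms, 4), ")")
  if (rms > max_rms)
    stop("six-pool fit residual ", signif(rms, 4),
         " exceeds ceiling ", max_rms)
  m <- matrix(theta, nrow = 3,
              dimnames = list(c("A", "W", "delta"), canonical))
  comps <- data.frame(pool = canonical, A = m["A", ], W = m["W", ],
                      delta = m["delta", ], row.names = NULL)
  structure(list(components = comps, rms_residual = rms,
                 offsets = offsets, data = values, fitted = fitted,
                 config = config, solver_info = fit$info,
                 niter = fit$niter),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat("Six-pool Lorentzian fit\n")
  print(format(x$components, digits = 4), row.names = FALSE)
  cat(sprintf("RMS residual: %.3e (%d points)\n",
              x$rms_residual, length(x$offsets)))
  invisible(x)
}

#' @export
coef.lorentzian_fit <- function(object, ...) {
  m <- t(as.matrix(object$components[, c("A", "W", "delta")]))
  colnames(m) <- object$components$pool
  m
}

#' @export
fitted.lorentzian_fit <- function(object, ...) object$fitted

#' @export
residuals.lorentzian_fit <- function(object, ...) object$data - object$fitted

#' @export
predict.lorentzian_fit <- function(object, offsets = object$offsets, ...) {
  theta <- as.numeric(coef(object))
  .multipool_model(theta, offsets)
}

#' @export
summary.lorentzian_fit <- function(object, ...) {
  out <- list(components = object$components,
              rms_residual = object$rms_residual,
              n = length(object$offsets), niter = object$niter)
  class(out) <- "summary.lorentzian_fit"
  out
}

#' @export
print.summary.lorentzian_fit <- function(x, ...) {
  print(format(x$components, digits = 4), row.names = FALSE)
  cat(sprintf("RMS residual %.3e over %d points (%d iterations)\n",
              x$rms_residual, x$n, x$niter))
  invisible(x)
}

#' @export
plot.lorentzian_fit <- function(x, ...) {
  graphics::plot(x$offsets, x$data, pch = 16, cex = 0.4,
                 xlim = rev(range(x$offsets)),
                 xlab = expression(Delta * omega ~ "(ppm)"),
                 ylab = expression(S / S[0]), ...)
  graphics::lines(x$offsets, x$fitted, col = "red3")
  invisible(x)
}

#' Evaluate one fitted Lorentzian component on a grid
#'
#' @param fit a \code{\link{fit_multipool}} result.
#' @param pool pool name.
#' @param offsets grid in ppm (defaults to the fit grid).
#' @return the component line L_p on the grid.
#' @export
fit_component <- function(fit, pool, offsets = fit$offsets) {
  row <- fit$components[fit$components$pool == pool, ]
  if (nrow(row) != 1) stop("unknown pool: ", pool)
  lorentzian_line(row$A, row$W, row$delta, offsets)
}

#' Save / load a fit result as JSON
#'
#' Serializes the component table, residual and configuration. The model
#' spectrum is recomputable from the components, so spectra are not stored.
#'
#' @param fit a \code{\link{fit_multipool}} result.
#' @param path file path.
#' @return \code{load_fit_json} returns a \code{lorentzian_fit} whose
#'   \code{offsets}/\code{data}/\code{fitted} are restored from the stored
#'   grid and components.
#' @export
save_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lorentzian_fit"))
  jsonlite::write_json(list(components = fit$components,
                            rms_residual = fit$rms_residual,
                            offsets = fit$offsets, data = fit$data,
                            config = fit$config),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fit_json
#' @export
load_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- as.numeric(t(as.matrix(obj$components[, c("A", "W", "delta")])))
  structure(list(components = obj$components,
                 rms_residual = obj$rms_residual,
                 offsets = obj$offsets, data = obj$data,
                 fitted = .multipool_model(theta, obj$offsets),
                 config = obj$config, solver_info = NA, niter = NA),
            class = "lorentzian_fit")
}

#' Label and per-pool reference spectra from a fit
#'
#' \code{S_lab/S0 = 1 - sum_i L_i}; for each pool p the reference
#' \code{S_ref,p/S0 = 1 - sum_{i != p} L_i}, so that
#' \code{S_ref,p - S_lab = L_p} exactly.
#'
#' @param fit a \code{\link{fit_multipool}} result.
#' @return list with \code{s_lab} (vector) and \code{s_ref} (named list of
#'   vectors, one per pool).
#' @export
decompose_fit <- function(fit) {
  stopifnot(inherits(fit, "lorentzian_fit"))
  L <- sapply(fit$components$pool, function(p) fit_component(fit, p))
  s_lab <- 1 - rowSums(L)
  s_ref <- lapply(seq_len(ncol(L)),
                  function(j) s_lab + L[, j])
  names(s_ref) <- fit$components$pool
  list(s_lab = s_lab, s_ref = s_ref)
}

#' Fitted APT spectrum
#'
#' CESTR of the amide decomposition: \code{S_ref,amide - S_lab = L_1}, i.e.
#' the fitted amide line itself, together with its amplitude and width.
#'
#' @param fit a \code{\link{fit_multipool}} result.
#' @return list with \code{offsets}, \code{spectrum}, \code{A}, \code{W}.
#' @export
fitted_apt_spectrum <- function(fit) {
  d <- decompose_fit(fit)
  row <- fit$components[fit$components$pool == "amide", ]
  list(offsets = fit$offsets,
       spectrum = cestr(d$s_ref$amide, d$s_lab),
       A = row$A, W = row$W)
}

#' Extract measured components for partially synthetic composition
#'
#' From a six-pool fit: the amine component as AREX with the fitted amine
#' reference, the semisolid component as \code{R1obs L6 / (1 - L6)}, and
#' the validation-only effective relaxation \code{R1obs S_ref,water /
#' S_lab}.
#'
#' @param fit a \code{\link{fit_multipool}} result.
#' @param R1obs observed water longitudinal rate (1/s).
#' @param fm semisolid pool-size ratio from measurement.
#' @return object of class \code{measured_components}: list with spectra
#'   \code{Rex_amines}, \code{Rex_mt}, \code{Reff_measured} on
#'   \code{offsets}, plus \code{R1obs} and \code{fm}.
#' @export
extract_measured_components <- function(fit, R1obs, fm, floor = 1e-4) {
  d <- decompose_fit(fit)
  L6 <- fit_component(fit, "mt")
  if (any(L6 >= 1)) stop("MT line reaches 1: Rex_MT undefined")
  ## the fitted S_lab can touch zero at the water resonance, where the
  ## inverse metric blows up; a small floor keeps the component finite there
  d$s_lab <- pmax(d$s_lab, floor)
  d$s_ref <- lapply(d$s_ref, pmax, floor)
  structure(list(
    offsets = fit$offsets,
    Rex_amines = arex(d$s_ref$amine, d$s_lab, R1obs, fm),
    Rex_mt = R1obs * L6 / (1 - L6),
    Reff_measured = R1obs * d$s_ref$water / d$s_lab,
    R1obs = R1obs, fm = fm
  ), class = "measured_components")
}
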