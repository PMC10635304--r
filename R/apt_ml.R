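#' Feature-selection windows for the APT network
#'
#' The network sees only the Z-spectrum samples within
#' [-10, -5], [-0.5, 0.5] and [2.5, 10] ppm (closed intervals). The
#' excluded segments (-5 to -0.5 and 0.5 to 2.5 ppm) have negligible
#' influence on the 3.5 ppm signal. On the default 87-point grid this
#' retains 37 samples.
#'
#' @param z a \code{\link{zspectrum}} or list with \code{offsets} and
#'   \code{values}.
#' @param windows matrix-like list of c(lo, hi) ppm windows.
#' @return list with \code{offsets} and \code{values} restricted to the
#'   windows, sorted by offset.
#' @export
select_features <- function(z, windows = feature_windows()) {
  keep <- rep(FALSE, length(z$offsets))
  for (w in windows)
    keep <- keep | (z$offsets >= w[1] - 1e-9 & z$offsets <= w[2] + 1e-9)
  if (!any(keep)) stop("offset grid contains no feature-window points")
  ord <- order(z$offsets[keep])
  list(offsets = z$offsets[keep][ord], values = z$values[keep][ord])
}

#' @rdname select_features
#' @export
feature_windows <- function() list(c(-10, -5), c(-0.5, 0.5), c(2.5, 10))

#' Network/training specification for the APT regressor
#'
#' A fully connected network, input -> 100 -> 100 -> 2, rectified-linear
#' activations after each hidden layer, mean-squared-error loss, Adam
#' optimizer. Training uses a seeded validation split and early stopping
#' on the validation loss with best-weights restore.
#'
#' @param hidden hidden-layer widths (fixed architecture: two layers of
#'   100).
#' @param epochs maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param val_fraction fraction of records held out for validation.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialization, split and batch
#'   order.
#' @return list of class \code{mlp_spec}.
#' @export
mlp_spec <- function(hidden = c(100, 100), epochs = 4000, lr = 1e-3,
                     batch_size = 64, val_fraction = 0.1, patience = 50,
                     seed = 1L) {
  stopifnot(length(hidden) == 2)
  structure(list(hidden = hidden, epochs = epochs, lr = lr,
                 batch_size = batch_size, val_fraction = val_fraction,
                 patience = patience, seed = seed), class = "mlp_spec")
}

.relu <- function(x) x * (x > 0)

.mlp_forward <- function(W, X) {
  H1 <- .relu(sweep(X %*% W$W1, 2, W$b1, `+`))
  H2 <- .relu(sweep(H1 %*% W$W2, 2, W$b2, `+`))
  Y <- sweep(H2 %*% W$W3, 2, W$b3, `+`)
  list(H1 = H1, H2 = H2, Y = Y)
}

#' Train the APT amplitude/width regressor
#'
#' Trains the two-hidden-layer network of \code{\link{mlp_spec}} to map
#' feature-selected, per-feature standardized Z-spectra to the amplitude A
#' and width W (ppm) of the amide CESTR peak. Standardization constants are
#' estimated on the training split and stored in the model; targets are
#' regressed in natural units. Training is fully deterministic given the
#' data and spec.
#'
#' @param records a \code{training_set} (see
#'   \code{\link{build_partial_synthetic}}), or a list with matrices
#'   \code{X} (n x p, full-grid spectra), \code{Y} (n x 2) and
#'   \code{offsets}.
#' @param spec an \code{\link{mlp_spec}}.
#' @param verbose print progress every 25 epochs.
#' @return object of class \code{apt_mlp}: weights, normalization
#'   constants, feature offsets, loss curves, and the epoch of the
#'   restored best weights.
#' @export
train_apt_mlp <- function(records, spec = mlp_spec(), verbose = FALSE) {
  dat <- if (inherits(records, "training_set")) training_matrices(records)
         else records
  sel <- select_features(list(offsets = dat$offsets,
                              values = dat$offsets))  # index template
  keep <- match(sel$offsets, dat$offsets)
  X <- dat$X[, keep, drop = FALSE]
  Y <- dat$Y
  if (any(!is.finite(Y))) stop("targets must be finite")
  n <- nrow(X)
  p <- ncol(X)
  set.seed(spec$seed)
  val_n <- max(1L, round(spec$val_fraction * n))
  val_idx <- sample.int(n, val_n)
  tr_idx <- setdiff(seq_len(n), val_idx)
  mu <- colMeans(X[tr_idx, , drop = FALSE])
  sg <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
  sg[sg < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  ## standardize targets as well: the width (ppm-scale) would otherwise
  ## dominate the MSE over the amplitude by more than an order of magnitude
  y_mu <- colMeans(Y[tr_idx, , drop = FALSE])
  y_sg <- apply(Y[tr_idx, , drop = FALSE], 2, stats::sd)
  y_sg[y_sg < 1e-12] <- 1
  Y <- sweep(sweep(Y, 2, y_mu), 2, y_sg, `/`)
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  h1 <- spec$hidden[1]; h2 <- spec$hidden[2]
  init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                  sqrt(2 / nin)), nin, nout)
  ## the output layer starts at zero so the initial prediction is the
  ## (standardized) target mean; hidden layers keep He initialization
  W <- list(W1 = init(p, h1), b1 = numeric(h1),
            W2 = init(h1, h2), b2 = numeric(h2),
            W3 = matrix(0, h2, 2), b3 = numeric(2))
  adam <- list(m = lapply(W, function(w) w * 0),
               v = lapply(W, function(w) w * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  ntr <- nrow(Xtr)
  nb <- ceiling(ntr / spec$batch_size)
  train_curve <- val_curve <- numeric(0)
  best <- list(loss = Inf, W = W, epoch = 0L)
  wait <- 0L
  mse <- function(W_, X_, Y_) mean((.mlp_forward(W_, X_)$Y - Y_)^2)

  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * spec$batch_size + 1):min(b * spec$batch_size, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
      f <- .mlp_forward(W, Xb)
      m <- nrow(Xb)
      dY <- 2 * (f$Y - Yb) / (m * 2)        # d(MSE)/dY
      gW3 <- crossprod(f$H2, dY); gb3 <- colSums(dY)
      dH2 <- (dY %*% t(W$W3)) * (f$H2 > 0)
      gW2 <- crossprod(f$H1, dH2); gb2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(W$W2)) * (f$H1 > 0)
      gW1 <- crossprod(Xb, dH1); gb1 <- colSums(dH1)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
      adam$t <- adam$t + 1
      corr1 <- 1 - beta1^adam$t; corr2 <- 1 - beta2^adam$t
      for (k in names(W)) {
        adam$m[[k]] <- beta1 * adam$m[[k]] + (1 - beta1) * g[[k]]
        adam$v[[k]] <- beta2 * adam$v[[k]] + (1 - beta2) * g[[k]]^2
        W[[k]] <- W[[k]] - spec$lr * (adam$m[[k]] / corr1) /
          (sqrt(adam$v[[k]] / corr2) + eps)
      }
      ep_loss <- ep_loss + mean((f$Y - Yb)^2) * m
    }
    train_curve[epoch] <- ep_loss / ntr
    val_curve[epoch] <- mse(W, Xva, Yva)
    if (!is.finite(val_curve[epoch]))
      stop("NaN loss at epoch ", epoch, "; aborting")
    if (val_curve[epoch] < best$loss - 1e-12) {
      best <- list(loss = val_curve[epoch], W = W, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
    if (verbose && epoch %% 25 == 0)
      message(sprintf("epoch %d train %.3e val %.3e", epoch,
                      train_curve[epoch], val_curve[epoch]))
  }
  structure(list(weights = best$W, mu = mu, sigma = sg,
                 y_mu = y_mu, y_sigma = y_sg,
                 feature_offsets = sel$offsets, spec = spec,
                 train_loss = train_curve, val_loss = val_curve,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 epochs_run = length(val_curve)),
            class = "apt_mlp")
}

#' @export
print.apt_mlp <- function(x, ...) {
  cat(sprintf("APT regressor: %d -> %d -> %d -> 2 (ReLU), %d features\n",
              length(x$feature_offsets), x$spec$hidden[1], x$spec$hidden[2],
              length(x$feature_offsets)))
  cat(sprintf("  trained %d epochs, best validation MSE %.3e at epoch %d\n",
              x$epochs_run, x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
plot.apt_mlp <- function(x, ...) {
  ep <- seq_along(x$train_loss)
  graphics::plot(ep, x$train_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE", col = "grey40", ...)
  graphics::lines(ep, x$val_loss, col = "red3")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("grey40", "red3"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict amide peak amplitude and width
#'
#' Applies the stored feature selection and standardization, runs the
#' network, and clamps negative amplitude/width predictions at a small
#' positive floor (counted in \code{attr(, "n_clamped")}).
#'
#' @param object an \code{\link{train_apt_mlp}} model.
#' @param newdata a \code{\link{zspectrum}}, a list of them, or an n x p
#'   matrix of full-grid spectra with attribute/argument \code{offsets}.
#' @param offsets full grid for matrix input.
#' @param ... unused.
#' @return data.frame with columns \code{A} and \code{W} (ppm), one row per
#'   spectrum, with attribute \code{n_clamped}.
#' @export
predict.apt_mlp <- function(object, newdata, offsets = NULL, ...) {
  if (inherits(newdata, "zspectrum")) newdata <- list(newdata)
  if (is.list(newdata) && inherits(newdata[[1]], "zspectrum")) {
    offsets <- newdata[[1]]$offsets
    newdata <- do.call(rbind, lapply(newdata, function(z) z$values))
  }
  if (is.null(offsets)) stop("offsets required for matrix input")
  keep <- match(object$feature_offsets, offsets)
  if (any(is.na(keep)))
    stop("input grid is missing feature offsets required by the model")
  X <- newdata[, keep, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sigma, `/`)
  Y <- .mlp_forward(object$weights, Xs)$Y
  Y <- sweep(sweep(Y, 2, object$y_sigma, `*`), 2, object$y_mu, `+`)
  n_clamped <- sum(Y[, 1] < 0)
  out <- data.frame(A = pmax(Y[, 1], 0), W = pmax(Y[, 2], 1e-3),
                    row.names = NULL)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Reconstruct an APT spectrum from predicted amplitude and width
#'
#' A Lorentzian line of amplitude \code{A} and FWHM \code{W} centered at
#' the amide resonance.
#'
#' @param A peak amplitude.
#' @param W FWHM in ppm.
#' @param offsets evaluation grid in ppm.
#' @param center amide offset in ppm.
#' @return the reconstructed CESTR spectrum.
#' @export
apt_spectrum_from_aw <- function(A, W, offsets, center = 3.5) {
  if (A <= 0) return(rep(0, length(offsets)))
  lorentzian_line(A, W, center, offsets)
}

#' Mean absolute APT-spectrum error over the 2-5 ppm window
#'
#' The accuracy measure of the platform: the mean absolute difference
#' between a predicted and a ground-truth APT spectrum over the grid points
#' within \code{window} (inclusive).
#'
#' @param pred,truth spectra on \code{offsets}.
#' @param offsets common grid in ppm.
#' @param window c(lo, hi) ppm.
#' @return scalar mean absolute difference.
#' @export
apt_loss <- function(pred, truth, offsets, window = c(2, 5)) {
  .check_same_grid(seq_along(pred), seq_along(truth), "pred and truth")
  keep <- offsets >= window[1] - 1e-9 & offsets <= window[2] + 1e-9
  if (!any(keep)) stop("offset grid does not cover the loss window")
  mean(abs(pred[keep] - truth[keep]))
}
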