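#' Validate the inverse-summation composition against a measured spectrum
#'
#' Fits the six-pool Lorentzian model to a Z-spectrum, extracts every
#' rotating-frame component from the fit (APT and the two NOE components
#' via AREX with their fitted references, amines and MT via
#' \code{\link{extract_measured_components}}, and the measured effective
#' relaxation \code{R1obs S_ref,water / S_lab}), then recomposes the
#' spectrum by inverse summation with unit scaling factors. Reports the
#' RMS discrepancy between the recomposition and the input, and the
#' APT-removed variant whose difference from the input isolates the APT
#' contribution.
#'
#' @param z a \code{\link{zspectrum}} on the full grid.
#' @param R1obs observed water longitudinal rate (1/s).
#' @param fm semisolid pool-size ratio.
#' @param acq the acquisition the spectrum was measured with.
#' @param config fit configuration.
#' @return list with the fit, the recomposed spectra (\code{z_composed},
#'   \code{z_composed_noapt}), \code{rms} (input vs recomposition) and
#'   \code{apt_contrast} (APT-removed minus full composition).
#' @export
workflow_validate_composition <- function(z, R1obs, fm,
                                          acq = cest_acquisition(),
                                          config = lorentzian_fit_config()) {
  fit <- fit_multipool(z, config)
  d <- decompose_fit(fit)
  d$s_lab <- pmax(d$s_lab, 1e-4)     # guard the 0 ppm inverse blow-up
  d$s_ref <- lapply(d$s_ref, pmax, 1e-4)
  mc <- extract_measured_components(fit, R1obs, fm)
  rex_apt <- arex(d$s_ref$amide, d$s_lab, R1obs, fm)
  rex_noe <- arex(d$s_ref$noe16, d$s_lab, R1obs, fm) +
    arex(d$s_ref$noe35, d$s_lab, R1obs, fm)
  tissue <- cest_tissue(R1obs = R1obs, R1w = R1obs, R2w = 1, R1M = 1,
                        fm = fm, r_amines = 1, r_MT = 1)
  comps <- list(Reff = mc$Reff_measured, Rex_apt = rex_apt,
                Rex_noe = rex_noe, Rex_amines = mc$Rex_amines,
                Rex_mt = mc$Rex_mt)
  zc <- compose_zspectrum(comps, tissue, acq$omega1, acq$offsets,
                          acq$hz_per_ppm)
  comps_noapt <- comps
  comps_noapt$Rex_apt <- NULL
  zna <- compose_zspectrum(comps_noapt, tissue, acq$omega1, acq$offsets,
                           acq$hz_per_ppm)
  list(fit = fit, z_composed = zc, z_composed_noapt = zna,
       rms = sqrt(mean((z$values - zc$values)^2)),
       apt_contrast = zna$values - zc$values)
}

#' Voxel stack for map-level prediction
#'
#' @param spectra array (rows x cols x offsets) of normalized Z-spectra.
#' @param offsets offset grid in ppm.
#' @param r1obs,fm per-voxel maps (rows x cols), or NULL.
#' @param brain_mask logical rows x cols mask; defaults to all voxels.
#' @return object of class \code{voxel_stack}.
#' @export
voxel_stack <- function(spectra, offsets, r1obs = NULL, fm = NULL,
                        brain_mask = NULL) {
  stopifnot(length(dim(spectra)) == 3, dim(spectra)[3] == length(offsets))
  dims <- dim(spectra)[1:2]
  if (is.null(brain_mask)) brain_mask <- matrix(TRUE, dims[1], dims[2])
  stopifnot(all(dim(brain_mask) == dims))
  if (!is.null(fm)) stopifnot(all(dim(fm) == dims))
  structure(list(spectra = spectra, offsets = offsets, r1obs = r1obs,
                 fm = fm, brain_mask = brain_mask), class = "voxel_stack")
}

#' Predict APT amplitude/width maps and compare tumor vs normal ROIs
#'
#' Runs the trained regressor on every voxel inside the brain mask (voxels
#' outside are NA), derives the tumor ROI from the semisolid pool-size map
#' (\code{fm < fm_threshold}, the tumor's reduced macromolecular content),
#' mirrors it across the vertical midline for the contralateral normal
#' ROI, and compares ROI means with Welch t-tests.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param model an \code{\link{train_apt_mlp}} model.
#' @param fm_threshold tumor threshold on the fm map (default 0.07).
#' @param fit_rois also run the six-pool Lorentzian fit on every ROI voxel
#'   and report its amide amplitude alongside the network prediction
#'   (slower; off by default).
#' @return list with \code{A_map}, \code{W_map}, masks, and \code{report}
#'   (data.frame of ROI means/sds and t-test p-values; NULL when the fm map
#'   is missing or an ROI is empty, with a flag in \code{notes}).
#' @export
workflow_apt_map <- function(stack, model, fm_threshold = 0.07,
                             fit_rois = FALSE) {
  stopifnot(inherits(stack, "voxel_stack"))
  dims <- dim(stack$spectra)[1:2]
  A_map <- W_map <- matrix(NA_real_, dims[1], dims[2])
  idx <- which(stack$brain_mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    X <- t(apply(idx, 1, function(rc) stack$spectra[rc[1], rc[2], ]))
    pred <- predict(model, X, offsets = stack$offsets)
    A_map[idx] <- pred$A
    W_map[idx] <- pred$W
  }
  notes <- character(0)
  tumor <- normal <- NULL
  report <- NULL
  if (is.null(stack$fm)) {
    notes <- c(notes, "fm map missing: tumor ROI unavailable")
  } else {
    tumor <- stack$brain_mask & (stack$fm < fm_threshold)
    normal <- stack$brain_mask & tumor[, rev(seq_len(dims[2]))] & !tumor
    if (!any(tumor)) {
      notes <- c(notes, "empty tumor ROI: no voxel below fm threshold")
    } else if (!any(normal)) {
      notes <- c(notes, "empty contralateral ROI after mirroring")
    } else {
      roi_stats <- function(map) {
        tv <- map[tumor]; nv <- map[normal]
        tt <- tryCatch(stats::t.test(tv, nv)$p.value,
                       error = function(e) NA_real_)
        c(tumor_mean = mean(tv, na.rm = TRUE),
          tumor_sd = stats::sd(tv, na.rm = TRUE),
          normal_mean = mean(nv, na.rm = TRUE),
          normal_sd = stats::sd(nv, na.rm = TRUE), p_value = tt)
      }
      rows <- list(A = roi_stats(A_map), W = roi_stats(W_map))
      if (!is.null(stack$r1obs)) rows$R1obs <- roi_stats(stack$r1obs)
      rows$fm <- roi_stats(stack$fm)
      if (fit_rois) {
        fitA <- matrix(NA_real_, dims[1], dims[2])
        roi_idx <- which(tumor | normal, arr.ind = TRUE)
        for (k in seq_len(nrow(roi_idx))) {
          rc <- roi_idx[k, ]
          z <- list(offsets = stack$offsets,
                    values = stack$spectra[rc[1], rc[2], ])
          fitA[rc[1], rc[2]] <- tryCatch(
            fit_multipool(z)$components$A[1], error = function(e) NA_real_)
        }
        rows$A_lorentzian_fit <- roi_stats(fitA)
      }
      report <- data.frame(metric = names(rows), do.call(rbind, rows),
                           row.names = NULL)
      report$n_tumor <- sum(tumor)
      report$n_normal <- sum(normal)
    }
  }
  list(A_map = A_map, W_map = W_map, tumor_mask = tumor,
       normal_mask = normal, report = report, notes = notes)
}

#' Read / write a Z-spectrum as two-column CSV
#'
#' Column headers \code{offset_ppm} and \code{signal_norm}.
#'
#' @param path file path.
#' @param z a \code{\link{zspectrum}} (write only).
#' @return \code{read_zspectrum} returns a \code{\link{zspectrum}}.
#' @export
read_zspectrum <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("offset_ppm", "signal_norm") %in% names(d)))
    stop("expected columns offset_ppm, signal_norm")
  zspectrum(d$offset_ppm, d$signal_norm, meta = list(source = path))
}

#' @rdname read_zspectrum
#' @export
write_zspectrum <- function(z, path) {
  utils::write.csv(data.frame(offset_ppm = z$offsets,
                              signal_norm = z$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained APT regressor as JSON
#'
#' Serializes weights, normalization constants, feature offsets and the
#' training spec; numeric precision is preserved exactly via full-precision
#' JSON.
#'
#' @param model an \code{apt_mlp}.
#' @param path file path.
#' @return \code{load_apt_mlp} returns the restored \code{apt_mlp}.
#' @export
save_apt_mlp <- function(model, path) {
  stopifnot(inherits(model, "apt_mlp"))
  obj <- list(weights = lapply(model$weights, function(w)
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = NULL, data = as.numeric(w))),
              mu = model$mu, sigma = model$sigma,
              y_mu = model$y_mu, y_sigma = model$y_sigma,
              feature_offsets = model$feature_offsets,
              spec = unclass(model$spec),
              best_epoch = model$best_epoch,
              best_val_loss = model$best_val_loss)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_apt_mlp
#' @export
load_apt_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim) == 2)
      matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  structure(list(weights = weights, mu = obj$mu, sigma = obj$sigma,
                 y_mu = obj$y_mu, y_sigma = obj$y_sigma,
                 feature_offsets = obj$feature_offsets,
                 spec = structure(as.list(obj$spec), class = "mlp_spec"),
                 train_loss = numeric(0), val_loss = numeric(0),
                 best_epoch = obj$best_epoch,
                 best_val_loss = obj$best_val_loss,
                 epochs_run = obj$best_epoch),
            class = "apt_mlp")
}

#' Read a YAML parameter-range configuration
#'
#' Nested YAML maps of two-element sequences are read as \code{c(min, max)}
#' ranges compatible with \code{\link{draw_parameters}}.
#'
#' @param path YAML file.
#' @return nested list of ranges.
#' @examples
#' rg <- read_ranges_yaml(system.file("extdata", "synth_ranges.yaml",
#'                                    package = "cestsynth"))
#' rg$amide$fs
#' @export
read_ranges_yaml <- function(path) {
  rapply(yaml::read_yaml(path), as.numeric, how = "replace")
}
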