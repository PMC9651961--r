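# Per-subject task GLM: spike detection, design construction, OLS fit,
# residual extraction for the connectivity analyses, contrast maps, and
# volumetric Gaussian smoothing.

#' A 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, time), all values finite.
#' @param tr_seconds repetition time in seconds.
#' @return object of class `bold_run` with fields `data` and `tr`.
#' @export
bold_run <- function(data, tr_seconds) {
  if (length(dim(data)) != 4L)
    eh_stop("bold_run data must be a 4D array", "ehconn_invalid_input")
  if (tr_seconds <= 0)
    eh_stop("tr_seconds must be positive", "ehconn_invalid_input")
  structure(list(data = data, tr = tr_seconds), class = "bold_run")
}

#' Canonical double-gamma haemodynamic response function
#'
#' The usual difference of two gamma densities (response peak delay 6 s,
#' undershoot delay 16 s, unit dispersions, undershoot ratio 1/6), sampled
#' at the repetition time and normalized to sum to one.
#'
#' @param tr sampling interval in seconds.
#' @param duration_s kernel support in seconds (>= 16).
#' @return numeric kernel vector of length `floor(duration_s / tr) + 1`.
#' @export
canonical_hrf <- function(tr, duration_s = 32) {
  stopifnot(tr > 0, duration_s >= 16)
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Detect spike (outlier) volumes from global intensity and motion
#'
#' A volume is flagged when the absolute scan-to-scan change of the global
#' mean intensity exceeds `intensity_pct` percent of the run-mean global
#' intensity, or when the scan-to-scan framewise displacement (sum of
#' absolute translation differences, first three motion columns) exceeds
#' `motion_mm`. The first volume is never intensity-flagged.
#'
#' @param run a [bold_run()].
#' @param motion T x 6 motion-parameter matrix (translations in mm first).
#' @param intensity_pct global-intensity threshold in percent (default 1.3).
#' @param motion_mm framewise-displacement threshold in mm (default 0.3).
#' @return sorted integer vector of flagged volume indices.
#' @export
detect_spikes <- function(run, motion, intensity_pct = 1.3, motion_mm = 0.3) {
  n_t <- dim(run$data)[4]
  if (n_t < 2L)
    eh_stop("spike detection needs at least 2 volumes", "ehconn_invalid_input")
  if (nrow(motion) != n_t)
    eh_stop("motion rows must match run length", "ehconn_invalid_input")
  g <- colMeans(as_voxel_matrix(run$data))
  pct <- 100 * abs(diff(g)) / mean(g)
  fd <- rowSums(abs(diff(motion[, 1:3, drop = FALSE])))
  flagged <- c(which(pct > intensity_pct) + 1L, which(fd > motion_mm) + 1L)
  sort(unique(flagged))
}

#' HRF-convolved regressor for one condition
#'
#' The event boxcar is built on a fine time grid (0.1 s), convolved with
#' the canonical HRF, and sampled at the volume acquisition times
#' `(i - 1) * tr`.
#'
#' @param events event table (`onset`, `duration`, `condition`).
#' @param condition condition name to extract.
#' @param n_time number of volumes.
#' @param tr repetition time in seconds.
#' @return numeric vector of length `n_time`.
#' @export
condition_regressor <- function(events, condition, n_time, tr) {
  dt <- 0.1
  run_len <- n_time * tr
  fine_t <- seq(0, run_len, by = dt)
  box <- numeric(length(fine_t))
  ev <- events[events$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(ev)))
    box[fine_t >= ev$onset[i] & fine_t < ev$onset[i] + ev$duration[i]] <- 1
  if (!any(box > 0)) return(numeric(n_time))
  h <- canonical_hrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(fine_t)]
  vol_t <- (seq_len(n_time) - 1) * tr
  conv[round(vol_t / dt) + 1L]
}

#' Build a GLM design matrix
#'
#' Columns: one HRF-convolved regressor per condition present in the event
#' table, six motion columns, one one-hot column per spike volume, and an
#' intercept. Condition columns are not mean-centred; the intercept absorbs
#' the offset.
#'
#' @param events event table, or `NULL` for a rest design.
#' @param nuisance list with `motion` (T x 6) and `spikes` (integer vector).
#' @param n_time number of volumes.
#' @param tr repetition time in seconds.
#' @return numeric T x p matrix with named columns, full column rank.
#' @export
build_design <- function(events, nuisance, n_time, tr) {
  cols <- list()
  if (!is.null(events) && nrow(events) > 0) {
    for (cond in unique(events$condition))
      cols[[cond]] <- condition_regressor(events, cond, n_time, tr)
  }
  motion <- nuisance$motion
  if (!is.null(motion)) {
    if (nrow(motion) != n_time)
      eh_stop("motion rows must match run length", "ehconn_invalid_input")
    for (j in seq_len(ncol(motion)))
      cols[[paste0("motion", j)]] <- motion[, j]
  }
  for (s in sort(unique(nuisance$spikes))) {
    v <- numeric(n_time)
    v[s] <- 1
    cols[[paste0("spike", s)]] <- v
  }
  cols[["intercept"]] <- rep(1, n_time)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    eh_stop(paste("design matrix is rank deficient; collinear columns:",
                  paste(dropped, collapse = ", ")),
            "ehconn_invalid_input")
  }
  X
}

#' Fit an ordinary-least-squares GLM per voxel
#'
#' @param run a [bold_run()].
#' @param design full-rank T x p design matrix with named columns.
#' @return object of class `glm_fit`: `betas` (voxels x p matrix),
#'   `residual_run` (a [bold_run()] of residuals), `design`, `dims`.
#' @export
fit_glm <- function(run, design) {
  Y <- as_voxel_matrix(run$data)
  if (!all(is.finite(Y))) {
    bad <- which(!apply(is.finite(Y), 1L, all))[1]
    coord <- arrayInd(bad, dim(run$data)[1:3])
    eh_stop(sprintf("non-finite voxel series at (%d, %d, %d)",
                    coord[1], coord[2], coord[3]),
            "ehconn_invalid_input")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design))
    eh_stop("design must be full rank", "ehconn_invalid_input")
  betas <- t(qr.coef(qrX, t(Y)))
  resid <- Y - betas %*% t(design)
  structure(list(betas = betas, design = design,
                 residual_run = bold_run(as_4d(resid, dim(run$data)[1:3]),
                                         run$tr),
                 dims = dim(run$data)[1:3]),
            class = "glm_fit")
}

#' Linear contrast of GLM coefficients
#'
#' @param fit a [fit_glm()] result.
#' @param weights named numeric vector; names must be design columns.
#' @param contrast_name label stored with the map.
#' @return list of class `contrast_map` with `values` (3D array) and
#'   `contrast_name`.
#' @export
glm_contrast <- function(fit, weights, contrast_name = NULL) {
  unknown <- setdiff(names(weights), colnames(fit$betas))
  if (length(unknown))
    eh_stop(paste("unknown design columns:", paste(unknown, collapse = ", ")),
            "ehconn_invalid_input")
  v <- as.vector(fit$betas[, names(weights), drop = FALSE] %*% weights)
  structure(list(values = array(v, dim = fit$dims),
                 contrast_name = contrast_name %||%
                   paste(names(weights), collapse = "_")),
            class = "contrast_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' @noRd
smooth_axis <- function(vol, axis, k) {
  # truncated-kernel convolution along one axis with edge renormalization
  # so that a constant volume is preserved exactly; all lines at once
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  M <- matrix(aperm(vol, perm), nrow = d[axis])
  r <- (length(k) - 1L) / 2L
  n <- nrow(M)
  pad <- matrix(0, r, ncol(M))
  num <- stats::filter(rbind(pad, M, pad), k, sides = 2)
  num <- num[(r + 1L):(r + n), , drop = FALSE]
  den <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)
  den <- as.numeric(den)[(r + 1L):(r + n)]
  aperm(array(num / den, d[perm]), order(perm))
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` in
#' voxel units; kernel truncated at three sigma with edge renormalization
#' (constant volumes are preserved). `fwhm_mm = 0` is the identity.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @return smoothed 3D array.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 1) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k <- gauss_kernel(sigma)
  out <- vol
  for (axis in 1:3) out <- smooth_axis(out, axis, k)
  out
}
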