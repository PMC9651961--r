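# Seed-to-voxel semipartial correlation on GLM residuals: intensity-based
# seed-mask exclusion, band-pass filtering, nuisance residualization,
# Pearson correlation and Fisher z transform.

#' Exclude low-intensity voxels from a seed mask
#'
#' Removes voxels whose temporal-mean intensity falls more than `k_sd`
#' sample standard deviations below the mean of the ROI voxel means
#' (guards against signal dropout distorting the seed average). The
#' reference population is the ROI itself. `k_sd = Inf` disables the
#' exclusion.
#'
#' @param run a [bold_run()] of raw (pre-residual) data.
#' @param voxels integer vector of linear voxel indices (nonempty).
#' @param k_sd threshold in standard deviations (default 2).
#' @return reduced integer vector of voxel indices.
#' @export
intensity_exclude <- function(run, voxels, k_sd = 2) {
  if (length(voxels) == 0L)
    eh_stop("empty seed mask", "ehconn_invalid_input")
  if (is.infinite(k_sd)) return(voxels)
  Y <- as_voxel_matrix(run$data)[voxels, , drop = FALSE]
  m <- rowMeans(Y)
  thr <- mean(m) - k_sd * stats::sd(m)
  if (length(m) == 1L) thr <- m  # sd undefined for a single voxel
  keep <- voxels[m >= thr]
  if (length(keep) == 0L)
    eh_stop("all seed voxels excluded by intensity thresholding",
            "ehconn_invalid_input")
  keep
}

#' Mean time series over a voxel set
#'
#' @param run a [bold_run()].
#' @param voxels integer vector of linear voxel indices (nonempty).
#' @return numeric vector of length T.
#' @export
mean_timeseries <- function(run, voxels) {
  if (length(voxels) == 0L)
    eh_stop("empty voxel set", "ehconn_invalid_input")
  n_vox <- prod(dim(run$data)[1:3])
  if (any(voxels < 1L | voxels > n_vox))
    eh_stop("voxel indices outside grid", "ehconn_invalid_input")
  colMeans(as_voxel_matrix(run$data)[voxels, , drop = FALSE])
}

#' Zero-phase band-pass filter
#'
#' Exact-passband filtering by zeroing FFT coefficients outside `band`;
#' the DC component is always removed. Filtering is zero-phase and
#' deterministic.
#'
#' @param x numeric vector, or T x k matrix filtered column-wise.
#' @param band passband `c(low, high)` in Hz.
#' @param tr sampling interval in seconds.
#' @return filtered vector or matrix of the same shape.
#' @export
bandpass <- function(x, band, tr) {
  check_band(band, tr)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n * tr < 3 / band[1])
    warning(sprintf(
      "series of %.0f s holds fewer than 3 cycles of the %.3g Hz low cutoff",
      n * tr, band[1]))
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0
  out <- Re(stats::mvfft(Xf, inverse = TRUE)) / n
  if (vec) as.numeric(out) else out
}

#' Fisher z transform of a correlation coefficient
#'
#' `atanh` with clipping at `1 - 1e-7` for numerical stability at perfect
#' correlations.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    eh_stop("correlation outside [-1, 1]", "ehconn_invalid_input")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @noRd
residualize <- function(y, X) {
  # residuals of y (vector or columns of a matrix) against columns of X
  # plus an intercept
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(y)
  qr.resid(qr(cbind(1, as.matrix(X))), y)
}

#' Semipartial seed-to-voxel connectivity map
#'
#' Computes, per voxel, the correlation between the voxel series and the
#' part of the seed series that is unique to the seed: (1) band-pass
#' filter seed, controls, nuisance and voxel series; (2) residualize every
#' voxel series against the nuisance set; (3) residualize the seed series
#' against the control series plus nuisance (the semipartial correlation
#' captures variance uniquely explained by the seed, excluding the other
#' sources); (4) Pearson-correlate; (5) Fisher-transform with clipping.
#'
#' Note the residualization is applied on the seed (predictor) side only;
#' voxel series are cleaned of nuisance but not of the control seeds.
#' Connectivity toolboxes differ on this convention.
#'
#' @param residual_run a [bold_run()] of GLM residuals.
#' @param seed_series numeric vector, the seed's mean time series.
#' @param control_series list of numeric vectors (other sources/seeds);
#'   must not include the seed itself.
#' @param nuisance T x q matrix of nuisance regressors, or `NULL`.
#' @param band passband `c(low, high)` in Hz, or `NULL` to skip filtering.
#' @param seed_name,subject_id labels stored with the map.
#' @return object of class `connectivity_map`: `z_values` (3D array),
#'   `seed_name`, `subject_id`.
#' @export
semipartial_connectivity <- function(residual_run, seed_series,
                                     control_series = list(),
                                     nuisance = NULL, band = NULL,
                                     seed_name = "seed",
                                     subject_id = "sub") {
  Y <- t(as_voxel_matrix(residual_run$data))  # time x voxels
  n_t <- nrow(Y)
  lens <- c(length(seed_series), vapply(control_series, length, 1L),
            if (!is.null(nuisance)) nrow(nuisance))
  if (any(lens != n_t))
    eh_stop("seed, control and nuisance series must match the run length",
            "ehconn_invalid_input")
  if (!is.null(band)) {
    tr <- residual_run$tr
    seed_series <- bandpass(seed_series, band, tr)
    control_series <- lapply(control_series, bandpass, band = band, tr = tr)
    if (!is.null(nuisance)) nuisance <- bandpass(nuisance, band, tr)
    Y <- bandpass(Y, band, tr)
  }
  Y <- residualize(Y, nuisance)
  X_seed <- cbind(nuisance,
                  if (length(control_series)) do.call(cbind, control_series))
  seed_u <- residualize(seed_series, X_seed)
  if (stats::sd(seed_u) < 1e-12)
    eh_stop("seed series fully explained by controls/nuisance",
            "ehconn_invalid_input")
  seed_c <- seed_u - mean(seed_u)
  Yc <- sweep(Y, 2L, colMeans(Y))
  num <- as.vector(crossprod(Yc, seed_c))
  den <- sqrt(colSums(Yc^2)) * sqrt(sum(seed_c^2))
  r <- ifelse(den > 0, num / den, 0)
  structure(list(z_values = array(fisher_z(r),
                                  dim = dim(residual_run$data)[1:3]),
                 seed_name = seed_name, subject_id = subject_id),
            class = "connectivity_map")
}
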