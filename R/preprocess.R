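#' Discard initial volumes of a session
#'
#' Drops the first `n_discard` volumes (signal-equilibration scans), keeping
#' the temporal order of the remainder.
#'
#' @param series a [series4d].
#' @param n_discard number of leading volumes to drop (default 10).
#' @return a [series4d] with `n_discard` fewer timepoints.
#' @export
discard_initial_volumes <- function(series, n_discard = 10L) {
  nt <- n_timepoints(series)
  if (n_discard < 0 || n_discard >= nt)
    stop("n_discard must satisfy 0 <= n_discard < ", nt)
  if (n_discard == 0) return(series)
  series4d(series$data[, , , -seq_len(n_discard), drop = FALSE],
           series$tr_seconds, series$voxel_mm)
}

#' Head-motion exclusion check
#'
#' A session is excluded when any translation exceeds `trans_mm` millimetres
#' or any rotation exceeds `rot_deg` degrees (absolute values of the
#' realignment-style parameters as given).
#'
#' @param motion timepoints x 6 table: 3 translations (mm) then 3 rotations
#'   (degrees).
#' @param trans_mm,rot_deg exclusion thresholds (defaults 1.5 mm / 1.5 deg).
#' @return list with `keep` (logical), `max_trans` and `max_rot`.
#' @export
check_motion_exclusion <- function(motion, trans_mm = 1.5, rot_deg = 1.5) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop("motion table must have exactly 6 columns")
  if (!all(is.finite(m))) stop("motion table contains non-finite values")
  max_trans <- max(abs(m[, 1:3]))
  max_rot <- max(abs(m[, 4:6]))
  list(keep = max_trans <= trans_mm && max_rot <= rot_deg,
       max_trans = max_trans, max_rot = max_rot)
}

#' Build the nuisance design matrix
#'
#' Columns: intercept, a linear trend (scan drift), the 6 motion
#' parameters, mean white-matter signal, mean CSF signal and (optionally)
#' the global mean over the whole volume (all voxels, labelled or not --
#' restricting the global mean to exactly the ROI-covered voxels would make
#' it an exact linear combination of the ROI means and leave the 20-ROI
#' covariance singular after regression).
#'
#' @param series a [series4d] (after volume discard).
#' @param motion timepoints x 6 motion table matching the series length.
#' @param atlas an [atlas_bundle] on the series grid.
#' @param global_signal include the global mean regressor (default TRUE).
#' @return numeric matrix timepoints x k with column names, of full rank.
#' @export
nuisance_design <- function(series, motion, atlas, global_signal = TRUE) {
  nt <- n_timepoints(series)
  m <- as.matrix(motion)
  if (nrow(m) != nt)
    stop("motion table has ", nrow(m), " rows but series has ", nt,
         " timepoints")
  if (ncol(m) != 6) stop("motion table must have exactly 6 columns")
  x <- series_matrix(series)
  d <- cbind(
    intercept = 1,
    trend = seq_len(nt) - (nt + 1) / 2,
    m,
    wm = rowMeans(x[, as.vector(atlas$wm), drop = FALSE]),
    csf = rowMeans(x[, as.vector(atlas$csf), drop = FALSE])
  )
  if (global_signal)
    d <- cbind(d, global = rowMeans(x))
  colnames(d)[3:8] <- colnames(motion)
  d
}

#' Regress nuisance signals out of every voxel series
#'
#' Replaces each voxel time series by its least-squares residual against the
#' design; residuals are orthogonal to every design column.
#'
#' @param series a [series4d].
#' @param design timepoints x k design matrix (see [nuisance_design()]).
#' @return a [series4d] of residuals.
#' @export
regress_nuisance <- function(series, design) {
  d <- as.matrix(design)
  if (nrow(d) != n_timepoints(series))
    stop("design rows do not match series timepoints")
  qrd <- qr(d)
  if (qrd$rank < ncol(d)) {
    dropped <- colnames(d)[qrd$pivot[(qrd$rank + 1):ncol(d)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  x <- series_matrix(series)
  res <- qr.resid(qrd, x)
  matrix_to_series(res, series)
}

bandpass_matrix <- function(x, tr_seconds, low_hz, high_hz) {
  # ideal (rectangular) frequency-domain band-pass; an exact projection,
  # so applying it twice is a no-op (linear drift is handled upstream by
  # the trend column of the nuisance design)
  nt <- nrow(x)
  k <- seq_len(nt) - 1L
  freqs <- pmin(k, nt - k) / (nt * tr_seconds)
  keep <- freqs >= low_hz & freqs <= high_hz
  spec <- stats::mvfft(x)
  spec[!keep, ] <- 0
  Re(stats::mvfft(spec, inverse = TRUE)) / nt
}

#' Ideal band-pass filter of a 4D series
#'
#' Rectangular frequency-domain band-pass: Fourier bins with frequency
#' inside `[low_hz, high_hz]` are kept unchanged, all others (including DC)
#' are zeroed. In-band components are preserved exactly; out-of-band
#' attenuation is total (edge behaviour: the bin whose centre frequency
#' equals a band edge is kept). The filter is an orthogonal projection, so
#' it is exactly idempotent; linear scan drift is removed upstream by the
#' trend column of the nuisance design.
#'
#' @param series a [series4d].
#' @param low_hz,high_hz passband in Hz (defaults 0.01 and 0.08); must lie
#'   inside (0, Nyquist).
#' @return a filtered [series4d], zero-mean per voxel.
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08) {
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band (", low_hz, ", ", high_hz, ") Hz outside (0, Nyquist = ",
         nyq, " Hz)")
  x <- series_matrix(series)
  matrix_to_series(bandpass_matrix(x, series$tr_seconds, low_hz, high_hz),
                   series)
}

#' Full preprocessing chain for one subject
#'
#' Fixed stage order: initial-volume discard, motion-exclusion check,
#' nuisance regression (6 motion parameters + WM + CSF + global mean),
#' band-pass filter.
#'
#' @param dataset a `subject_dataset` (see [generate_subject()]).
#' @param atlas an [atlas_bundle].
#' @param n_discard leading volumes to drop (default 10).
#' @param band passband in Hz (default `c(0.01, 0.08)`).
#' @param trans_mm,rot_deg motion-exclusion thresholds.
#' @param global_signal include the global-signal regressor (default TRUE).
#' @return list with `series` (preprocessed [series4d] or `NULL` when the
#'   session is excluded), `kept` (logical) and `motion_check`.
#' @export
preprocess_subject <- function(dataset, atlas, n_discard = 10L,
                               band = c(0.01, 0.08),
                               trans_mm = 1.5, rot_deg = 1.5,
                               global_signal = TRUE) {
  series <- discard_initial_volumes(dataset$series, n_discard)
  motion <- dataset$motion[-seq_len(n_discard), , drop = FALSE]
  if (n_discard == 0) motion <- dataset$motion
  mc <- check_motion_exclusion(motion, trans_mm, rot_deg)
  if (!mc$keep)
    return(list(series = NULL, kept = FALSE, motion_check = mc))
  design <- nuisance_design(series, motion, atlas, global_signal)
  series <- regress_nuisance(series, design)
  series <- bandpass_filter(series, band[1], band[2])
  list(series = series, kept = TRUE, motion_check = mc)
}
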