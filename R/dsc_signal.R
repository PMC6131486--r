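#' Construct a DSC signal-intensity series
#'
#' Bundles a 4D dynamic susceptibility contrast (DSC) acquisition with the
#' metadata needed for tracer-kinetic processing: the echo time TE, the frame
#' spacing, the index of the pre-bolus baseline frame and an optional brain
#' mask.
#'
#' @param intensities 4D numeric array of signal intensities, axis order
#'   (x, y, z, t), arbitrary scanner units.
#' @param te_seconds Echo time TE in seconds (> 0).
#' @param dt_seconds Frame spacing in seconds (> 0).
#' @param baseline_index 1-based index of the pre-bolus reference frame
#'   (default 1, the first frame).
#' @param brain_mask Optional 3D logical array; voxels outside the mask are
#'   ignored by downstream processing. `NULL` means all voxels are in-mask.
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(intensities, te_seconds, dt_seconds,
                       baseline_index = 1L, brain_mask = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 4L)
    stop("`intensities` must be a 4D array (x, y, z, t)")
  nt <- dim(intensities)[4]
  if (nt < 2L) stop("time dimension must have length >= 2")
  if (!is.numeric(te_seconds) || length(te_seconds) != 1L || te_seconds <= 0)
    stop("`te_seconds` must be a single positive number")
  if (!is.numeric(dt_seconds) || length(dt_seconds) != 1L || dt_seconds <= 0)
    stop("`dt_seconds` must be a single positive number")
  baseline_index <- as.integer(baseline_index)
  if (baseline_index < 1L || baseline_index > nt)
    stop("`baseline_index` outside the time range")
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(intensities)[1:3]))
      stop("`brain_mask` must match the spatial dimensions of `intensities`")
    brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  }
  structure(list(intensities = intensities, te_seconds = te_seconds,
                 dt_seconds = dt_seconds, baseline_index = baseline_index,
                 brain_mask = brain_mask),
            class = "dsc_series")
}

#' Construct a concentration-time-curve volume
#'
#' @param curves 4D numeric array (x, y, z, time) of contrast concentration.
#' @param dt_seconds Spacing of the (possibly resampled) time grid, seconds.
#' @return An object of class `ctc_volume`.
#' @export
ctc_volume <- function(curves, dt_seconds) {
  if (!is.array(curves) || length(dim(curves)) != 4L)
    stop("`curves` must be a 4D array (x, y, z, time)")
  if (any(!is.finite(curves)))
    stop("concentration curves must be finite everywhere")
  if (dt_seconds <= 0) stop("`dt_seconds` must be positive")
  structure(list(curves = curves, n_time = dim(curves)[4],
                 dt_seconds = dt_seconds),
            class = "ctc_volume")
}

#' Construct an arterial input function
#'
#' @param values 1D numeric concentration curve on the same time grid as the
#'   tissue curves it will be deconvolved against.
#' @param dt_seconds Grid spacing in seconds.
#' @param source Free-text provenance, e.g. `"supplied"`, `"voxels"`,
#'   `"simulated"`.
#' @return An object of class `aif`.
#' @export
aif <- function(values, dt_seconds, source = "supplied") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("AIF values must be finite")
  if (max(values) <= 0)
    warning("AIF has a non-positive peak; it cannot be used for deconvolution")
  if (dt_seconds <= 0) stop("`dt_seconds` must be positive")
  structure(list(values = values, dt_seconds = dt_seconds, source = source),
            class = "aif")
}

#' Convert DSC signal intensities to concentration-time curves
#'
#' Applies the standard T2*-weighted susceptibility relation
#' \deqn{CTC(t) = \frac{1}{TE} \log\frac{I(t_0)}{I(t)}}
#' at every in-mask voxel, where `I(t0)` is the pre-bolus baseline intensity.
#' The baseline may be averaged over the first `baseline_frames` frames to
#' reduce baseline noise; with the default of 1 frame the reference is the
#' single frame at `baseline_index`.
#'
#' Non-physical intensities are handled conservatively: `I(t) <= 0` is clamped
#' to `clamp_frac * I(t0)` before the log, and voxels whose baseline is not
#' strictly positive are removed from the mask and reported via the
#' `excluded` attribute.
#'
#' @param series A [dsc_series()].
#' @param baseline_frames Number of leading frames (starting at
#'   `baseline_index`) averaged to form the baseline (default 1).
#' @param clamp_frac Clamping floor for non-positive intensities, as a
#'   fraction of the voxel baseline (default 1e-6).
#' @return A [ctc_volume()] on the acquisition grid. Out-of-mask voxels are
#'   zero. Attribute `mask` holds the effective mask after exclusions;
#'   attribute `excluded` the integer count of voxels dropped for a
#'   non-positive baseline.
#' @export
signal_to_ctc <- function(series, baseline_frames = 1L, clamp_frac = 1e-6) {
  stopifnot(inherits(series, "dsc_series"))
  I <- series$intensities
  d <- dim(I)
  nt <- d[4]
  b0 <- series$baseline_index
  b1 <- min(nt, b0 + as.integer(baseline_frames) - 1L)
  base <- if (b1 > b0) apply(I[, , , b0:b1, drop = FALSE], 1:3, mean)
          else array(I[, , , b0], dim = d[1:3])

  mask <- if (is.null(series$brain_mask)) array(TRUE, d[1:3]) else series$brain_mask
  bad <- mask & !(base > 0)
  n_excluded <- sum(bad)
  mask[bad] <- FALSE

  ctc <- array(0, dim = d)
  floor_val <- clamp_frac * base
  for (t in seq_len(nt)) {
    It <- array(I[, , , t], dim = d[1:3])
    It <- pmax(It, floor_val)
    sl <- log(base / It) / series$te_seconds
    sl[!mask] <- 0
    ctc[, , , t] <- sl
  }
  out <- ctc_volume(ctc, series$dt_seconds)
  attr(out, "mask") <- mask
  attr(out, "excluded") <- n_excluded
  out
}

#' Resample a curve in time by cubic interpolation
#'
#' Re-grids a sampled curve onto `n_out` evenly spaced points spanning the
#' same physical time window, using a cubic interpolating spline. Endpoints
#' are preserved exactly and polynomials of degree up to three are reproduced.
#'
#' @param curve Numeric vector, length >= 4.
#' @param src_dt Source grid spacing in seconds.
#' @param n_out Number of output samples (>= 2).
#' @return Numeric vector of length `n_out` with attribute `dt_seconds`, the
#'   spacing of the new grid (chosen so the window `(length(curve)-1)*src_dt`
#'   is preserved).
#' @export
resample_temporal <- function(curve, src_dt, n_out) {
  curve <- as.numeric(curve)
  n_in <- length(curve)
  if (n_in < 4L) stop("cubic resampling needs at least 4 samples")
  if (n_out < 2L) stop("`n_out` must be >= 2")
  t_in <- (seq_len(n_in) - 1) * src_dt
  t_out <- seq(0, t_in[n_in], length.out = n_out)
  f <- stats::splinefun(t_in, curve, method = "fmm")
  out <- f(t_out)
  out[1] <- curve[1]
  out[n_out] <- curve[n_in]
  attr(out, "dt_seconds") <- t_in[n_in] / (n_out - 1)
  out
}

#' Resample every curve of a CTC volume onto a common grid
#'
#' Applies [resample_temporal()] voxel-wise; the conventional grid length for
#' cross-case pooling is 40 samples.
#'
#' @param ctc A [ctc_volume()].
#' @param n_out Target grid length (default 40).
#' @return A [ctc_volume()] with `n_time = n_out`.
#' @export
resample_ctc_volume <- function(ctc, n_out = 40L) {
  stopifnot(inherits(ctc, "ctc_volume"))
  d <- dim(ctc$curves)
  if (d[4] == n_out) return(ctc)
  flat <- matrix(ctc$curves, nrow = prod(d[1:3]), ncol = d[4])
  t_in <- (seq_len(d[4]) - 1) * ctc$dt_seconds
  t_out <- seq(0, t_in[d[4]], length.out = n_out)
  res <- t(apply(flat, 1, function(v)
    stats::splinefun(t_in, v, method = "fmm")(t_out)))
  res[, 1] <- flat[, 1]
  res[, n_out] <- flat[, d[4]]
  out <- ctc_volume(array(res, dim = c(d[1:3], n_out)),
                    dt_seconds = t_in[d[4]] / (n_out - 1))
  attr(out, "mask") <- attr(ctc, "mask")
  out
}

#' Average designated voxels into an arterial input function
#'
#' The arterial voxels themselves are chosen upstream (manually or by an
#' external tool); this helper only averages the concentration curves at the
#' given coordinates and optionally applies a centred moving-average low-pass
#' filter.
#'
#' @param ctc A [ctc_volume()].
#' @param coordinates Matrix or list of (x, y, z) voxel coordinates, 1-based.
#' @param lowpass_window Odd window length of the moving-average filter;
#'   `0` (default) disables filtering.
#' @return An [aif()] with source `"voxels"`.
#' @export
aif_from_voxels <- function(ctc, coordinates, lowpass_window = 0L) {
  stopifnot(inherits(ctc, "ctc_volume"))
  if (is.list(coordinates)) coordinates <- do.call(rbind, coordinates)
  coordinates <- matrix(as.integer(coordinates), ncol = 3)
  if (nrow(coordinates) < 1L) stop("at least one coordinate is required")
  d <- dim(ctc$curves)
  for (i in seq_len(nrow(coordinates))) {
    co <- coordinates[i, ]
    if (any(co < 1L) || any(co > d[1:3]))
      stop(sprintf("coordinate (%d, %d, %d) is outside the volume",
                   co[1], co[2], co[3]))
  }
  curves <- t(vapply(seq_len(nrow(coordinates)), function(i) {
    co <- coordinates[i, ]
    ctc$curves[co[1], co[2], co[3], ]
  }, numeric(d[4])))
  m <- colMeans(curves)
  if (lowpass_window > 1L) m <- moving_average(m, lowpass_window)
  aif(m, dt_seconds = ctc$dt_seconds, source = "voxels")
}

# Centred moving average with edge shrinkage (window truncated at the ends),
# used as the low-pass filter for arterial curves.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd")
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}
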