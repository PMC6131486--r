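#' Deconvolution configuration
#'
#' Settings for block-circulant SVD deconvolution. Two regularisations are
#' available: plain truncated SVD (`"tsvd"`, also called cSVD in the
#' block-circulant form), which zeroes singular values below a fixed fraction
#' of the largest one, and oscillation-index SVD (`"osvd"`), which raises the
#' truncation level per voxel until the recovered residue curve is smooth
#' enough.
#'
#' @param method `"tsvd"` or `"osvd"`.
#' @param truncation_fraction tSVD threshold as a fraction of the largest
#'   singular value (default 0.10).
#' @param oscillation_threshold oSVD oscillation-index limit (default 0.095).
#' @param pad_factor Circulant padding multiple of the grid length
#'   (default 2; time-domain zero padding makes the circular deconvolution
#'   delay-insensitive).
#' @param osvd_grid Increasing truncation fractions tried by oSVD; the first
#'   level whose residue passes the oscillation test is kept.
#' @return An object of class `deconv_config`.
#' @export
deconv_config <- function(method = c("osvd", "tsvd"),
                          truncation_fraction = 0.10,
                          oscillation_threshold = 0.095,
                          pad_factor = 2L,
                          osvd_grid = c(0.01, seq(0.02, 0.5, by = 0.02))) {
  method <- match.arg(method)
  if (truncation_fraction <= 0 || truncation_fraction >= 1)
    stop("`truncation_fraction` must lie in (0, 1)")
  if (oscillation_threshold <= 0 || oscillation_threshold >= 1)
    stop("`oscillation_threshold` must lie in (0, 1)")
  if (pad_factor < 2L) stop("`pad_factor` must be >= 2")
  structure(list(method = method,
                 truncation_fraction = truncation_fraction,
                 oscillation_threshold = oscillation_threshold,
                 pad_factor = as.integer(pad_factor),
                 osvd_grid = osvd_grid),
            class = "deconv_config")
}

#' Build the block-circulant convolution matrix of an AIF
#'
#' Returns the `n_pad x n_pad` circulant matrix `A` built from the
#' zero-padded arterial input curve and scaled by the grid spacing, so that
#' `A %*% r` is the discrete circular convolution of the AIF with `r` times
#' `dt`. Padding to at least twice the curve length turns circular
#' convolution into plain (linear) convolution for causal curves, which is
#' what makes the decomposition delay-insensitive.
#'
#' @param aif An [aif()].
#' @param n_pad Padded length, >= `length(aif$values)`.
#' @return Numeric `n_pad x n_pad` matrix.
#' @export
build_circulant <- function(aif, n_pad) {
  stopifnot(inherits(aif, "aif"))
  a <- aif$values
  n <- length(a)
  if (n_pad < n) stop("`n_pad` must be at least the AIF length")
  ap <- c(a, rep(0, n_pad - n))
  idx <- outer(seq_len(n_pad), seq_len(n_pad),
               function(i, j) ((i - j) %% n_pad) + 1L)
  matrix(ap[idx], n_pad, n_pad) * aif$dt_seconds
}

#' Oscillation index of a residue curve
#'
#' Normalised sum of absolute second differences,
#' `OI = 1/L * 1/max|R| * sum_k |R[k] - 2 R[k-1] + R[k-2]|`,
#' the roughness measure used to pick the per-voxel truncation level in
#' oscillation-index SVD.
#'
#' @param r Numeric residue curve.
#' @return Scalar oscillation index (0 for a flat or empty curve).
#' @export
oscillation_index <- function(r) {
  L <- length(r)
  m <- max(abs(r))
  if (L < 3L || m == 0) return(0)
  sum(abs(diff(r, differences = 2L))) / (L * m)
}

# Precompute the SVD of the padded circulant AIF matrix together with the
# truncated pseudo-inverses for a grid of threshold fractions. Sharing this
# across voxels is what makes whole-volume deconvolution cheap: applying a
# level is one matrix-vector product.
deconv_operator <- function(aif, n_time, cfg) {
  if (max(aif$values) <= 0) stop("AIF peak must be positive for deconvolution")
  n_pad <- cfg$pad_factor * n_time
  A <- build_circulant(aif, n_pad)
  sv <- svd(A)
  fractions <- if (cfg$method == "tsvd") cfg$truncation_fraction else cfg$osvd_grid
  smax <- sv$d[1]
  pinvs <- lapply(fractions, function(f) {
    dinv <- ifelse(sv$d >= f * smax, 1 / sv$d, 0)
    sv$v %*% (dinv * t(sv$u))
  })
  list(n_pad = n_pad, fractions = fractions, pinvs = pinvs, cfg = cfg)
}

# Deconvolve a matrix of padded tissue curves (n_pad x n_voxels) with a
# precomputed operator; returns the residue matrix (CBF * R, same shape).
deconv_apply <- function(op, C_pad) {
  if (op$cfg$method == "tsvd") return(op$pinvs[[1]] %*% C_pad)
  n_lv <- length(op$pinvs)
  R <- op$pinvs[[1]] %*% C_pad
  oi <- apply(R, 2, oscillation_index)
  pending <- which(oi > op$cfg$oscillation_threshold)
  lv <- 2L
  while (length(pending) > 0L && lv <= n_lv) {
    R2 <- op$pinvs[[lv]] %*% C_pad[, pending, drop = FALSE]
    oi2 <- apply(R2, 2, oscillation_index)
    R[, pending] <- R2
    pending <- pending[oi2 > op$cfg$oscillation_threshold]
    lv <- lv + 1L
  }
  R
}

#' Deconvolve a single tissue concentration curve
#'
#' Recovers the scaled residue function `CBF * R(t)` from a tissue
#' concentration-time curve and the arterial input function by inverting the
#' block-circulant convolution with truncated SVD; in oSVD mode the
#' truncation level is raised per voxel until the oscillation index of the
#' recovered curve drops below the configured threshold.
#'
#' @param ctc Numeric tissue curve on the same grid as `aif`.
#' @param aif An [aif()] with positive peak.
#' @param cfg A [deconv_config()].
#' @return An object of class `residue_curve`: list with `values` (length
#'   `pad_factor * n_time`), `dt_seconds`, and `truncation_fraction` actually
#'   used.
#' @export
deconvolve_voxel <- function(ctc, aif, cfg = deconv_config()) {
  stopifnot(inherits(aif, "aif"))
  ctc <- as.numeric(ctc)
  n <- length(ctc)
  if (n != length(aif$values)) stop("CTC and AIF must share one grid")
  if (all(ctc == 0)) {
    return(structure(list(values = rep(0, cfg$pad_factor * n),
                          dt_seconds = aif$dt_seconds,
                          truncation_fraction = NA_real_),
                     class = "residue_curve"))
  }
  op <- deconv_operator(aif, n, cfg)
  C_pad <- matrix(c(ctc, rep(0, op$n_pad - n)), ncol = 1)
  if (cfg$method == "tsvd") {
    R <- op$pinvs[[1]] %*% C_pad
    used <- cfg$truncation_fraction
  } else {
    R <- NULL
    used <- op$fractions[length(op$fractions)]
    for (lv in seq_along(op$pinvs)) {
      R <- op$pinvs[[lv]] %*% C_pad
      if (oscillation_index(R) <= cfg$oscillation_threshold) {
        used <- op$fractions[lv]
        break
      }
    }
  }
  structure(list(values = as.numeric(R), dt_seconds = aif$dt_seconds,
                 truncation_fraction = used),
            class = "residue_curve")
}

# Trapezoidal integral on an evenly spaced grid.
trapz <- function(y, dt) {
  n <- length(y)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

#' Relative cerebral blood volume of one voxel
#'
#' Ratio of the tissue curve's time integral to the arterial curve's,
#' `rCBV = integral(CTC) / integral(AIF)` (trapezoidal rule), with the
#' hematocrit/density proportionality constant fixed at 1, i.e. relative
#' units.
#'
#' @param ctc Numeric tissue curve.
#' @param aif An [aif()] with non-zero integral.
#' @return Scalar rCBV.
#' @export
compute_cbv <- function(ctc, aif) {
  stopifnot(inherits(aif, "aif"))
  ia <- trapz(aif$values, aif$dt_seconds)
  if (ia <= 0) stop("AIF integral must be positive")
  trapz(as.numeric(ctc), aif$dt_seconds) / ia
}

#' Scalar perfusion parameters of one voxel
#'
#' Reads the five standard parameters off a recovered residue curve and the
#' tissue/arterial curves: `rCBF = max(CBF * R)`; `rCBV` per [compute_cbv()];
#' `MTT = rCBV / rCBF` (central volume theorem); `TTP = dt * argmax(CTC)`;
#' `Tmax = dt * argmax(residue)`. Both argmaxes are taken over the
#' acquisition window (the first `n_time` samples of the padded residue) and
#' reported in seconds from the window start.
#'
#' @param residue A `residue_curve` from [deconvolve_voxel()].
#' @param ctc Numeric tissue curve (unpadded).
#' @param aif An [aif()].
#' @param cbf_floor rCBF values at or below this floor mark the voxel
#'   degenerate: MTT is set to `NA` and the `ok` flag cleared.
#' @return Named list `(cbf, cbv, mtt, ttp, tmax, ok)`.
#' @export
compute_scalar_params <- function(residue, ctc, aif, cbf_floor = 1e-9) {
  stopifnot(inherits(residue, "residue_curve"), inherits(aif, "aif"))
  ctc <- as.numeric(ctc)
  n_time <- length(ctc)
  r <- residue$values[seq_len(n_time)]
  cbf <- max(r)
  cbv <- compute_cbv(ctc, aif)
  dt <- aif$dt_seconds
  ttp <- dt * (which.max(ctc) - 1L)
  tmax <- dt * (which.max(r) - 1L)
  if (cbf <= cbf_floor) {
    list(cbf = cbf, cbv = cbv, mtt = NA_real_, ttp = ttp, tmax = tmax,
         ok = FALSE)
  } else {
    list(cbf = cbf, cbv = cbv, mtt = cbv / cbf, ttp = ttp, tmax = tmax,
         ok = TRUE)
  }
}

#' Compute all five perfusion maps for a case
#'
#' Whole-volume driver: deconvolves every in-mask voxel against the arterial
#' input function and assembles rCBF, rCBV, MTT, TTP and Tmax volumes.
#' Per-voxel failures (degenerate rCBF) are flagged in the QC report, never
#' fatal.
#'
#' @param ctc A [ctc_volume()].
#' @param aif_obj An [aif()] on the same grid.
#' @param cfg A [deconv_config()].
#' @param mask Optional 3D logical mask; defaults to the mask attribute of
#'   `ctc` or all voxels.
#' @param cbf_floor Degeneracy floor passed to [compute_scalar_params()].
#' @return An object of class `perfusion_maps`: list of five 3D arrays
#'   (`cbf`, `cbv`, `mtt`, `ttp`, `tmax`; out-of-mask voxels `NA`), plus
#'   `provenance` (method and thresholds, AIF source) and `qc` (counts of
#'   flagged voxels).
#' @export
maps_from_case <- function(ctc, aif_obj, cfg = deconv_config(), mask = NULL,
                           cbf_floor = 1e-9) {
  stopifnot(inherits(ctc, "ctc_volume"), inherits(aif_obj, "aif"))
  d <- dim(ctc$curves)
  n_time <- d[4]
  if (n_time != length(aif_obj$values))
    stop("CTC volume and AIF must share one grid")
  if (is.null(mask)) mask <- attr(ctc, "mask")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  empty <- array(NA_real_, d[1:3])
  maps <- list(cbf = empty, cbv = empty, mtt = empty, ttp = empty,
               tmax = empty)
  idx <- which(mask)
  if (length(idx) == 0L) {
    warning("empty mask: returning all-NA maps")
    maps <- lapply(maps, function(m) { m[] <- 0; m })
    return(structure(list(maps = maps, provenance = map_provenance(aif_obj, cfg),
                          qc = list(n_voxels = 0L, n_flagged = 0L)),
                     class = "perfusion_maps"))
  }

  flat <- matrix(ctc$curves, nrow = prod(d[1:3]), ncol = n_time)
  C <- t(flat[idx, , drop = FALSE])                    # n_time x n_voxels
  op <- deconv_operator(aif_obj, n_time, cfg)
  C_pad <- rbind(C, matrix(0, op$n_pad - n_time, ncol(C)))
  R <- deconv_apply(op, C_pad)[seq_len(n_time), , drop = FALSE]

  dt <- aif_obj$dt_seconds
  ia <- trapz(aif_obj$values, dt)
  if (ia <= 0) stop("AIF integral must be positive")
  cbf <- apply(R, 2, max)
  cbv <- (dt * (colSums(C) - (C[1, ] + C[n_time, ]) / 2)) / ia
  ttp <- dt * (max.col(t(C), ties.method = "first") - 1L)
  tmax <- dt * (max.col(t(R), ties.method = "first") - 1L)
  degenerate <- cbf <= cbf_floor
  mtt <- ifelse(degenerate, NA_real_, cbv / cbf)

  maps$cbf[idx] <- cbf
  maps$cbv[idx] <- cbv
  maps$mtt[idx] <- mtt
  maps$ttp[idx] <- ttp
  maps$tmax[idx] <- tmax
  structure(list(maps = maps,
                 provenance = map_provenance(aif_obj, cfg),
                 qc = list(n_voxels = length(idx),
                           n_flagged = sum(degenerate))),
            class = "perfusion_maps")
}

map_provenance <- function(aif_obj, cfg) {
  list(method = cfg$method,
       truncation_fraction = cfg$truncation_fraction,
       oscillation_threshold = cfg$oscillation_threshold,
       pad_factor = cfg$pad_factor,
       aif_source = aif_obj$source)
}
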