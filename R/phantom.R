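#' Simulation configuration for synthetic DSC cases
#'
#' Defines the forward model used to generate fully synthetic perfusion
#' cases: a gamma-variate arterial input function
#' `AIF(t) = amp * ((t - t0)/beta)^alpha * exp(-(t - t0)/beta)` for
#' `t >= t0`, convolved per voxel with a delayed mono-exponential residue
#' function `R(t) = exp(-(t - delay)/MTT) * 1[t >= delay]`, scaled by the
#' voxel's CBF. Concentration curves are converted to signal intensities by
#' the inverse susceptibility relation `I(t) = I0 * exp(-TE * CTC(t))`.
#'
#' @param dim_xyz Spatial dimensions `(nx, ny, nz)` of the simulated volume.
#' @param n_time Number of frames (default 40).
#' @param dt_seconds Frame spacing (default 1.5 s).
#' @param te_seconds Echo time (default 0.03 s).
#' @param aif_amplitude,aif_t0,aif_alpha,aif_beta Gamma-variate AIF
#'   parameters: peak scaling, bolus arrival time (s), shape, scale (s).
#' @param cbf_range Per-voxel CBF drawn log-uniformly over this range
#'   (relative units; default a 10x range `c(0.2, 2)`).
#' @param mtt_range Per-voxel MTT drawn uniformly (seconds, default
#'   `c(4, 12)`).
#' @param delay_range Per-voxel arrival delay drawn uniformly on the grid
#'   (seconds, default `c(0, 0)`, i.e. no dispersion of arrival).
#' @param i0 Pre-bolus baseline intensity (default 1000).
#' @param noise_snr_db Optional SNR (dB) of Gaussian noise added in
#'   intensity space; `NULL` for noiseless series.
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dim_xyz = c(16L, 16L, 2L), n_time = 40L,
                              dt_seconds = 1.5, te_seconds = 0.03,
                              aif_amplitude = 1, aif_t0 = 10,
                              aif_alpha = 3, aif_beta = 1.5,
                              cbf_range = c(0.2, 2), mtt_range = c(4, 12),
                              delay_range = c(0, 0), i0 = 1000,
                              noise_snr_db = NULL, seed = 1L) {
  if (aif_alpha <= 0 || aif_beta <= 0) stop("gamma-variate shape/scale must be positive")
  if (n_time < 4L) stop("`n_time` must be >= 4")
  if (any(cbf_range <= 0)) stop("`cbf_range` must be positive")
  if (diff(range(mtt_range)) < 0 || any(mtt_range <= 0))
    stop("`mtt_range` must be positive")
  structure(list(dim_xyz = as.integer(dim_xyz), n_time = as.integer(n_time),
                 dt_seconds = dt_seconds, te_seconds = te_seconds,
                 aif_amplitude = aif_amplitude, aif_t0 = aif_t0,
                 aif_alpha = aif_alpha, aif_beta = aif_beta,
                 cbf_range = cbf_range, mtt_range = mtt_range,
                 delay_range = delay_range, i0 = i0,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Gamma-variate arterial input curve
#'
#' @param t Time points (seconds).
#' @param amplitude Peak scaling.
#' @param t0 Bolus arrival time (s).
#' @param alpha Shape parameter.
#' @param beta Scale parameter (s).
#' @return Numeric vector; zero before `t0`, normalised so the maximum of
#'   the shape term is `amplitude`.
#' @export
gamma_variate_aif <- function(t, amplitude = 1, t0 = 10, alpha = 3,
                              beta = 1.5) {
  u <- (t - t0) / beta
  v <- ifelse(u > 0, u^alpha * exp(-u), 0)
  peak <- alpha^alpha * exp(-alpha)   # max of u^alpha e^-u at u = alpha
  amplitude * v / peak
}

#' Simulate a synthetic DSC case with known ground truth
#'
#' Draws per-voxel (CBF, MTT, delay), forms each tissue curve by discrete
#' convolution of the gamma-variate arterial curve with the voxel's delayed
#' exponential residue (times `dt`), converts concentrations to signal
#' intensities, and returns the series together with the analytic parameter
#' maps: `cbf`, `cbv = cbf * mtt`, `mtt`, `tmax = delay` (the residue peaks
#' at its arrival sample) and `ttp` (argmax of the noiseless tissue curve).
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `series` ([dsc_series()]), `ctc` (the
#'   noiseless [ctc_volume()]), `aif` ([aif()], source `"simulated"`),
#'   `truth` (a `perfusion_maps` object holding the analytic maps) and
#'   `id` (seed-derived case label).
#' @export
simulate_case <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  d <- cfg$dim_xyz
  nt <- cfg$n_time
  dt <- cfg$dt_seconds
  tt <- (seq_len(nt) - 1) * dt
  a <- gamma_variate_aif(tt, cfg$aif_amplitude, cfg$aif_t0, cfg$aif_alpha,
                         cfg$aif_beta)
  n_vox <- prod(d)
  sim <- with_seed(cfg$seed, {
    lu <- log(cfg$cbf_range)
    cbf <- exp(stats::runif(n_vox, lu[1], lu[2]))
    mtt <- stats::runif(n_vox, cfg$mtt_range[1], cfg$mtt_range[2])
    delay_s <- stats::runif(n_vox, cfg$delay_range[1], cfg$delay_range[2])
    # snap delays to the grid so the residue argmax is well defined
    delay <- round(delay_s / dt) * dt
    list(cbf = cbf, mtt = mtt, delay = delay)
  })
  if (any(sim$mtt <= dt))
    warning("some MTT values are at or below the frame spacing; kinetics under-resolved")

  ctc_flat <- matrix(0, nrow = n_vox, ncol = nt)
  ttp <- numeric(n_vox)
  for (i in seq_len(n_vox)) {
    r <- exp(-(tt - sim$delay[i]) / sim$mtt[i]) * (tt >= sim$delay[i])
    c_i <- sim$cbf[i] * dt * conv_linear(a, r)[seq_len(nt)]
    ctc_flat[i, ] <- c_i
    ttp[i] <- dt * (which.max(c_i) - 1L)
  }

  I <- cfg$i0 * exp(-cfg$te_seconds * ctc_flat)
  if (!is.null(cfg$noise_snr_db)) {
    I <- with_seed(cfg$seed + 1L, {
      sig_p <- mean(I^2)
      sd_n <- sqrt(sig_p / 10^(cfg$noise_snr_db / 10))
      I + matrix(stats::rnorm(length(I), 0, sd_n), nrow = n_vox)
    })
  }

  shape3 <- function(v) array(v, dim = d)
  truth <- structure(list(
    maps = list(cbf = shape3(sim$cbf), cbv = shape3(sim$cbf * sim$mtt),
                mtt = shape3(sim$mtt), ttp = shape3(ttp),
                tmax = shape3(sim$delay)),
    provenance = list(method = "analytic", aif_source = "simulated"),
    qc = list(n_voxels = n_vox, n_flagged = 0L)), class = "perfusion_maps")

  series <- dsc_series(array(I, dim = c(d, nt)), te_seconds = cfg$te_seconds,
                       dt_seconds = dt, baseline_index = 1L)
  list(series = series,
       ctc = ctc_volume(array(ctc_flat, dim = c(d, nt)), dt_seconds = dt),
       aif = aif(a, dt_seconds = dt, source = "simulated"),
       truth = truth,
       id = sprintf("sim%04d", cfg$seed))
}

# Linear (acyclic) discrete convolution, full length n+m-1.
conv_linear <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

#' Build a CBF noise phantom from one case
#'
#' Condenses a case into a small set of idealised concentration curves:
#' CBF values between their 5th and 95th percentiles are divided into
#' `n_bins` equal-width bins, and each bin's level curve is the
#' per-timepoint trimmed mean of the tissue curves of all voxels falling in
#' that bin. The arterial curve is low-pass filtered with a centred moving
#' average. Empty bins are dropped with a warning.
#'
#' @param ctc A [ctc_volume()].
#' @param cbf_map 3D array of CBF values aligned with `ctc`.
#' @param aif_obj An [aif()].
#' @param n_bins Number of CBF levels (default 12).
#' @param pct_low,pct_high Percentile window of CBF values used
#'   (defaults 5 and 95).
#' @param trim_frac Fraction trimmed from each tail of the per-timepoint
#'   mean (default 0.10).
#' @param lowpass_window Moving-average window for the AIF (default 3).
#' @param case_id Free-text identifier.
#' @return An object of class `phantom_case`: `level_curves` (matrix, one
#'   row per level), `level_values` (bin-centre CBF, strictly increasing),
#'   `aif`, `case_id`.
#' @export
build_phantom <- function(ctc, cbf_map, aif_obj, n_bins = 12L, pct_low = 5,
                          pct_high = 95, trim_frac = 0.10,
                          lowpass_window = 3L, case_id = "phantom") {
  stopifnot(inherits(ctc, "ctc_volume"), inherits(aif_obj, "aif"))
  v <- as.numeric(cbf_map)
  ok <- which(is.finite(v))
  if (length(ok) < n_bins * 10L)
    stop(sprintf("need at least %d finite voxels to build the phantom",
                 n_bins * 10L))
  q <- stats::quantile(v[ok], c(pct_low, pct_high) / 100, names = FALSE)
  edges <- seq(q[1], q[2], length.out = n_bins + 1L)
  centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  d <- dim(ctc$curves)
  flat <- matrix(ctc$curves, nrow = prod(d[1:3]), ncol = d[4])

  curves <- NULL
  values <- NULL
  for (b in seq_len(n_bins)) {
    in_bin <- ok[v[ok] >= edges[b] & (if (b == n_bins) v[ok] <= edges[b + 1]
                                      else v[ok] < edges[b + 1])]
    if (length(in_bin) == 0L) {
      warning(sprintf("CBF bin %d is empty and was dropped", b))
      next
    }
    lc <- apply(flat[in_bin, , drop = FALSE], 2, mean, trim = trim_frac)
    curves <- rbind(curves, lc)
    values <- c(values, centres[b])
  }
  a_f <- if (lowpass_window > 1L) moving_average(aif_obj$values, lowpass_window)
         else aif_obj$values
  structure(list(level_curves = unname(curves), level_values = values,
                 aif = aif(a_f, aif_obj$dt_seconds, source = "phantom-lowpass"),
                 case_id = case_id),
            class = "phantom_case")
}

#' Add white Gaussian noise at a given SNR
#'
#' Noise variance is set from the power SNR convention:
#' `var = mean(curve^2) / 10^(snr_db / 10)`.
#'
#' @param curve Numeric vector with positive power.
#' @param snr_db Signal-to-noise ratio in decibels.
#' @param seed Integer seed; the realisation is deterministic given it.
#' @return Noisy curve of the same length.
#' @export
add_awgn <- function(curve, snr_db, seed = 1L) {
  curve <- as.numeric(curve)
  p <- mean(curve^2)
  if (p <= 0) stop("curve has zero power; SNR is undefined")
  sd_n <- sqrt(p / 10^(snr_db / 10))
  curve + with_seed(seed, stats::rnorm(length(curve), 0, sd_n))
}

#' Noise-robustness experiment on CBF phantoms
#'
#' For every model, SNR level and repetition, adds white Gaussian noise to
#' each phantom level curve, predicts CBF from the noisy curve, and scores
#' the NRMSE of those predictions against the same model's predictions on
#' the noiseless curves (so the metric isolates noise sensitivity from model
#' bias). The block-circulant tSVD deconvolution baseline is included as the
#' pseudo-model `"csvd"`.
#'
#' Models trained on patch features wider than a single voxel are fed the
#' level curve tiled over the whole patch.
#'
#' @param models Named list of `dscml_model` objects (names label the rows).
#' @param phantoms List of `phantom_case` objects.
#' @param snr_grid Numeric SNR levels in dB (default
#'   `c(50, 40, 30, 20, 10, 5, 1)`).
#' @param n_reps Noise realisations per SNR (default 20).
#' @param seed Integer base seed.
#' @param include_csvd Include the deconvolution baseline (default TRUE).
#' @param csvd_cfg [deconv_config()] for the baseline (default tSVD 0.10).
#' @return Data frame with columns `model`, `snr_db`, `rep`, `nrmse`
#'   (`|models| * |snr_grid| * n_reps` rows, averaged over phantoms and
#'   levels within each row).
#' @export
noise_robustness_experiment <- function(models, phantoms,
                                        snr_grid = c(50, 40, 30, 20, 10, 5, 1),
                                        n_reps = 20L, seed = 1L,
                                        include_csvd = TRUE,
                                        csvd_cfg = deconv_config(method = "tsvd")) {
  stopifnot(length(phantoms) >= 1L, length(snr_grid) >= 1L)
  predictors <- lapply(models, function(m) {
    function(curves, aif_obj) predict_phantom_model(m, curves, aif_obj)
  })
  if (include_csvd) {
    predictors$csvd <- function(curves, aif_obj) {
      apply(curves, 1, function(cv) {
        r <- deconvolve_voxel(cv, aif_obj, csvd_cfg)
        max(r$values[seq_along(cv)])
      })
    }
  }

  # Noiseless reference predictions per model x phantom
  ref <- lapply(predictors, function(pf)
    lapply(phantoms, function(ph) pf(ph$level_curves, ph$aif)))

  rows <- vector("list", length(predictors) * length(snr_grid) * n_reps)
  k <- 0L
  for (mi in seq_along(predictors)) {
    mname <- names(predictors)[mi]
    for (s in snr_grid) {
      for (rep_i in seq_len(n_reps)) {
        errs <- vapply(seq_along(phantoms), function(pi) {
          ph <- phantoms[[pi]]
          sd_ <- seed + 7919L * pi + 101L * rep_i + round(13 * s)
          noisy <- t(vapply(seq_len(nrow(ph$level_curves)), function(li)
            add_awgn(ph$level_curves[li, ], s, seed = sd_ + li),
            numeric(ncol(ph$level_curves))))
          y0 <- ref[[mi]][[pi]]
          yn <- predictors[[mi]](noisy, ph$aif)
          rng <- diff(range(y0))
          if (rng == 0) rng <- max(abs(y0), 1e-12)
          sqrt(mean((yn - y0)^2)) / rng
        }, numeric(1))
        k <- k + 1L
        rows[[k]] <- data.frame(model = mname, snr_db = s, rep = rep_i,
                                nrmse = mean(errs))
      }
    }
  }
  do.call(rbind, rows)
}

# Feed phantom level curves to a patch-trained model: the level curve is
# replicated over every patch position, the phantom AIF appended.
predict_phantom_model <- function(model, curves, aif_obj) {
  nt <- ncol(curves)
  p_model <- model$provenance$p
  n_blocks <- p_model / nt - 1L
  if (n_blocks < 1L || p_model %% nt != 0L)
    stop("model feature width is incompatible with the phantom grid")
  X <- cbind(do.call(cbind, replicate(n_blocks, curves, simplify = FALSE)),
             matrix(aif_obj$values, nrow(curves), nt, byrow = TRUE))
  predict(model, X)
}
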