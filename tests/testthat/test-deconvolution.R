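test_that("build_circulant realises discrete circular convolution", {
  # impulse AIF with unit spacing gives the identity operator
  imp <- aif(c(1, rep(0, 7)), dt_seconds = 1, source = "test")
  A <- build_circulant(imp, 8)
  expect_equal(A, diag(8), tolerance = 1e-14)

  set.seed(21)
  a <- stats::runif(8)
  dt <- 1.5
  A2 <- build_circulant(aif(a, dt, "test"), 8)
  # circulant structure: every column is a cyclic shift of column 0
  for (j in 2:8)
    expect_equal(A2[, j], A2[((seq_len(8) - j) %% 8) + 1, 1])

  # double-loop circular convolution oracle
  r <- stats::rnorm(8)
  ref <- sapply(0:7, function(n) {
    s <- 0
    for (k in 0:7) s <- s + a[((n - k) %% 8) + 1] * r[k + 1]
    s * dt
  })
  expect_lt(max(abs(A2 %*% r - ref)), 1e-12)

  expect_error(build_circulant(aif(a, dt, "t"), 4), "at least")
})

test_that("deconvolution with an impulse AIF is the identity", {
  cv <- c(0, 1, 3, 2.5, 1.2, 0.4, 0.1, 0)
  imp <- aif(c(1, rep(0, 7)), 1, "test")
  r <- deconvolve_voxel(cv, imp, deconv_config(method = "tsvd"))
  expect_equal(r$values[1:8], cv, tolerance = 1e-10)
  expect_equal(length(r$values), 16L)

  # all-zero curve deconvolves to zero without touching the operator
  z <- deconvolve_voxel(rep(0, 8), imp, deconv_config())
  expect_equal(z$values, rep(0, 16))

  expect_error(
    suppressWarnings(deconvolve_voxel(cv, aif(rep(0, 8), 1, "t"))),
    "peak")
})

test_that("noiseless forward-simulated voxels are recovered", {
  # forward model: CTC = CBF * dt * (AIF conv exp(-t/MTT)); oSVD at its
  # default settings inverts the matched discrete operator near-exactly
  nt <- 40L; dt <- 1.5
  tt <- (0:(nt - 1)) * dt
  a <- gamma_variate_aif(tt, 1, 10, 3, 1.5)
  aobj <- aif(a, dt, "sim")
  for (mtt in c(4, 8, 12)) {
    cbf <- 1.3
    r_true <- exp(-tt / mtt)
    cv <- cbf * dt * stats::convolve(a, rev(r_true), type = "open")[1:nt]
    dec <- deconvolve_voxel(cv, aobj, deconv_config(method = "osvd"))
    cbf_hat <- max(dec$values[1:nt])
    expect_lt(abs(cbf_hat - cbf) / cbf, 0.02)
  }
})

test_that("delay insensitivity: circular delays shift Tmax, not CBF", {
  nt <- 40L; dt <- 1.5
  tt <- (0:(nt - 1)) * dt
  a <- gamma_variate_aif(tt, 1, 10, 3, 1.5)
  aobj <- aif(a, dt, "sim")
  cv <- 0.9 * dt * stats::convolve(a, rev(exp(-tt / 6)), type = "open")[1:nt]
  cfg <- deconv_config(method = "tsvd")
  base <- deconvolve_voxel(cv, aobj, cfg)
  cbf0 <- max(base$values[1:nt])
  i0 <- which.max(base$values[1:nt])
  for (d in 1:3) {
    cvd <- cv[((seq_len(nt) - 1 - d) %% nt) + 1]
    dec <- deconvolve_voxel(cvd, aobj, cfg)
    expect_lt(abs(max(dec$values[1:nt]) - cbf0) / cbf0, 0.05)
    expect_equal(which.max(dec$values[1:nt]) - i0, d)
  }
})

test_that("compute_cbv is the trapezoidal integral ratio", {
  nt <- 40L; dt <- 1.5
  a <- gamma_variate_aif((0:(nt - 1)) * dt, 1, 10, 3, 1.5)
  aobj <- aif(a, dt, "sim")
  expect_equal(compute_cbv(a, aobj), 1)
  expect_equal(compute_cbv(rep(0, nt), aobj), 0)
  # scaled and circularly delayed copy: integral ratio stays 2
  cv <- 2 * a[((seq_len(nt) - 1 - 4) %% nt) + 1]
  expect_lt(abs(compute_cbv(cv, aobj) - 2), 1e-6)
  neg <- suppressWarnings(aif(c(-1, rep(0, nt - 1)), dt, "t"))
  expect_error(compute_cbv(a, neg), "positive")
})

test_that("scalar parameters read off the residue and curves correctly", {
  res <- structure(list(values = c(0, 5, 3, 1, rep(0, 12)), dt_seconds = 1.5,
                        truncation_fraction = 0.1), class = "residue_curve")
  a <- aif(c(1, 2, 1, rep(0, 5)), 1.5, "t")
  cv <- c(0, 1, 2, 1, 0.5, 0.2, 0, 0)
  p <- compute_scalar_params(res, cv, a)
  expect_equal(p$cbf, 5)
  expect_equal(p$tmax, 1.5)
  expect_equal(p$ttp, 1.5 * 2)          # ctc peaks at sample 3 (0-based 2)
  expect_equal(p$mtt, p$cbv / p$cbf)
  expect_true(p$ok)

  # degenerate residue: mtt masked
  res0 <- structure(list(values = rep(0, 16), dt_seconds = 1.5,
                         truncation_fraction = 0.1), class = "residue_curve")
  p0 <- compute_scalar_params(res0, cv, a)
  expect_false(p0$ok)
  expect_true(is.na(p0$mtt))
})

test_that("central volume: CBV matches a scalar oracle exactly and
           approaches cbf * mtt in the continuum limit", {
  nt <- 40L; dt <- 1.5
  tt <- (0:(nt - 1)) * dt
  a <- gamma_variate_aif(tt, 1, 10, 3, 1.5)
  aobj <- aif(a, dt, "sim")
  for (mtt in c(4, 7, 12)) {
    cbf <- 0.8
    r <- exp(-tt / mtt)
    cv <- cbf * dt * stats::convolve(a, rev(r), type = "open")[1:nt]
    # fully independent scalar oracle: double-loop convolution + hand trapz
    cv_ref <- sapply(0:(nt - 1), function(n) {
      s <- 0
      for (k in 0:n) s <- s + a[k + 1] * r[n - k + 1]
      cbf * dt * s
    })
    expect_lt(max(abs(cv - cv_ref)), 1e-9)
    tr <- function(v) dt * (sum(v) - (v[1] + v[nt]) / 2)
    expect_equal(compute_cbv(cv, aobj), tr(cv_ref) / tr(a), tolerance = 1e-9)
  }
  # continuum limit: at fine sampling the ratio approaches cbf * mtt
  # (at dt = 1.5 s it carries the known +dt/2 half-cell offset instead)
  ntf <- 800L; dtf <- 0.15   # 120 s window so the venous tail is negligible
  ttf <- (0:(ntf - 1)) * dtf
  af <- gamma_variate_aif(ttf, 1, 10, 3, 1.5)
  aobjf <- aif(af, dtf, "sim")
  for (mtt in c(4, 8, 12)) {
    cvf <- 0.8 * dtf * stats::convolve(af, rev(exp(-ttf / mtt)), type = "open")[1:ntf]
    expect_lt(abs(compute_cbv(cvf, aobjf) - 0.8 * mtt) / (0.8 * mtt), 0.02)
  }
})

test_that("maps_from_case drives the voxel pipeline over a volume", {
  # spatially constant volume -> spatially constant maps
  nt <- 40L; dt <- 1.5
  tt <- (0:(nt - 1)) * dt
  a <- gamma_variate_aif(tt, 1, 10, 3, 1.5)
  cv <- 0.7 * dt * stats::convolve(a, rev(exp(-tt / 7)), type = "open")[1:nt]
  cur <- array(rep(cv, each = 4 * 4), dim = c(4, 4, 1, nt))
  ctc <- ctc_volume(aperm(array(cv, dim = c(nt, 4, 4, 1)), c(2, 3, 4, 1)), dt)
  m <- maps_from_case(ctc, aif(a, dt, "sim"))
  for (nm in names(m$maps))
    expect_equal(diff(range(m$maps[[nm]])), 0)

  # linearity: scaling the curves scales cbf/cbv, fixes mtt/ttp/tmax
  ctc3 <- ctc_volume(3 * ctc$curves, dt)
  m3 <- maps_from_case(ctc3, aif(a, dt, "sim"))
  expect_equal(m3$maps$cbf, 3 * m$maps$cbf, tolerance = 1e-8)
  expect_equal(m3$maps$cbv, 3 * m$maps$cbv, tolerance = 1e-8)
  expect_equal(m3$maps$mtt, m$maps$mtt, tolerance = 1e-8)
  expect_equal(m3$maps$ttp, m$maps$ttp)
  expect_equal(m3$maps$tmax, m$maps$tmax)

  # empty mask warns and returns zero maps
  expect_warning(
    m0 <- maps_from_case(ctc, aif(a, dt, "sim"),
                         mask = array(FALSE, c(4, 4, 1))),
    "empty mask")
  expect_equal(max(abs(m0$maps$cbf)), 0)
})

test_that("whole-volume recovery matches per-voxel ground truth at zero
           noise", {
  cs <- small_case(seed = 31L)
  cbf_err <- abs(cs$maps$maps$cbf - cs$sim$truth$maps$cbf) /
    cs$sim$truth$maps$cbf
  expect_lt(max(cbf_err), 0.10)
  expect_equal(cs$maps$maps$tmax, cs$sim$truth$maps$tmax)
  expect_equal(cs$maps$maps$ttp, cs$sim$truth$maps$ttp)
})

test_that("oSVD residues satisfy the oscillation constraint by
           construction", {
  cs <- small_case(seed = 32L, dim_xyz = c(6L, 6L, 1L))
  cfg <- deconv_config(method = "osvd")
  flat <- matrix(cs$ctc$curves, 36, 40)
  ois <- apply(flat[1:12, ], 1, function(cv) {
    oscillation_index(deconvolve_voxel(cv, cs$aif, cfg)$values)
  })
  expect_true(all(ois <= cfg$oscillation_threshold))
})
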