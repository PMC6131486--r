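test_that("extract_patch concatenates patch curves then the AIF", {
  set.seed(5)
  nt <- 40L
  cur <- array(stats::rnorm(7 * 7 * 2 * nt), dim = c(7, 7, 2, nt))
  ctc <- ctc_volume(cur, 1.5)
  a <- aif(abs(stats::rnorm(nt)) + 0.1, 1.5, "test")

  v0 <- extract_patch(ctc, a, 4, 4, 1, e = 0)
  expect_length(v0, 80L)
  expect_equal(v0[1:40], cur[4, 4, 1, ], ignore_attr = TRUE)
  expect_equal(v0[41:80], a$values, ignore_attr = TRUE)

  v2 <- extract_patch(ctc, a, 4, 4, 2, e = 2)
  expect_length(v2, 1040L)
  # centre block sits at positions [12*40, 13*40) (0-based)
  expect_equal(v2[(12 * 40 + 1):(13 * 40)], cur[4, 4, 2, ],
               ignore_attr = TRUE)
  # row-major ordering: first block is (x-2, y-2), second (x-1, y-2)
  expect_equal(v2[1:40], cur[2, 2, 2, ], ignore_attr = TRUE)
  expect_equal(v2[41:80], cur[3, 2, 2, ], ignore_attr = TRUE)
  expect_equal(v2[1001:1040], a$values, ignore_attr = TRUE)

  # spatially constant volume: all patch blocks equal the centre block
  cc <- ctc_volume(array(rep(cur[1, 1, 1, ], each = 49),
                         dim = c(7, 7, 1, nt))[, , 1, , drop = FALSE], 1.5)
  vc <- extract_patch(cc, a, 4, 4, 1, e = 1)
  for (b in 0:8)
    expect_equal(vc[(b * 40 + 1):((b + 1) * 40)], vc[1:40])

  expect_error(extract_patch(ctc, a, 1, 4, 1, e = 2), "border")
  # edge replication fills the border patch instead
  vp <- extract_patch(ctc, a, 1, 4, 1, e = 2, pad = TRUE)
  expect_length(vp, 1040L)
})

test_that("uniform_range_sample flattens the target distribution", {
  # already uniform targets: near-equal bin occupancy
  set.seed(6)
  u <- stats::runif(5000)
  idx <- uniform_range_sample(u, 1200, n_bins = 12, seed = 3)
  expect_length(idx, 1200L)
  expect_length(unique(idx), 1200L)
  counts <- table(cut(u[idx], seq(min(u), max(u), length.out = 13),
                      include.lowest = TRUE))
  expect_true(max(counts) - min(counts) <= 1)

  # degenerate range: single bin still returns n draws
  same <- uniform_range_sample(rep(2.5, 400), 50, n_bins = 12, seed = 3)
  expect_length(same, 50L)

  # skewed targets with all bins populated get flattened: chi-square on the
  # sampled histogram accepts uniformity
  sk <- stats::rbeta(20000, 2, 2)
  idx2 <- uniform_range_sample(sk, 1000, n_bins = 10, seed = 4)
  rng <- range(sk)
  edges <- seq(rng[1], rng[2], length.out = 11)
  cnt <- as.numeric(table(cut(sk[idx2], edges, include.lowest = TRUE)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)

  # heavily skewed targets: rich bins keep their full quota, sparse bins are
  # exhausted, and the shortfall lands on the bins with the most headroom
  ex <- stats::rexp(20000, rate = 3)
  idx3 <- uniform_range_sample(ex, 1000, n_bins = 10, seed = 5)
  rngx <- range(ex)
  edgx <- seq(rngx[1], rngx[2], length.out = 11)
  avail <- as.numeric(table(cut(ex, edgx, include.lowest = TRUE)))
  got <- as.numeric(table(cut(ex[idx3], edgx, include.lowest = TRUE)))
  expect_equal(sum(got), 1000)
  expect_true(all(got[avail >= 100] >= 100))
  expect_true(all(got[avail < 100] == avail[avail < 100]))

  # determinism and the too-few-voxels warning
  expect_identical(uniform_range_sample(u, 500, seed = 9),
                   uniform_range_sample(u, 500, seed = 9))
  expect_warning(uniform_range_sample(u[1:80], 200, seed = 1), "available")
})

test_that("build_dataset assembles aligned, reproducible feature tables", {
  cases <- list(small_case(seed = 41L, dim_xyz = c(12L, 12L, 2L)),
                small_case(seed = 42L, dim_xyz = c(12L, 12L, 2L)))
  ds <- build_dataset(cases, "cbf", e = 2L, n_samples = 100L, seed = 7)
  expect_equal(nrow(ds$X), 100L)
  expect_equal(ncol(ds$X), 1040L)
  expect_length(ds$y, 100L)
  expect_true(all(is.finite(ds$y)))
  # per-case quota
  expect_true(all(table(ds$voxels$case) == 50))
  # patch-interior coordinates only
  expect_true(all(ds$voxels$x >= 3 & ds$voxels$x <= 10))
  expect_true(all(ds$voxels$y >= 3 & ds$voxels$y <= 10))
  # no duplicated voxel ids
  expect_false(any(duplicated(ds$voxels)))
  # targets align with the map values at the sampled voxels
  i <- 17L
  cs <- cases[[which(vapply(cases, function(c) c$id, "") == ds$voxels$case[i])]]
  expect_equal(ds$y[i],
               cs$maps$maps$cbf[ds$voxels$x[i], ds$voxels$y[i], ds$voxels$z[i]])

  # determinism: same seed, identical dataset
  ds2 <- build_dataset(cases, "cbf", e = 2L, n_samples = 100L, seed = 7)
  expect_identical(ds, ds2)

  # slice exclusion: volume with 5 slices drops the lowest by default
  tall <- small_case(seed = 43L, dim_xyz = c(8L, 8L, 5L))
  ds3 <- build_dataset(list(tall), "cbf", e = 0L, n_samples = 60L,
                       drop_low_frac = 0.2, seed = 8)
  expect_true(all(ds3$voxels$z >= 2))

  # feature rows reconstruct the centre CTC (ordering round trip)
  e <- 2L; nt <- 40L
  centre0 <- ((2 * e + 1)^2 - 1) / 2 * nt
  v <- ds$X[i, (centre0 + 1):(centre0 + nt)]
  expect_equal(v,
               cs$ctc$curves[ds$voxels$x[i], ds$voxels$y[i], ds$voxels$z[i], ],
               ignore_attr = TRUE)

  expect_error(build_dataset(cases, "nope", n_samples = 50L),
               "'arg' should be one of")
})
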