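#' Extract the patch feature vector of one voxel
#'
#' The regression input for a voxel at (x, y) in slice z is the concatenation
#' of the concentration-time curves of the in-plane `(2e+1) x (2e+1)` patch
#' centred on the voxel, in row-major order (x varying fastest, then y),
#' followed by the arterial input function:
#' `[C(x-e,y-e), C(x-e+1,y-e), ..., C(x,y), ..., C(x+e,y+e), A]`.
#' With grid length `n_time` the vector has `((2e+1)^2 + 1) * n_time`
#' entries; the centre curve occupies the block starting at
#' `((2e+1)^2 - 1) / 2 * n_time` (0-based).
#'
#' @param ctc A [ctc_volume()].
#' @param aif_obj An [aif()] on the same grid.
#' @param x,y,z 1-based voxel coordinates.
#' @param e Patch half-width (>= 0); patches are in-plane only.
#' @param pad If `TRUE`, patches crossing the in-plane border are completed
#'   by edge replication; if `FALSE` (default) such voxels are an error (the
#'   dataset builder skips them instead).
#' @return Numeric feature vector with attribute `voxel_id = c(x, y, z)`.
#' @export
extract_patch <- function(ctc, aif_obj, x, y, z, e = 0L, pad = FALSE) {
  stopifnot(inherits(ctc, "ctc_volume"), inherits(aif_obj, "aif"))
  d <- dim(ctc$curves)
  e <- as.integer(e)
  if (e < 0L) stop("`e` must be >= 0")
  if (x < 1L || x > d[1] || y < 1L || y > d[2] || z < 1L || z > d[3])
    stop("voxel coordinate outside the volume")
  xs <- (x - e):(x + e)
  ys <- (y - e):(y + e)
  if (!pad && (min(xs) < 1L || max(xs) > d[1] || min(ys) < 1L || max(ys) > d[2]))
    stop("patch crosses the in-plane border (enable `pad` to replicate edges)")
  xs <- pmin(pmax(xs, 1L), d[1])
  ys <- pmin(pmax(ys, 1L), d[2])
  blocks <- ctc$curves[xs, ys, z, , drop = FALSE]     # (2e+1, 2e+1, 1, nt)
  w <- 2L * e + 1L
  nt <- d[4]
  # row-major over the patch: x fastest, then y; block m holds curve m
  flat <- aperm(array(blocks, dim = c(w, w, nt)), c(3, 1, 2))
  out <- c(as.numeric(flat), aif_obj$values)
  attr(out, "voxel_id") <- c(x = x, y = y, z = z)
  out
}

#' Sample voxels uniformly over the range of a target map
#'
#' Drawing training voxels from the empirical distribution of a perfusion
#' parameter over-represents its bulk; this sampler instead divides the
#' target range into `n_bins` equal-width bins and draws (without
#' replacement) an equal quota from each, redistributing the shortfall of
#' sparse bins to the bins with the most remaining voxels.
#'
#' @param targets Numeric vector (or 3D array) of target values; `NA`s are
#'   excluded.
#' @param n Number of voxels requested.
#' @param n_bins Number of equal-width bins (default 12).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param eligible Optional logical vector/array marking voxels that may be
#'   drawn (e.g. patch-interior voxels); defaults to all finite targets.
#' @return Integer vector of (linear) voxel indices into `targets`,
#'   length `min(n, n available)`.
#' @export
uniform_range_sample <- function(targets, n, n_bins = 12L, seed = 1L,
                                 eligible = NULL) {
  v <- as.numeric(targets)
  ok <- is.finite(v)
  if (!is.null(eligible)) ok <- ok & as.logical(eligible)
  avail <- which(ok)
  if (length(avail) == 0L) stop("no finite, eligible target voxels")
  if (n < n_bins) stop("`n` must be at least `n_bins`")
  if (length(avail) <= n) {
    if (length(avail) < n)
      warning(sprintf("only %d eligible voxels available (requested %d)",
                      length(avail), n))
    return(avail)
  }
  rng <- range(v[avail])
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(avail))
    n_bins <- 1L
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(v[avail], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  by_bin <- split(avail, factor(bin, levels = seq_len(n_bins)))
  sizes <- lengths(by_bin)
  quota <- rep(n %/% n_bins, n_bins)
  quota[seq_len(n %% n_bins)] <- quota[seq_len(n %% n_bins)] + 1L
  take <- pmin(quota, sizes)
  short <- n - sum(take)
  while (short > 0L) {
    headroom <- sizes - take
    if (all(headroom == 0L)) break
    b <- which.max(headroom)
    add <- min(short, headroom[b])
    take[b] <- take[b] + add
    short <- short - add
  }
  out <- integer(0)
  with_seed(seed, {
    for (b in seq_len(n_bins)) {
      if (take[b] == 0L) next
      ids <- by_bin[[b]]
      out <- c(out, if (length(ids) == 1L) ids else
        sample(ids, take[b], replace = FALSE))
    }
  })
  sort(out)
}

#' Build a patch-regression dataset from processed cases
#'
#' Pairs patch feature vectors (concentration curves of an in-plane patch
#' plus the arterial input function) with one perfusion parameter value per
#' voxel, taken from each case's reference maps. Low slices (where parameter
#' estimates are typically unreliable) are excluded, the per-case voxel quota
#' is drawn uniformly over the parameter range, and border voxels whose patch
#' would leave the slice are skipped.
#'
#' @param cases List of cases; each a list with elements `ctc`
#'   ([ctc_volume()]), `aif` ([aif()]), `maps` (`perfusion_maps`) and
#'   optionally `id`.
#' @param parameter One of `"cbf"`, `"cbv"`, `"mtt"`, `"ttp"`, `"tmax"`.
#' @param e Patch half-width.
#' @param n_samples Total number of rows; split into equal per-case quotas.
#' @param drop_low_frac Fraction of the lowest slices excluded per case
#'   (default 0.2); ignored when `slice_range` is given.
#' @param slice_range Optional inclusive 1-based `(first, last)` slice range
#'   to keep.
#' @param n_bins Bins for [uniform_range_sample()].
#' @param seed Integer seed; datasets are byte-identical given the seed.
#' @return An object of class `feature_dataset`: list with `X` (numeric
#'   matrix, one row per voxel), `y` (targets), `voxels` (data frame: case,
#'   x, y, z) and `provenance`.
#' @export
build_dataset <- function(cases, parameter, e = 0L, n_samples = 1000L,
                          drop_low_frac = 0.2, slice_range = NULL,
                          n_bins = 12L, seed = 1L) {
  parameter <- match.arg(parameter, c("cbf", "cbv", "mtt", "ttp", "tmax"))
  n_cases <- length(cases)
  if (n_cases == 0L) stop("no cases supplied")
  quota <- rep(n_samples %/% n_cases, n_cases)
  quota[seq_len(n_samples %% n_cases)] <- quota[seq_len(n_samples %% n_cases)] + 1L

  X_rows <- vector("list", n_cases)
  y_all <- vector("list", n_cases)
  vox_all <- vector("list", n_cases)
  for (ci in seq_len(n_cases)) {
    cs <- cases[[ci]]
    if (is.null(cs$maps$maps[[parameter]]))
      stop(sprintf("case %s lacks a '%s' map",
                   cs$id %||% as.character(ci), parameter))
    tgt <- cs$maps$maps[[parameter]]
    d <- dim(tgt)
    keep_z <- if (!is.null(slice_range)) {
      if (slice_range[1] < 1L || slice_range[2] > d[3])
        stop("`slice_range` outside the volume")
      seq(slice_range[1], slice_range[2])
    } else {
      seq(floor(drop_low_frac * d[3]) + 1L, d[3])
    }
    elig <- array(FALSE, d)
    xr <- if (2L * e + 1L > d[1]) integer(0) else seq(1L + e, d[1] - e)
    yr <- if (2L * e + 1L > d[2]) integer(0) else seq(1L + e, d[2] - e)
    if (length(xr) == 0L || length(yr) == 0L)
      stop("patch half-width `e` too large for the volume extent")
    elig[xr, yr, keep_z] <- TRUE
    idx <- uniform_range_sample(tgt, quota[ci], n_bins = n_bins,
                                seed = seed + ci, eligible = elig)
    co <- arrayInd(idx, d)
    nt <- cs$ctc$n_time
    w <- (2L * e + 1L)^2 + 1L
    M <- matrix(NA_real_, nrow = length(idx), ncol = w * nt)
    for (i in seq_along(idx)) {
      M[i, ] <- extract_patch(cs$ctc, cs$aif, co[i, 1], co[i, 2], co[i, 3],
                              e = e)
    }
    X_rows[[ci]] <- M
    y_all[[ci]] <- tgt[idx]
    vox_all[[ci]] <- data.frame(case = cs$id %||% ci, x = co[, 1],
                                y = co[, 2], z = co[, 3])
  }
  X <- do.call(rbind, X_rows)
  y <- unlist(y_all, use.names = FALSE)
  structure(list(X = X, y = y, voxels = do.call(rbind, vox_all),
                 provenance = list(parameter = parameter, e = e,
                                   n_time = cases[[1]]$ctc$n_time,
                                   n_bins = n_bins, seed = seed,
                                   n_cases = n_cases)),
            class = "feature_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code with a local, restored RNG state so that seeded draws do not
# perturb (or depend on) the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
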