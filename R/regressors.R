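#' @title Regression families for perfusion-map reconstruction
#' @description Six regression families behind one fit/predict contract:
#'   multiple linear regression, ridge regression (linear and Gaussian
#'   kernel), epsilon support-vector regression, a feedforward multilayer
#'   perceptron and a bagged random forest. All fitted objects share class
#'   `dscml_model`, are deterministic given their seed, and serialise with
#'   `saveRDS()` to identical predictions.
#' @name regressors
NULL

new_model <- function(family, fit, spec, scaler = NULL, provenance = NULL) {
  structure(list(family = family, fit = fit, spec = spec, scaler = scaler,
                 provenance = provenance),
            class = c(paste0("dscml_", family), "dscml_model"))
}

# Column standardisation fitted on the training set only; constant columns
# get unit scale so they map to zero rather than NaN.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(center = mu, scale = sd_)
}
apply_scaler <- function(scaler, X) {
  if (is.null(scaler)) return(X)
  if (ncol(X) != length(scaler$center))
    stop(sprintf("feature width mismatch: expected %d, got %d",
                 length(scaler$center), ncol(X)))
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y have mismatched lengths")
  if (any(!is.finite(y))) stop("targets must be finite")
  list(X = X, y = y)
}

#' Fit a multiple linear regression by QR factorisation
#'
#' Least-squares fit of `y ~ X` (with intercept) solved through the QR
#' factorisation of the design matrix rather than the normal equations.
#' Rank-deficient designs fall back to the minimum-norm solution (deficient
#' coefficients zeroed) with a warning.
#'
#' @param X Numeric feature matrix, one row per sample.
#' @param y Numeric target vector.
#' @return A `dscml_model` of family `"linear"`.
#' @export
fit_linear <- function(X, y) {
  d <- check_xy(X, y)
  A <- cbind(`(Intercept)` = 1, d$X)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A))
    warning("rank-deficient design: minimum-norm coefficients used")
  beta <- qr.coef(qr_, d$y)
  beta[is.na(beta)] <- 0
  new_model("linear", list(beta = beta), spec = list(),
            provenance = list(n = nrow(d$X), p = ncol(d$X)))
}

#' @export
predict.dscml_linear <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  check_width(object, ncol(X), length(object$fit$beta) - 1L)
  if (nrow(X) == 0L) return(numeric(0))
  as.numeric(cbind(1, X) %*% object$fit$beta)
}

#' Fit ridge or Gaussian-kernel ridge regression
#'
#' Solves the regularised least-squares problem in its dual form
#' `(K + alpha I) a = y` by Cholesky factorisation, with `K = X Xᵀ` for the
#' linear kernel or the Gaussian (RBF) kernel matrix. Features are
#' standardised and targets centred internally. For the linear kernel with
#' more rows than columns the mathematically identical primal system
#' `(XᵀX + alpha I) b = Xᵀy` is factorised instead, which is much cheaper
#' and yields the same predictions.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric targets.
#' @param alpha Regularisation strength (> 0), default 1.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param sigma Gaussian kernel width; `NULL` (default) uses the median
#'   pairwise-distance heuristic on a subsample.
#' @param seed Seed for the sigma-heuristic subsample.
#' @return A `dscml_model` of family `"ridge"` (linear) or `"kernel_ridge"`.
#' @export
fit_ridge <- function(X, y, alpha = 1, kernel = c("linear", "gaussian"),
                      sigma = NULL, seed = 1L, chol_limit = 8000L) {
  kernel <- match.arg(kernel)
  if (alpha <= 0) stop("`alpha` must be positive")
  d <- check_xy(X, y)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(scaler, d$X)
  y_mean <- mean(d$y)
  yc <- d$y - y_mean
  n <- nrow(Xs); p <- ncol(Xs)
  if (kernel == "linear") {
    if (n > p) {
      G <- crossprod(Xs)
      diag(G) <- diag(G) + alpha
      b <- chol_solve(G, crossprod(Xs, yc))
      fit <- list(mode = "primal", beta = as.numeric(b), y_mean = y_mean)
    } else {
      K <- tcrossprod(Xs)
      diag(K) <- diag(K) + alpha
      a <- chol_solve(K, yc)
      fit <- list(mode = "dual", a = a, Xtrain = Xs, y_mean = y_mean)
    }
    fam <- "ridge"
    sigma <- NA_real_
  } else {
    if (is.null(sigma)) sigma <- median_sigma(Xs, seed)
    K <- rbf_kernel(Xs, Xs, sigma)
    diag(K) <- diag(K) + alpha
    # Cholesky needs a second n x n triangle; above `chol_limit` rows the
    # system is solved by conjugate gradients instead (same solution to
    # solver tolerance, roughly half the peak memory)
    a <- if (n <= chol_limit) chol_solve(K, yc) else cg_solve(K, yc)
    rm(K); gc(FALSE)   # release the n x n kernel before returning
    fit <- list(mode = "dual", a = a, Xtrain = Xs, y_mean = y_mean,
                sigma = sigma)
    fam <- "kernel_ridge"
  }
  new_model(fam, fit, spec = list(alpha = alpha, kernel = kernel,
                                  sigma = sigma),
            scaler = scaler, provenance = list(n = n, p = p))
}

chol_solve <- function(A, b) {
  U <- chol(A)
  as.numeric(backsolve(U, forwardsolve(t(U), b)))
}

# Jacobi-preconditioned conjugate gradients for a symmetric positive
# definite system; used for large kernel systems where a Cholesky copy
# would double peak memory.
cg_solve <- function(A, b, tol = 1e-10, maxit = 1000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b * b))
  for (i in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    al <- rz / sum(p * Ap)
    x <- x + al * p
    r <- r - al * Ap
    if (sqrt(sum(r * r)) <= tol * b2) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

# Squared Euclidean cross-distances via the Gram expansion, computed in
# column blocks to keep peak memory near one |A| x |B| matrix.
cross_dist2 <- function(A, B, block = 2000L) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  n <- nrow(A); m <- nrow(B)
  D2 <- matrix(0, n, m)
  for (j0 in seq(1L, m, by = block)) {
    j1 <- min(m, j0 + block - 1L)
    blk <- an - 2 * tcrossprod(A, B[j0:j1, , drop = FALSE])
    blk <- sweep(blk, 2, bn[j0:j1], "+")
    blk[blk < 0] <- 0
    D2[, j0:j1] <- blk
  }
  D2
}

rbf_kernel <- function(A, B, sigma, block = 1000L) {
  n <- nrow(A); m <- nrow(B)
  K <- matrix(0, n, m)
  s2 <- 2 * sigma^2
  for (j0 in seq(1L, m, by = block)) {
    j1 <- min(m, j0 + block - 1L)
    blk <- rowSums(A^2) - 2 * tcrossprod(A, B[j0:j1, , drop = FALSE])
    blk <- sweep(blk, 2, rowSums(B[j0:j1, , drop = FALSE]^2), "+")
    blk[blk < 0] <- 0
    K[, j0:j1] <- exp(-blk / s2)
  }
  K
}

# Median pairwise distance over a subsample of at most 500 rows.
median_sigma <- function(X, seed = 1L) {
  n <- nrow(X)
  idx <- if (n > 500L) with_seed(seed, sample(n, 500L)) else seq_len(n)
  D2 <- cross_dist2(X[idx, , drop = FALSE], X[idx, , drop = FALSE])
  m <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' @export
predict.dscml_ridge <- function(object, newdata, ...) {
  X <- apply_scaler(object$scaler, as.matrix(newdata))
  f <- object$fit
  if (nrow(X) == 0L) return(numeric(0))
  if (f$mode == "primal") {
    as.numeric(X %*% f$beta) + f$y_mean
  } else {
    as.numeric(tcrossprod(X, f$Xtrain) %*% f$a) + f$y_mean
  }
}

#' @export
predict.dscml_kernel_ridge <- function(object, newdata, ...) {
  X <- apply_scaler(object$scaler, as.matrix(newdata))
  f <- object$fit
  if (nrow(X) == 0L) return(numeric(0))
  K <- rbf_kernel(X, f$Xtrain, f$sigma)
  out <- as.numeric(K %*% f$a) + f$y_mean
  rm(K); gc(FALSE)   # the cross-kernel and its block temporaries are large
  out
}

#' Fit epsilon support-vector regression with a Gaussian kernel
#'
#' Wraps libsvm's epsilon-SVR (through e1071) with the package's common
#' standardisation and seeding conventions. Targets are centred and scaled
#' internally so `epsilon` is expressed in standard deviations of `y`.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric targets.
#' @param C Error-penalty constant (> 0), default 10.
#' @param epsilon Width of the insensitive tube on the standardised target
#'   scale, default 0.1 (libsvm's default; tighter tubes multiply the
#'   support-vector count with little accuracy gain on curve features).
#' @param sigma Gaussian kernel width; `NULL` uses the median heuristic.
#' @param seed Seed for the sigma-heuristic subsample.
#' @param cachesize Kernel cache in MB passed to libsvm.
#' @param tolerance SMO termination tolerance.
#' @param ... Further arguments passed to [e1071::svm()].
#' @return A `dscml_model` of family `"svr"`.
#' @export
fit_svr <- function(X, y, C = 10, epsilon = 0.1, sigma = NULL, seed = 1L,
                    cachesize = 512, tolerance = 0.01, ...) {
  if (C <= 0 || epsilon < 0) stop("need C > 0 and epsilon >= 0")
  d <- check_xy(X, y)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(scaler, d$X)
  y_mean <- mean(d$y)
  y_sd <- stats::sd(d$y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (d$y - y_mean) / y_sd
  if (is.null(sigma)) sigma <- median_sigma(Xs, seed)
  gc(FALSE)
  m <- if (stats::sd(d$y) == 0) NULL else
    e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
               gamma = 1 / (2 * sigma^2), cost = C, epsilon = epsilon,
               cachesize = cachesize, tolerance = tolerance,
               scale = FALSE, fitted = FALSE, ...)
  # all targets inside one epsilon tube leaves no support vectors; the
  # fitted function is then the constant offset
  if (!is.null(m) && m$tot.nSV == 0L) m <- NULL
  new_model("svr", list(svm = m, y_mean = y_mean, y_sd = y_sd),
            spec = list(C = C, epsilon = epsilon, sigma = sigma),
            scaler = scaler, provenance = list(n = nrow(Xs), p = ncol(Xs)))
}

#' @export
predict.dscml_svr <- function(object, newdata, ...) {
  X <- apply_scaler(object$scaler, as.matrix(newdata))
  if (nrow(X) == 0L) return(numeric(0))
  if (is.null(object$fit$svm)) return(rep(object$fit$y_mean, nrow(X)))
  p <- as.numeric(stats::predict(object$fit$svm, X))
  p * object$fit$y_sd + object$fit$y_mean
}

#' Fit a bagged random-forest regressor
#'
#' CART-style regression trees (variance-reduction splitting) aggregated by
#' bootstrap averaging, via the ranger implementation. Defaults follow
#' common perfusion-regression practice: 100 trees, minimum leaf size 5.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric targets.
#' @param n_trees Number of trees (default 100).
#' @param min_leaf Minimum samples per leaf (default 5).
#' @param seed Integer seed (forests are deterministic given it).
#' @param num_threads Threads used by ranger (default 1 for reproducible
#'   single-core behaviour).
#' @return A `dscml_model` of family `"random_forest"`.
#' @export
fit_random_forest <- function(X, y, n_trees = 100L, min_leaf = 5L,
                              seed = 1L, num_threads = 1L) {
  if (n_trees < 1L || min_leaf < 1L) stop("need n_trees >= 1 and min_leaf >= 1")
  d <- check_xy(X, y)
  if (nrow(d$X) < min_leaf) stop("fewer rows than `min_leaf`")
  colnames(d$X) <- paste0("f", seq_len(ncol(d$X)))
  gc(FALSE)
  m <- ranger::ranger(x = d$X, y = d$y, num.trees = n_trees,
                      min.node.size = min_leaf, seed = seed,
                      num.threads = num_threads, oob.error = FALSE)
  new_model("random_forest", list(rf = m, p = ncol(d$X)),
            spec = list(n_trees = n_trees, min_leaf = min_leaf, seed = seed),
            provenance = list(n = nrow(d$X), p = ncol(d$X)))
}

#' @export
predict.dscml_random_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  check_width(object, ncol(X), object$fit$p)
  if (nrow(X) == 0L) return(numeric(0))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  as.numeric(stats::predict(object$fit$rf, data = X,
                            num.threads = 1L)$predictions)
}

check_width <- function(object, got, expected) {
  if (got != expected)
    stop(sprintf("feature width mismatch for %s model: expected %d, got %d",
                 object$family, expected, got))
}

#' Predict from any fitted dscml model
#'
#' All families share this contract: one finite prediction per row of
#' `newdata`, a pure function of the fitted object and the features. A
#' mismatched feature width is an error naming both widths.
#'
#' @param object A `dscml_model`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions, `nrow(newdata)` long.
#' @export
predict.dscml_model <- function(object, newdata, ...) {
  stop(sprintf("no predict method for family '%s'", object$family))
}

#' Fit any regression family by name
#'
#' Dispatcher used by the experiment drivers: `"linear"`, `"ridge"`,
#' `"kernel_ridge"`, `"svr"`, `"mlp"`, `"random_forest"`.
#'
#' @param family Family name.
#' @param X,y Training data.
#' @param seed Integer seed forwarded to stochastic fitters.
#' @param ... Family-specific hyperparameters.
#' @return A `dscml_model`.
#' @export
fit_regressor <- function(family, X, y, seed = 1L, ...) {
  switch(family,
    linear = fit_linear(X, y),
    ridge = fit_ridge(X, y, kernel = "linear", seed = seed, ...),
    kernel_ridge = fit_ridge(X, y, kernel = "gaussian", seed = seed, ...),
    svr = fit_svr(X, y, seed = seed, ...),
    mlp = fit_mlp(X, y, seed = seed, ...),
    random_forest = fit_random_forest(X, y, seed = seed, ...),
    stop(sprintf("unknown regression family '%s'", family))
  )
}

#' @export
print.dscml_model <- function(x, ...) {
  cat(sprintf("<dscml_model: %s> trained on n=%s, p=%s\n", x$family,
              x$provenance$n %||% "?", x$provenance$p %||% "?"))
  invisible(x)
}

#' All regression family names
#' @return Character vector of the six family identifiers.
#' @export
regressor_families <- function() {
  c("linear", "ridge", "kernel_ridge", "svr", "mlp", "random_forest")
}
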