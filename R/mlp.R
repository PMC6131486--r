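#' Fit a feedforward multilayer perceptron regressor
#'
#' A fully connected network with tanh hidden units and a single linear
#' output, trained full-batch by the scaled conjugate gradient (SCG)
#' algorithm on the mean-squared error. The default of five hidden layers
#' gives seven layers in total including the input and output layers.
#' Features are standardised and targets centred/scaled internally; training
#' is deterministic given the seed.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric targets.
#' @param layers Integer vector of hidden-layer widths
#'   (default `c(64, 32, 16, 8, 4)`).
#' @param seed Integer seed for the weight initialisation.
#' @param maxit Maximum SCG iterations (default 300).
#' @param tol Relative improvement tolerance for early stopping.
#' @param lambda_wd L2 weight-decay coefficient (default 1e-4).
#' @return A `dscml_model` of family `"mlp"`.
#' @export
fit_mlp <- function(X, y, layers = c(64L, 32L, 16L, 8L, 4L), seed = 1L,
                    maxit = 200L, tol = 1e-8, lambda_wd = 1e-4) {
  d <- check_xy(X, y)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(scaler, d$X)
  y_mean <- mean(d$y)
  y_sd <- stats::sd(d$y)
  if (!is.finite(y_sd) || y_sd == 0) {
    # degenerate constant target: the fitted function is the constant
    return(new_model("mlp", list(constant = TRUE, y_mean = y_mean),
                     spec = list(layers = layers, seed = seed),
                     scaler = scaler,
                     provenance = list(n = nrow(Xs), p = ncol(Xs))))
  }
  ys <- (d$y - y_mean) / y_sd

  sizes <- c(ncol(Xs), as.integer(layers), 1L)
  w0 <- mlp_init(sizes, seed)
  n <- nrow(Xs)
  gc(FALSE)
  # objective and gradient share one cached forward pass per weight vector
  last_w <- NULL
  last_fw <- NULL
  fwd <- function(w) {
    if (!identical(w, last_w)) {
      last_fw <<- mlp_forward(w, sizes, Xs)
      last_w <<- w
    }
    last_fw
  }
  obj <- function(w) {
    r <- fwd(w)$out - ys
    mean(r^2) + lambda_wd * sum(w^2)
  }
  grd <- function(w) {
    mlp_grad(w, sizes, Xs, ys, fw = fwd(w)) + 2 * lambda_wd * w
  }
  w <- scg_minimize(w0, obj, grd, maxit = maxit, tol = tol)
  if (!is.finite(obj(w)))
    stop("MLP training diverged to a non-finite loss")
  new_model("mlp", list(w = w, sizes = sizes, y_mean = y_mean, y_sd = y_sd),
            spec = list(layers = layers, seed = seed, maxit = maxit,
                        lambda_wd = lambda_wd),
            scaler = scaler, provenance = list(n = n, p = ncol(Xs)))
}

#' @export
predict.dscml_mlp <- function(object, newdata, ...) {
  X <- apply_scaler(object$scaler, as.matrix(newdata))
  f <- object$fit
  if (nrow(X) == 0L) return(numeric(0))
  if (isTRUE(f$constant)) return(rep(f$y_mean, nrow(X)))
  mlp_forward(f$w, f$sizes, X)$out * f$y_sd + f$y_mean
}

# --- network internals -----------------------------------------------------

# Weights are stored flat; per layer l: a (sizes[l] x sizes[l+1]) weight
# matrix followed by sizes[l+1] biases. Glorot-uniform initialisation.
mlp_init <- function(sizes, seed) {
  L <- length(sizes) - 1L
  with_seed(seed, {
    unlist(lapply(seq_len(L), function(l) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      c(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
        rep(0, sizes[l + 1]))
    }))
  })
}

mlp_unpack <- function(w, sizes) {
  L <- length(sizes) - 1L
  Ws <- vector("list", L); bs <- vector("list", L)
  off <- 0L
  for (l in seq_len(L)) {
    nw <- sizes[l] * sizes[l + 1]
    Ws[[l]] <- matrix(w[off + seq_len(nw)], sizes[l], sizes[l + 1])
    off <- off + nw
    bs[[l]] <- w[off + seq_len(sizes[l + 1])]
    off <- off + sizes[l + 1]
  }
  list(W = Ws, b = bs)
}

mlp_forward <- function(w, sizes, X) {
  p <- mlp_unpack(w, sizes)
  L <- length(p$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% p$W[[l]], 2, p$b[[l]], "+")
    A <- if (l < L) tanh(Z) else Z
    acts[[l + 1L]] <- A
  }
  list(out = as.numeric(A), acts = acts)
}

# Gradient of mean((out - y)^2) by backpropagation, same flat layout; a
# precomputed forward pass can be supplied to avoid recomputation.
mlp_grad <- function(w, sizes, X, y, fw = NULL) {
  p <- mlp_unpack(w, sizes)
  L <- length(p$W)
  if (is.null(fw)) fw <- mlp_forward(w, sizes, X)
  n <- nrow(X)
  delta <- matrix(2 * (fw$out - y) / n, ncol = 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A_prev <- fw$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(p$W[[l]])) * (1 - fw$acts[[l]]^2)
    }
  }
  unlist(lapply(seq_len(L), function(l) c(as.numeric(gW[[l]]), gb[[l]])))
}

# --- scaled conjugate gradient (Moller 1993) -------------------------------

# Deterministic batch minimiser; second-order information is approximated by
# a finite difference of gradients along the search direction, with
# Levenberg-Marquardt style scaling to keep the curvature estimate positive.
scg_minimize <- function(w, fn, gr, maxit = 300L, tol = 1e-8,
                         sigma0 = 5e-5, lambda0 = 5e-7) {
  k <- 1L
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  f_w <- fn(w)
  r <- -gr(w)
  p <- r
  n_par <- length(w)
  delta <- 0; mu <- 0
  for (k in seq_len(maxit)) {
    if (success) {
      mu <- sum(p * r)
      if (mu == 0) break
      p2 <- sum(p * p)
      sigma <- sigma0 / sqrt(p2)
      # one-sided secant curvature estimate, reusing the current gradient -r
      s <- (gr(w + sigma * p) + r) / sigma
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * sum(p * p)
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / sum(p * p))
      delta_k <- -delta_k + lambda * sum(p * p)
      lambda <- lambda_bar
    }
    alpha <- mu / delta_k
    w_new <- w + alpha * p
    f_new <- fn(w_new)
    Delta <- 2 * delta_k * (f_w - f_new) / (mu^2)
    if (is.finite(Delta) && Delta >= 0) {
      improve <- f_w - f_new
      w <- w_new
      f_w <- f_new
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      if (Delta >= 0.75) lambda <- lambda / 4
      beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
      r <- r_new
      p <- r + beta * p
      if (improve >= 0 && improve < tol * max(1, abs(f_w))) break
      if (sqrt(sum(r * r)) < 1e-10) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + (delta_k * (1 - Delta) / sum(p * p))
    if (!is.finite(lambda) || lambda > 1e20) break
  }
  w
}
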