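## Gaussian process emulators: one univariate GP per biomarker, with
##   f(x) = beta0 + sum_i beta_i x_i + G(x) + eps,
## G a zero-mean GP with ARD squared-exponential kernel
##   k(x, x') = sigma_f^2 exp(-1/2 sum_i (x_i - x_i')^2 / delta_i^2)
## and eps ~ N(0, sigma_n). Inputs are expected in the unit hypercube.

## squared-distance matrices per input dimension (cached across likelihood
## evaluations; they depend on X only)
sq_dist_list <- function(X1, X2 = X1) {
  lapply(seq_len(ncol(X1)), function(j) outer(X1[, j], X2[, j], "-")^2)
}

ard_kernel <- function(D, lengthscales, outputscale) {
  Q <- 0
  for (j in seq_along(D)) Q <- Q + D[[j]] / lengthscales[j]^2
  outputscale^2 * exp(-0.5 * Q)
}

## Cholesky with escalating jitter (relative to mean diagonal)
chol_jitter <- function(K, jitters = c(0, 1e-10, 1e-8, 1e-6)) {
  dmean <- mean(diag(K))
  for (j in jitters) {
    U <- tryCatch(chol(K + diag(j * dmean, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop("training covariance is not positive definite after jitter escalation",
       call. = FALSE)
}

chol_solve <- function(U, b) backsolve(U, forwardsolve(t(U), b))

#' Construct a Gaussian process emulator with fixed hyperparameters
#'
#' Builds the cached factorization for an exact GP with linear mean
#' `beta0 + X beta`, ARD squared-exponential kernel and Gaussian noise,
#' without any hyperparameter optimization. Used directly when the
#' hyperparameters are known (e.g. calibration studies of the emulator
#' itself) and internally by [fit_gpe()].
#'
#' @param X Unit-frame training design (`n x d` matrix).
#' @param y Numeric response vector of length `n`.
#' @param beta0 Mean intercept.
#' @param beta Mean slope vector (length `d`).
#' @param lengthscales Positive length-scale vector `delta` (length `d`).
#' @param outputscale Positive kernel output scale `sigma_f` (standard
#'   deviation; the kernel variance is `outputscale^2`).
#' @param noise_var Non-negative noise variance `sigma_n`.
#' @return An object of class `gpe`.
#' @export
gpe <- function(X, y, beta0, beta, lengthscales, outputscale, noise_var) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n, length(beta) == d, length(lengthscales) == d)
  if (any(!is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (any(lengthscales <= 0) || outputscale <= 0 || noise_var < 0)
    stop("lengthscales and outputscale must be positive, noise_var >= 0",
         call. = FALSE)
  D <- sq_dist_list(X)
  K <- ard_kernel(D, lengthscales, outputscale) + diag(noise_var, n)
  U <- chol_jitter(K)
  r <- y - beta0 - drop(X %*% beta)
  alpha <- chol_solve(U, r)
  lml <- -0.5 * sum(r * alpha) - sum(log(diag(U))) - n / 2 * log(2 * pi)
  structure(list(
    beta0 = beta0, beta = beta, lengthscales = lengthscales,
    outputscale = outputscale, noise_var = noise_var,
    X_train = X, y_train = y, U = U, alpha = alpha, lml = lml
  ), class = "gpe")
}

#' @export
print.gpe <- function(x, ...) {
  cat(sprintf("<gpe: n = %d, d = %d>\n", nrow(x$X_train), ncol(x$X_train)))
  cat(sprintf("  outputscale %.4g, noise_var %.4g, log-marginal lik %.4g\n",
              x$outputscale, x$noise_var, x$lml))
  cat("  lengthscales:", format(x$lengthscales, digits = 3), "\n")
  invisible(x)
}

## negative profiled log-marginal likelihood and gradient.
## theta = c(log delta (d), log sigma_f, [log sigma_n unless noise_free]).
## The mean coefficients are profiled out by generalized least squares; by
## the envelope theorem the gradient of the profiled likelihood equals the
## partial gradient at the GLS optimum.
gp_nll_make <- function(X, y, noise_free, jitter_floor = 1e-10) {
  n <- nrow(X); d <- ncol(X)
  D <- sq_dist_list(X)
  H <- cbind(1, X)
  p <- ncol(H)
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evaluate <- function(theta) {
    delta <- exp(theta[1:d])
    sigma_f <- exp(theta[d + 1])
    sigma_n <- if (noise_free) jitter_floor else exp(theta[d + 2])
    Kf <- ard_kernel(D, delta, sigma_f)
    K <- Kf + diag(sigma_n, n)
    U <- tryCatch(chol_jitter(K), error = function(e) NULL)
    if (is.null(U)) return(list(nll = 1e10, grad = rep(0, length(theta))))
    Ki_H <- chol_solve(U, H)
    Ki_y <- chol_solve(U, y)
    A <- crossprod(H, Ki_H)
    beta <- tryCatch(solve(A, crossprod(H, Ki_y)),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(nll = 1e10, grad = rep(0, length(theta))))
    r <- y - drop(H %*% beta)
    alpha <- chol_solve(U, r)
    lml <- -0.5 * sum(r * alpha) - sum(log(diag(U))) - n / 2 * log(2 * pi)
    Kinv <- chol2inv(U)
    W <- tcrossprod(alpha) - Kinv
    M <- W * Kf
    grad <- numeric(length(theta))
    for (j in seq_len(d)) grad[j] <- 0.5 * sum(M * D[[j]]) / delta[j]^2
    grad[d + 1] <- sum(M)
    if (!noise_free) grad[d + 2] <- 0.5 * sigma_n * sum(diag(W))
    list(nll = -lml, grad = -grad, beta = beta, lml = lml)
  }
  get <- function(theta) {
    if (!identical(theta, cache$theta)) {
      cache$theta <- theta
      cache$res <- evaluate(theta)
    }
    cache$res
  }
  list(fn = function(theta) get(theta)$nll,
       gr = function(theta) get(theta)$grad,
       full = function(theta) get(theta))
}

#' Fit a Gaussian process emulator by maximum marginal likelihood
#'
#' Hyperparameters (length-scales `delta`, output scale `sigma_f`, noise
#' variance `sigma_n`) are optimized by multi-restart L-BFGS in
#' log-hyperparameter space; the linear-mean coefficients `beta0`, `beta`
#' are profiled out analytically by generalized least squares at every
#' step. The response is standardized internally (zero mean, unit variance
#' over the training set) for optimizer conditioning, and all returned
#' hyperparameters are transformed back to the natural response scale.
#'
#' @param X Unit-frame training design (`n x d` matrix).
#' @param y Numeric response vector.
#' @param noise_free If `TRUE`, pin the noise variance to a jitter floor
#'   (1e-10 on the standardized scale, escalated only if the covariance
#'   factorization demands it); the emulator then interpolates the
#'   training data with near-zero variance at training points.
#' @param restarts Number of optimizer restarts (Latin-hypercube-seeded
#'   initial log-hyperparameters).
#' @param seed Integer seed for the restart initializations.
#' @param maxit Maximum L-BFGS iterations per restart.
#' @return A [gpe()] object; component `fit` records per-restart initial
#'   and achieved log-marginal likelihoods (standardized scale).
#' @export
fit_gpe <- function(X, y, noise_free = FALSE, restarts = 10L, seed = 1L,
                    maxit = 100L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (any(!is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < d + 2)
    warning(sprintf("only %d training points for %d dimensions; the fit may be poor",
                    n, d), call. = FALSE)
  if (noise_free && anyDuplicated(X))
    stop("duplicate training inputs are not allowed for a noise-free GP",
         call. = FALSE)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  obj <- gp_nll_make(X, ys, noise_free)
  n_par <- d + 1L + if (noise_free) 0L else 1L
  lower <- c(rep(log(1e-2), d), log(1e-4), if (!noise_free) log(1e-10))
  upper <- c(rep(log(1e3), d), log(1e3), if (!noise_free) log(1))

  set.seed(seed)
  inits <- matrix(0, restarts, n_par)
  ## first restart at a conventional starting point, rest space-filling
  inits[1, ] <- c(rep(log(0.5), d), log(1), if (!noise_free) log(1e-3))
  if (restarts > 1) {
    L <- lhs::randomLHS(restarts - 1L, n_par)
    lo <- c(rep(log(0.1), d), log(0.3), if (!noise_free) log(1e-6))
    hi <- c(rep(log(3), d), log(2), if (!noise_free) log(0.1))
    inits[-1, ] <- sweep(sweep(L, 2, hi - lo, "*"), 2, lo, "+")
  }

  best <- NULL
  trace <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    init_val <- -obj$fn(inits[r, ])
    opt <- tryCatch(
      stats::optim(inits[r, ], fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(opt)) {
      trace[[r]] <- list(init_lml = init_val, final_lml = init_val,
                         theta = inits[r, ])
      next
    }
    trace[[r]] <- list(init_lml = init_val, final_lml = -opt$value,
                       theta = opt$par)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)
  res <- obj$full(best$par)
  delta <- exp(best$par[1:d])
  sigma_f_s <- exp(best$par[d + 1])
  sigma_n_s <- if (noise_free) 1e-10 else exp(best$par[d + 2])
  beta_s <- res$beta

  out <- gpe(X, y,
             beta0 = y_center + y_scale * beta_s[1],
             beta = y_scale * beta_s[-1],
             lengthscales = delta,
             outputscale = y_scale * sigma_f_s,
             noise_var = y_scale^2 * sigma_n_s)
  out$fit <- list(restarts = trace, y_center = y_center, y_scale = y_scale,
                  lml_standardized = res$lml, noise_free = noise_free)
  out
}

#' Posterior prediction from a GP emulator
#'
#' Returns the exact-GP posterior mean (including the linear mean function)
#' and the latent-plus-noise predictive variance
#' `Var[f(x)] = sigma_f^2 + sigma_n - k*' (K + sigma_n I)^{-1} k*`
#' at each row of `X`. The fitted noise variance is included because the
#' noise term is part of the emulator's predictive uncertainty as used by
#' the implausibility measure.
#'
#' @param object A [gpe()].
#' @param X Unit-frame matrix of prediction points.
#' @param ... Unused.
#' @return A list with numeric vectors `mean` and `var`.
#' @export
predict.gpe <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  if (ncol(X) != ncol(object$X_train))
    stop(sprintf("prediction points have %d columns; emulator expects %d",
                 ncol(X), ncol(object$X_train)), call. = FALSE)
  Dx <- sq_dist_list(X, object$X_train)
  Ks <- ard_kernel(Dx, object$lengthscales, object$outputscale)  # n* x n
  mu <- object$beta0 + drop(X %*% object$beta) + drop(Ks %*% object$alpha)
  V <- forwardsolve(t(object$U), t(Ks))                          # n x n*
  var <- object$outputscale^2 + object$noise_var - colSums(V^2)
  var <- pmax(var, 0)
  list(mean = mu, var = var)
}

#' Emulator validation metrics
#'
#' `r2_score()` is the coefficient of determination `1 - SS_res / SS_tot`.
#' `ise_score()` is the independent standard error: the percentage of
#' points whose true value lies strictly within 2 predictive standard
#' deviations of the predicted mean. The inequality is strict, so a
#' degenerate zero-SD prediction counts as a failure even when the mean is
#' exact.
#'
#' @param y_pred_mean Predicted means.
#' @param y_pred_sd Predictive standard deviations (>= 0).
#' @param y_true Observed values.
#' @return `r2_score()`: a scalar (1 = perfect); `ise_score()`: a
#'   percentage in \[0, 100\].
#' @export
r2_score <- function(y_pred_mean, y_true) {
  stopifnot(length(y_pred_mean) == length(y_true), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0)
    stop("R^2 is undefined for a constant y_true", call. = FALSE)
  1 - sum((y_true - y_pred_mean)^2) / ss_tot
}

#' @rdname r2_score
#' @export
ise_score <- function(y_pred_mean, y_pred_sd, y_true) {
  stopifnot(length(y_pred_mean) == length(y_true),
            length(y_pred_sd) == length(y_true), all(y_pred_sd >= 0))
  100 * mean(abs(y_pred_mean - y_true) < 2 * y_pred_sd)
}
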