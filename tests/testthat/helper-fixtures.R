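# Shared fixtures, built in code at test time.

# a 1-D unit space with an identity simulator (biomarker y = x)
space_1d <- function() parameter_space("x", 0, 1)

identity_simulator <- function() function(X_nat) data.frame(y = X_nat[, 1])

# small smooth test function on the unit cube, low effective dimension
smooth_fn <- function(U) {
  3 * U[, 1] - 2 * U[, ncol(U)] + 0.5 * sin(2 * pi * U[, 1]) +
    0.3 * U[, 1] * U[, 2]
}

# a scaled-down wave configuration for pipeline tests
small_wave_config <- function(seed = 5L, thresholds = c(3.2, 3.2, 3.0),
                              n_candidates = 1500L, n_reference = 1500L) {
  wave_config(n_initial_train = 80L, n_initial_val = 15L,
              n_initial_test = 15L, n_per_wave = 40L,
              n_candidates = n_candidates, n_reference = n_reference,
              thresholds = thresholds, seed = seed, restarts = 2L,
              maxit = 60L)
}

# dense-linear-algebra GP oracle: explicit inverse of (K + noise I),
# independent of the package's Cholesky implementation
gp_oracle <- function(X, y, Xs, beta0, beta, ls, sf, sn) {
  n <- nrow(X)
  kfun <- function(A, B)
    sf^2 * exp(-0.5 * outer(seq_len(nrow(A)), seq_len(nrow(B)),
                            Vectorize(function(i, j)
                              sum((A[i, ] - B[j, ])^2 / ls^2))))
  K <- kfun(X, X) + diag(sn, n)
  Ks <- kfun(Xs, X)
  Kinv <- solve(K)
  r <- y - beta0 - drop(X %*% beta)
  list(mean = beta0 + drop(Xs %*% beta) + drop(Ks %*% Kinv %*% r),
       var = sf^2 + sn - diag(Ks %*% Kinv %*% t(Ks)))
}

# brute-force star-discrepancy estimate on anchored boxes with corners on a
# grid (lower bound to the true star discrepancy; adequate for comparison)
star_discrepancy_2d <- function(P, grid = 32) {
  g <- seq_len(grid) / grid
  worst <- 0
  for (a in g) for (b in g) {
    frac <- mean(P[, 1] < a & P[, 2] < b)
    worst <- max(worst, abs(frac - a * b))
  }
  worst
}
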