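test_that("log-marginal likelihood matches the 1-point closed form", {
  # single training pair (0, 2), beta = 0, sigma_f^2 = 1, delta = 1,
  # sigma_n = 0: log N(2 | 0, 1) = -1/2 * 4 - 1/2 * log(2*pi)
  g <- gpe(matrix(0, 1, 1), 2, beta0 = 0, beta = 0, lengthscales = 1,
           outputscale = 1, noise_var = 0)
  expect_equal(g$lml, -0.5 * 4 - 0.5 * log(2 * pi), tolerance = 1e-9)
})

test_that("posterior at a new point matches the single-point closed form", {
  # k(0,1) = exp(-0.5): mean(1) = 2 exp(-0.5), var(1) = 1 - exp(-1)
  g <- gpe(matrix(0, 1, 1), 2, beta0 = 0, beta = 0, lengthscales = 1,
           outputscale = 1, noise_var = 0)
  pr <- predict(g, matrix(1, 1, 1))
  expect_equal(pr$mean, 2 * exp(-0.5), tolerance = 1e-9)
  expect_equal(pr$var, 1 - exp(-1), tolerance = 1e-9)
})

test_that("noise-free emulator interpolates and reverts to the mean far away", {
  set.seed(21)
  X <- matrix(runif(30), 15, 2)
  y <- smooth_fn(cbind(X, X[, 2, drop = FALSE]))
  g <- fit_gpe(X, y, noise_free = TRUE, restarts = 3, seed = 2)
  pr <- predict(g, X)
  expect_equal(pr$mean, y, tolerance = 1e-6)
  expect_true(all(pr$var <= 1e-6))
  # far from the data (>> any length-scale) the kernel vanishes:
  # mean -> linear mean, var -> sigma_f^2 + sigma_n
  far <- matrix(50, 1, 2)
  prf <- predict(g, far)
  expect_equal(prf$mean, g$beta0 + sum(g$beta * far), tolerance = 1e-6)
  expect_equal(prf$var, g$outputscale^2 + g$noise_var, tolerance = 1e-6)
})

test_that("an exactly linear response is absorbed by the mean function", {
  set.seed(4)
  X <- matrix(runif(40), 20, 2)
  y <- 2 + 3 * X[, 1] - X[, 2]
  g <- fit_gpe(X, y, noise_free = TRUE, restarts = 2, seed = 1)
  Xt <- matrix(runif(20), 10, 2)
  pr <- predict(g, Xt)
  expect_equal(pr$mean, 2 + 3 * Xt[, 1] - Xt[, 2], tolerance = 1e-6)
  # the residual process carries (almost) nothing
  expect_equal(predict(g, X)$mean, y, tolerance = 1e-6)
})

test_that("fit validates inputs and flags degenerate cases", {
  X <- matrix(runif(10), 5, 2)
  expect_error(fit_gpe(X, c(1, 2, NA, 4, 5)), "non-finite")
  expect_warning(fit_gpe(matrix(runif(6), 3, 2), rnorm(3), restarts = 1,
                         maxit = 5), "training points")
  Xd <- rbind(X, X[1, ])
  expect_error(fit_gpe(Xd, rnorm(6), noise_free = TRUE), "duplicate")
})

test_that("returned hyperparameters never degrade any restart's own start", {
  set.seed(9)
  X <- matrix(runif(24), 12, 2)
  y <- sin(4 * X[, 1]) + 0.5 * X[, 2] + rnorm(12, 0, 0.05)
  g <- fit_gpe(X, y, restarts = 3, seed = 7)
  for (tr in g$fit$restarts)
    expect_gte(tr$final_lml, tr$init_lml - 1e-8)
  # the selected fit is at least as good as every restart
  best <- max(vapply(g$fit$restarts, function(t) t$final_lml, numeric(1)))
  expect_equal(g$fit$lml_standardized, best, tolerance = 1e-9)
})

test_that("adding a training point never increases noise-free posterior variance", {
  set.seed(31)
  X <- matrix(runif(16), 8, 2)
  y <- smooth_fn(cbind(X, X[, 1, drop = FALSE]))
  ls <- c(0.5, 0.8); sf <- 1.2
  g1 <- gpe(X, y, 0, c(0, 0), ls, sf, 1e-10)
  xnew <- matrix(runif(2), 1, 2)
  ynew <- smooth_fn(cbind(xnew, xnew[, 1, drop = FALSE]))
  g2 <- gpe(rbind(X, xnew), c(y, ynew), 0, c(0, 0), ls, sf, 1e-10)
  Xt <- matrix(runif(40), 20, 2)
  expect_true(all(predict(g2, Xt)$var <= predict(g1, Xt)$var + 1e-8))
})

test_that("R-squared and ISE reproduce hand-computed examples", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 9)
  expect_equal(r2_score(rep(mean(y), 3), y), 0)
  expect_equal(r2_score(c(1.1, 1.9, 3.2), c(1, 2, 3)), 1 - 0.06 / 2)
  expect_error(r2_score(c(1, 2), c(5, 5)), "constant")
  expect_equal(ise_score(c(1, 2), c(0.1, 0.2), c(1, 2)), 100)
  # exact mean but zero sd fails the strict inequality
  expect_equal(ise_score(c(1, 2), c(0, 0), c(1, 2)), 0)
  expect_equal(ise_score(c(11, 25, 30.5), c(1, 2, 0.2), c(10, 20, 30)),
               100 / 3, tolerance = 1e-9)
})

test_that("bank fitting is name-keyed and records per-biomarker scores", {
  set.seed(12)
  X <- matrix(runif(60), 30, 2)
  Y <- data.frame(a = 2 * X[, 1] + rnorm(30, 0, 0.01),
                  b = X[, 2]^2 + rnorm(30, 0, 0.01))
  Xv <- matrix(runif(20), 10, 2)
  Yv <- data.frame(a = 2 * Xv[, 1], b = Xv[, 2]^2)
  bank <- fit_bank(X, Y, restarts = 2, seed = 3, X_val = Xv, Y_val = Yv)
  expect_s3_class(bank, "gpe_bank")
  expect_named(bank$emulators, c("a", "b"))
  expect_setequal(bank$scores$biomarker, c("a", "b"))
  expect_true(all(c("r2", "ise") %in% names(bank$scores)))
  # permuting response columns yields the same per-name emulators
  bank2 <- fit_bank(X, Y[, c("b", "a")], restarts = 2, seed = 3)
  expect_equal(bank2$emulators$a$lengthscales, bank$emulators$a$lengthscales)
  expect_equal(bank2$emulators$a$beta0, bank$emulators$a$beta0)
})

test_that("bank serialization round-trips hyperparameters exactly", {
  set.seed(5)
  X <- matrix(runif(40), 20, 2)
  Y <- data.frame(a = X[, 1] + rnorm(20, 0, 0.05), b = cos(3 * X[, 2]))
  bank <- fit_bank(X, Y, restarts = 2, seed = 1, provenance = "wave 1")
  dir <- withr::local_tempdir()
  write_bank(bank, dir)
  bank2 <- read_bank(dir)
  expect_identical(bank2$biomarker_names, bank$biomarker_names)
  expect_identical(bank2$provenance, "wave 1")
  for (nm in names(bank$emulators)) {
    expect_identical(bank2$emulators[[nm]]$lengthscales,
                     bank$emulators[[nm]]$lengthscales)
    expect_identical(bank2$emulators[[nm]]$outputscale,
                     bank$emulators[[nm]]$outputscale)
    expect_identical(bank2$emulators[[nm]]$noise_var,
                     bank$emulators[[nm]]$noise_var)
  }
  # predictions agree to the training-data round-trip precision
  Xt <- matrix(runif(10), 5, 2)
  expect_equal(predict_bank(bank2, Xt)$mean, predict_bank(bank, Xt)$mean,
               tolerance = 1e-9)
})
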