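# a bank whose emulators predict exactly (zero variance) at a given point:
# each is a noise-free GP trained only at that point
exact_bank_at <- function(x0, values) {
  ems <- lapply(values, function(v)
    gpe(matrix(x0, nrow = 1), v, beta0 = 0, beta = rep(0, length(x0)),
        lengthscales = rep(1, length(x0)), outputscale = 1, noise_var = 0))
  structure(list(biomarker_names = names(values), emulators = ems,
                 scores = NULL, provenance = ""), class = "gpe_bank")
}

test_that("target construction follows the sigma = c * |mu| rule", {
  tg <- make_targets_from_values(c(TAT = 76.4, TAT_LV_endo = 31.3), c = 0.1)
  expect_equal(tg$sigma, c(7.64, 3.13))
  tg5 <- make_targets_from_values(c(TAT = 76.4, TAT_LV_endo = 31.3), c = 0.05)
  expect_equal(tg5$sigma, tg$sigma / 2)
  expect_gt(make_targets_from_values(c(a = -4), c = 0.1)$sigma, 0)
  expect_error(make_targets_from_values(c(a = 0), c = 0.1), "degenerate")
  expect_error(make_targets_from_values(c(a = 1), c = -1), "> 0")
})

test_that("implausibility reproduces the hand-worked two-biomarker example", {
  x0 <- c(0.5, 0.5)
  bank <- exact_bank_at(x0, c(TAT = 84.04, TAT_LV_endo = 31.3))
  tg <- target_spec(c("TAT", "TAT_LV_endo"), c(76.4, 31.3), c(7.64, 3.13))
  I <- implausibility(bank, tg, matrix(x0, nrow = 1))
  expect_equal(I, (84.04 - 76.4) / 7.64, tolerance = 1e-6)  # = 1.0
  # exact match on every biomarker gives I = 0 regardless of variances
  bank0 <- exact_bank_at(x0, c(TAT = 76.4, TAT_LV_endo = 31.3))
  expect_equal(implausibility(bank0, tg, matrix(x0, nrow = 1)), 0,
               tolerance = 1e-6)
  # doubling every sigma strictly decreases positive implausibility
  tg2 <- target_spec(tg$biomarker_names, tg$mu, 2 * tg$sigma)
  expect_lt(implausibility(bank, tg2, matrix(x0, nrow = 1)), I)
  expect_error(implausibility(bank, target_spec("other", 1, 1),
                              matrix(x0, nrow = 1)), "no emulator")
})

test_that("vectorized implausibility equals a scalar-loop oracle", {
  set.seed(14)
  X <- matrix(runif(40), 20, 2)
  y1 <- 2 * X[, 1] + 0.2 * rnorm(20)
  y2 <- X[, 2]^2 + 0.1 * rnorm(20)
  bank <- structure(list(
    biomarker_names = c("b1", "b2"),
    emulators = list(b1 = gpe(X, y1, 0.1, c(1, 0), c(0.4, 0.9), 1.1, 0.01),
                     b2 = gpe(X, y2, 0, c(0, 0.5), c(0.7, 0.3), 0.8, 0.02)),
    scores = NULL, provenance = ""), class = "gpe_bank")
  tg <- target_spec(c("b1", "b2"), c(1, 0.4), c(0.2, 0.1))
  Xq <- matrix(runif(30), 15, 2)
  I <- implausibility(bank, tg, Xq)
  I_oracle <- vapply(seq_len(15), function(i) {
    worst <- -Inf
    for (k in 1:2) {
      em <- bank$emulators[[k]]
      pr <- predict(em, Xq[i, , drop = FALSE])
      worst <- max(worst, abs(pr$mean - tg$mu[k]) / sqrt(pr$var + tg$sigma[k]^2))
    }
    worst
  }, numeric(1))
  expect_equal(I, I_oracle, tolerance = 1e-10)
})

test_that("variance quotient matches hand values and scales with sigma", {
  x0 <- c(0.3, 0.7)
  bank <- exact_bank_at(x0, c(b1 = 1, b2 = 2))
  tg <- target_spec(c("b1", "b2"), c(1, 2), c(1, 1))
  # far from the training point the posterior variance is sigma_f^2 = 1
  far <- matrix(c(30, 30), nrow = 1)
  expect_equal(variance_quotient(bank, tg, far), 1, tolerance = 1e-6)
  tg_half <- target_spec(tg$biomarker_names, tg$mu, tg$sigma / 2)
  expect_equal(variance_quotient(bank, tg_half, far), 4, tolerance = 1e-5)
  # max over biomarkers: Var = (4, 1), sigma^2 = (1, 1) -> VQ = 4
  bank2 <- exact_bank_at(x0, c(b1 = 1, b2 = 2))
  bank2$emulators$b1$outputscale <- 2  # Var far away = 4
  bank2$emulators$b1$noise_var <- 0
  vq <- variance_quotient(structure(bank2, class = "gpe_bank"), tg, far)
  expect_equal(vq, 4, tolerance = 1e-4)
  st <- vq_stats(bank, tg, rbind(far, far))
  expect_equal(st$max, 1, tolerance = 1e-6)
  expect_equal(st$median, 1, tolerance = 1e-6)
  expect_true(is.na(vq_stats(bank, tg, far, mask = FALSE)$max))
})

test_that("NROY agreement handles equality, the worked example, and empty A", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(nroy_agreement(a, a), list(whole_space_pct = 100, nroy_pct = 100))
  b <- c(TRUE, FALSE, TRUE, FALSE)
  ag <- nroy_agreement(a, b)
  expect_equal(ag$whole_space_pct, 50)
  expect_equal(ag$nroy_pct, 50)
  expect_true(is.na(nroy_agreement(c(FALSE, FALSE), c(TRUE, FALSE))$nroy_pct))
  expect_error(nroy_agreement(a, b[1:3]), "equal length")
})

test_that("frequency maps are normalized histograms over natural units", {
  sp <- make_default_space()
  set.seed(3)
  U <- matrix(runif(14 * 4000), ncol = 14)
  fm <- frequency_map(U, sp, n_bins = 10)
  sums <- tapply(fm$proportion, fm$parameter, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(abs(fm$proportion - 0.1) < 0.05))  # uniform input
  alpha_rows <- fm[fm$parameter == "alpha", ]
  expect_equal(alpha_rows$lower[1], 40)
  expect_equal(alpha_rows$upper[10], 90)
  # all mass in one bin
  fm1 <- frequency_map(matrix(0.999, 5, 14), sp, n_bins = 10)
  expect_true(all(fm1$proportion[fm1$bin == 10] == 1))
  expect_warning(fm0 <- frequency_map(matrix(numeric(0), 0, 14), sp, 10),
                 "empty")
  expect_equal(nrow(fm0), 0)
  expect_error(frequency_map(U, sp, n_bins = 1), ">= 2")
})

test_that("wave config validates thresholds and counts", {
  expect_error(wave_config(thresholds = c(3.0, 3.2)), "non-increasing")
  expect_error(wave_config(n_per_wave = 0), "n_per_wave")
  cfg <- wave_config()
  expect_equal(cfg$n_initial_train, 280L)
  expect_equal(cfg$n_per_wave, 140L)
  expect_equal(cfg$n_candidates, 10000L)
  expect_equal(cfg$thresholds, c(3.2, 3.2, 3.0))
})

test_that("a full scaled-down run shrinks NROY monotonically and keeps the truth", {
  sp <- make_default_space()
  pat <- make_patient(sp, seed = 11, c = 0.10)
  run <- run_history_matching(sp, synthetic_simulator(sp), pat$targets,
                              small_wave_config(seed = 5))
  sizes <- vapply(0:3, function(j) nroy_size(run, j), numeric(1))
  expect_equal(sizes[1], 100)
  expect_true(all(diff(sizes) <= 0))
  # candidate sets honour the configured size
  for (w in run$waves) expect_lte(nrow(w$candidates), 1500)
  # ground truth stays non-implausible at every wave
  for (j in seq_along(run$waves))
    expect_lt(implausibility(run$waves[[j]]$bank, pat$targets,
                             matrix(pat$u_star, nrow = 1)),
              run$waves[[j]]$threshold)
  expect_true(nroy_membership(run, matrix(pat$u_star, nrow = 1)))
  # membership is cumulative: wave k+1 members are a subset of wave k members
  m1 <- nroy_membership(run, run$reference_set, 1)
  m2 <- nroy_membership(run, run$reference_set, 2)
  m3 <- nroy_membership(run, run$reference_set, 3)
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m2))
  expect_true(all(nroy_membership(run, run$reference_set, 0)))
  # the ledger recorded the initial design plus two 40-point batches
  expect_equal(nrow(run$ledger), 110 + 40 + 40)
  # reports carry the Table-2-style fields
  rep <- run_report(run, truth = pat$u_star)
  expect_equal(rep$n_waves, 3)
  w3 <- rep$waves[[3]]
  expect_true(all(c("nroy_size_pct", "vq_max", "vq_median",
                    "truth_implausibility") %in% names(w3)))
})

test_that("reuse scores a reference set with zero simulations and sane stats", {
  sp <- make_default_space()
  donor <- make_patient(sp, seed = 21, c = 0.10)
  recipient <- make_patient(sp, seed = 22, c = 0.10)
  csim <- counting_simulator(synthetic_simulator(sp))
  run <- run_history_matching(sp, csim, donor$targets,
                              small_wave_config(seed = 9,
                                                thresholds = c(3.2, 3.0)))
  calls_after_run <- attr(csim, "count")()
  donor_bank <- run$waves[[length(run$waves)]]$bank
  res <- reuse_calibrate(donor_bank, recipient$targets, run$reference_set,
                         threshold = 3.0, truth = recipient$u_star)
  expect_identical(attr(csim, "count")(), calls_after_run)  # no new sims
  expect_equal(res$stats$nroy_pct, 100 * mean(res$mask))
  expect_true(res$stats$truth_implausibility < 3)
  # donor's own targets reproduce the donor's final single-bank cut
  own <- reuse_calibrate(donor_bank, donor$targets, run$reference_set,
                         threshold = 3.0)
  single_cut <- implausibility(donor_bank, donor$targets,
                               run$reference_set) < 3.0
  expect_identical(own$mask, single_cut)
})

test_that("empty NROY regions are reported as errors that name the remedy", {
  sp <- space_1d()
  impossible <- target_spec("y", mu = 50, sigma = 1e-4)
  cfg <- wave_config(n_initial_train = 12, n_initial_val = 4,
                     n_initial_test = 4, n_per_wave = 5, n_candidates = 200,
                     n_reference = 200, thresholds = c(3.2, 3.0), seed = 2,
                     restarts = 1, maxit = 30)
  expect_error(
    suppressWarnings(run_history_matching(sp, identity_simulator(),
                                          impossible, cfg)),
    "empty NROY")
})

test_that("uncertainty sensitivity tabulates per-c stats and pairwise overlaps", {
  sp <- space_1d()
  factory <- function(cv) {
    tg <- make_targets_from_values(c(y = 0.5), c = cv)
    cfg <- wave_config(n_initial_train = 20, n_initial_val = 5,
                       n_initial_test = 5, n_per_wave = 6, n_candidates = 300,
                       n_reference = 300, thresholds = 3.0, seed = 6,
                       restarts = 1, maxit = 40, noise_free = TRUE)
    run_history_matching(sp, identity_simulator(), tg, cfg)
  }
  sens <- uncertainty_sensitivity(factory, c_values = c(0.10, 0.05))
  expect_equal(sens$per_c$c, c(0.10, 0.05))
  expect_true(all(c("nroy_pct", "vq_max", "vq_median") %in% names(sens$per_c)))
  # the tighter uncertainty keeps less of the space
  expect_lt(sens$per_c$nroy_pct[2], sens$per_c$nroy_pct[1])
  expect_true(all(c("whole_space_pct", "nroy_a_in_b_pct", "nroy_b_in_a_pct")
                  %in% names(sens$pairs)))
  # a duplicated c value overlaps itself perfectly
  same <- uncertainty_sensitivity(factory, c_values = c(0.10, 0.10))
  expect_equal(same$pairs$whole_space_pct, 100)
  expect_equal(same$pairs$nroy_a_in_b_pct, 100)
})
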