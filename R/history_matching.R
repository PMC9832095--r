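#' Calibration targets per biomarker
#'
#' A `target_spec` holds the observed (or desired) value `mu_i` and its
#' uncertainty `sigma_i` for each biomarker, in natural biomarker units.
#'
#' @param names Character vector of unique biomarker names.
#' @param mu Numeric vector of target means.
#' @param sigma Numeric vector of positive target standard deviations.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(names, mu, sigma) {
  names <- as.character(names)
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (anyDuplicated(names)) stop("biomarker names must be unique", call. = FALSE)
  if (length(mu) != length(names) || length(sigma) != length(names))
    stop("names, mu and sigma must have equal length", call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  structure(list(biomarker_names = names, mu = mu, sigma = sigma),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  print(data.frame(biomarker = x$biomarker_names, mu = x$mu, sigma = x$sigma,
                   row.names = NULL))
  invisible(x)
}

#' Build targets with uncertainty proportional to the mean
#'
#' When calibrating to deterministic simulation output there is no
#' measurement variance, but setting `sigma = 0` would discard regions
#' compatible with slightly perturbed simulations. The convention here sets
#' `sigma_i = c * |mu_i|`, with `c = 0.10` as the default ("high
#' uncertainty") and `c = 0.05` as the tighter variant.
#'
#' @param mu Named numeric vector (or plain vector plus `names`) of target
#'   means; all nonzero.
#' @param c Positive proportionality constant.
#' @param names Biomarker names (defaults to `names(mu)`).
#' @return A [target_spec()].
#' @export
make_targets_from_values <- function(mu, c = 0.10, names = NULL) {
  if (is.null(names)) names <- base::names(mu)
  if (is.null(names)) stop("biomarker names are required", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  if (any(mu == 0))
    stop("zero target mean gives a degenerate sigma = 0", call. = FALSE)
  target_spec(names, mu, c * abs(mu))
}

## order a bank's emulators by the targets' biomarker names
bank_match_targets <- function(bank, targets) {
  missing <- setdiff(targets$biomarker_names, bank$biomarker_names)
  if (length(missing))
    stop("bank has no emulator for biomarker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  targets$biomarker_names
}

#' Implausibility of candidate parameter points
#'
#' For each row `x` of `X`, the implausibility is
#' `I(x) = max_i |E[f_i(x)] - mu_i| / sqrt(Var[f_i(x)] + sigma_i^2)`,
#' the worst standardized discrepancy between emulator prediction and
#' target across biomarkers, with both emulator variance and observation
#' variance in the denominator. High `I(x)` means `x` is unlikely to yield
#' a good match and can be ruled out.
#'
#' @param bank A `gpe_bank` covering the targets' biomarkers.
#' @param targets A [target_spec()].
#' @param X Unit-frame matrix of candidate points.
#' @return Numeric vector of implausibilities, one per row of `X`.
#' @export
implausibility <- function(bank, targets, X) {
  nm <- bank_match_targets(bank, targets)
  pr <- predict_bank(bank, X)
  Imat <- vapply(seq_along(nm), function(k) {
    j <- match(nm[k], colnames(pr$mean))
    abs(pr$mean[, j] - targets$mu[k]) / sqrt(pr$var[, j] + targets$sigma[k]^2)
  }, numeric(nrow(pr$mean)))
  if (is.null(dim(Imat))) Imat <- matrix(Imat, nrow = 1)
  apply(Imat, 1, max)
}

#' Point-wise variance quotient of an emulator bank
#'
#' `VQ(x) = max_i Var[f_i(x)] / sigma_i^2` compares the emulator's
#' predictive variance with the target variance, biomarker-wise worst case.
#' Values well above 1 indicate that emulator uncertainty, not observation
#' uncertainty, dominates the implausibility denominator.
#'
#' @inheritParams implausibility
#' @return Numeric vector of variance quotients, one per row of `X`.
#' @export
variance_quotient <- function(bank, targets, X) {
  nm <- bank_match_targets(bank, targets)
  pr <- predict_bank(bank, X)
  Q <- vapply(seq_along(nm), function(k) {
    j <- match(nm[k], colnames(pr$var))
    pr$var[, j] / targets$sigma[k]^2
  }, numeric(nrow(pr$var)))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  apply(Q, 1, max)
}

#' Maximum and median variance quotient over a point set
#'
#' @inheritParams implausibility
#' @param mask Optional logical vector restricting the statistics to a
#'   subset of rows (typically the NROY members).
#' @return Named list `max`, `median` (both `NA` if no points remain).
#' @export
vq_stats <- function(bank, targets, X, mask = NULL) {
  if (!is.null(mask)) X <- X[mask, , drop = FALSE]
  if (nrow(X) == 0) return(list(max = NA_real_, median = NA_real_))
  vq <- variance_quotient(bank, targets, X)
  list(max = max(vq), median = stats::median(vq))
}

#' Wave configuration for a history-matching run
#'
#' Defaults follow the reference protocol: a 280/70/88 train/validation/test
#' initial Latin hypercube design, 140 new simulations per subsequent wave,
#' 10,000 emulated candidate points per wave, and implausibility thresholds
#' 3.2, 3.2, 3.0 — the final cutoff of 3 motivated by Pukelsheim's
#' three-sigma rule.
#'
#' @param n_initial_train,n_initial_val,n_initial_test Initial design split.
#' @param n_per_wave Simulations added per wave after the first.
#' @param n_candidates Emulated candidate points per wave.
#' @param n_reference Size of the fixed Sobol' reference set used for all
#'   NROY-size and overlap estimates.
#' @param thresholds Non-increasing implausibility thresholds, one per wave.
#' @param seed Integer seed governing all randomness in the run.
#' @param restarts,maxit Emulator optimizer settings (see [fit_gpe()]).
#' @param noise_free Fit noise-free (interpolating) emulators.
#' @param cloud_scale,cloud_offspring,cloud_max_rounds Cloud resampler
#'   settings (see [cloud_sample()]).
#' @return A list of class `wave_config`.
#' @export
wave_config <- function(n_initial_train = 280L, n_initial_val = 70L,
                        n_initial_test = 88L, n_per_wave = 140L,
                        n_candidates = 10000L, n_reference = 10000L,
                        thresholds = c(3.2, 3.2, 3.0), seed = 1L,
                        restarts = 5L, maxit = 100L, noise_free = FALSE,
                        cloud_scale = 0.05, cloud_offspring = 5L,
                        cloud_max_rounds = 50L) {
  stopifnot(n_initial_train >= 1, n_per_wave >= 1, n_candidates >= 1,
            n_reference >= 1, length(thresholds) >= 1)
  if (is.unsorted(rev(thresholds)))
    stop("thresholds must be non-increasing", call. = FALSE)
  structure(list(
    n_initial_train = as.integer(n_initial_train),
    n_initial_val = as.integer(n_initial_val),
    n_initial_test = as.integer(n_initial_test),
    n_per_wave = as.integer(n_per_wave),
    n_candidates = as.integer(n_candidates),
    n_reference = as.integer(n_reference),
    thresholds = as.numeric(thresholds), seed = as.integer(seed),
    restarts = as.integer(restarts), maxit = as.integer(maxit),
    noise_free = isTRUE(noise_free),
    cloud_scale = cloud_scale, cloud_offspring = as.integer(cloud_offspring),
    cloud_max_rounds = as.integer(cloud_max_rounds)
  ), class = "wave_config")
}

## evaluate the simulator on a unit-frame design, returning a data frame of
## biomarkers; non-finite rows are dropped (with a warning) and the ledger
## records every successful evaluation.
run_simulator <- function(run, U) {
  X_nat <- from_unit(run$space, U)
  Y <- as.data.frame(run$simulator(X_nat))
  ok <- stats::complete.cases(Y) & apply(as.matrix(Y), 1, function(r) all(is.finite(r)))
  if (!all(ok))
    warning(sprintf("simulator failed on %d point(s); dropped", sum(!ok)),
            call. = FALSE)
  list(U = U[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE])
}

## cumulative NROY membership of unit-frame points through waves 1..upto
nroy_eval <- function(waves, targets, X, upto = length(waves)) {
  keep <- rep(TRUE, nrow(X))
  if (upto == 0) return(keep)
  for (j in seq_len(upto)) {
    if (!any(keep)) break
    I <- implausibility(waves[[j]]$bank, targets, X[keep, , drop = FALSE])
    keep[keep] <- I < waves[[j]]$threshold
  }
  keep
}

#' Run a full Bayesian history-matching calibration
#'
#' Orchestrates the whole pipeline: (1) an initial Latin hypercube design
#' is simulated and split into train/validation/test sets; (2) a bank of
#' per-biomarker emulators is fitted to the training set ("reference"
#' bank); (3) wave 1 emulates a Sobol' candidate set and cuts it at the
#' first implausibility threshold; (4) each later wave selects a maximin
#' batch from the surviving candidates, simulates it, refits the bank on
#' all accumulated simulations, repopulates the NROY region with the cloud
#' technique and applies its threshold cumulatively (a point must pass
#' every wave's bank/threshold to remain NROY). NROY sizes are Monte-Carlo
#' fractions over a fixed Sobol' reference set created at run start.
#'
#' @param space A [parameter_space()].
#' @param simulator Function mapping a natural-units design matrix to a
#'   data frame of biomarker values (one row per design row).
#' @param targets A [target_spec()].
#' @param config A [wave_config()].
#' @return An object of class `hm_run` with fields `space`, `targets`,
#'   `config`, `waves` (per-wave state), `reference_set`, `ref_impl`
#'   (per-wave implausibility over the reference set), `ledger`
#'   (all simulated points and biomarkers) and `splits`.
#' @export
run_history_matching <- function(space, simulator, targets, config = wave_config()) {
  cfg <- config
  run <- structure(list(space = space, simulator = simulator,
                        targets = targets, config = cfg,
                        waves = list()), class = "hm_run")

  ## fixed reference set for all NROY-size / overlap estimates
  run$reference_set <- sobol_points(space, cfg$n_reference, skip = 0L)

  n_tot <- cfg$n_initial_train + cfg$n_initial_val + cfg$n_initial_test
  U0 <- latin_hypercube(space, n_tot, seed = cfg$seed)
  sim0 <- run_simulator(run, U0)
  idx <- rep(c("train", "val", "test"),
             c(cfg$n_initial_train, cfg$n_initial_val, cfg$n_initial_test))
  idx <- idx[seq_len(nrow(sim0$U))]
  tr <- idx == "train"; va <- idx == "val"; te <- idx == "test"

  run$train_U <- sim0$U[tr, , drop = FALSE]
  run$train_Y <- sim0$Y[tr, , drop = FALSE]
  run$splits <- list(
    val = list(U = sim0$U[va, , drop = FALSE], Y = sim0$Y[va, , drop = FALSE]),
    test = list(U = sim0$U[te, , drop = FALSE], Y = sim0$Y[te, , drop = FALSE]))
  run$ledger <- cbind(as.data.frame(sim0$U), sim0$Y,
                      wave = 0L, row.names = NULL)

  bank0 <- fit_bank(run$train_U, run$train_Y, noise_free = cfg$noise_free,
                    restarts = cfg$restarts, seed = cfg$seed,
                    maxit = cfg$maxit,
                    X_val = run$splits$val$U, Y_val = run$splits$val$Y,
                    X_test = run$splits$test$U, Y_test = run$splits$test$Y,
                    provenance = "initial design")

  ## wave 1: cut a fresh Sobol' candidate set with the reference bank
  cand1 <- sobol_points(space, cfg$n_candidates, skip = cfg$n_reference)
  I1 <- implausibility(bank0, targets, cand1)
  run$waves[[1]] <- list(
    wave_index = 1L, bank = bank0, threshold = cfg$thresholds[1],
    candidates = cand1, implausibility = I1,
    nroy_mask = I1 < cfg$thresholds[1],
    scores = bank0$scores, n_new_sims = 0L)
  run$ref_impl <- matrix(implausibility(bank0, targets, run$reference_set),
                         ncol = 1)

  for (j in seq_along(cfg$thresholds)[-1]) run <- run_wave(run, simulator)
  run
}

#' Execute one additional history-matching wave
#'
#' Selects a space-filling batch from the current NROY candidates, runs the
#' simulator on it, refits the emulator bank on all accumulated
#' simulations, repopulates the candidate set inside the current NROY
#' region with [cloud_sample()], and applies the next threshold
#' cumulatively. Normally called via [run_history_matching()].
#'
#' @param run An `hm_run` with at least one completed wave.
#' @param simulator As in [run_history_matching()] (defaults to the
#'   simulator stored in the run).
#' @return The extended `hm_run`.
#' @export
run_wave <- function(run, simulator = run$simulator) {
  cfg <- run$config
  j <- length(run$waves) + 1L
  if (j > length(cfg$thresholds))
    stop("all configured waves have already been run", call. = FALSE)
  run$simulator <- simulator
  prev <- run$waves[[j - 1L]]
  parents <- prev$candidates[prev$nroy_mask, , drop = FALSE]
  if (nrow(parents) == 0)
    stop(sprintf(paste0("empty NROY region after wave %d: no candidate ",
                        "survives; consider relaxing the thresholds"), j - 1L),
         call. = FALSE)

  batch <- select_batch(parents, cfg$n_per_wave, seed = cfg$seed + 10L * j)
  sims <- run_simulator(run, batch)
  run$train_U <- rbind(run$train_U, sims$U)
  run$train_Y <- rbind(run$train_Y, sims$Y)
  run$ledger <- rbind(run$ledger,
                      cbind(as.data.frame(sims$U), sims$Y, wave = j - 1L,
                            row.names = NULL))

  bank <- fit_bank(run$train_U, run$train_Y, noise_free = cfg$noise_free,
                   restarts = cfg$restarts, seed = cfg$seed + j,
                   maxit = cfg$maxit,
                   X_val = run$splits$val$U, Y_val = run$splits$val$Y,
                   X_test = run$splits$test$U, Y_test = run$splits$test$Y,
                   provenance = sprintf("wave %d", j))

  membership <- function(U) nroy_eval(run$waves, run$targets, U, j - 1L)
  cand <- cloud_sample(parents, cfg$n_candidates, membership,
                       sampler_config(seed = cfg$seed + 20L * j,
                                      cloud_scale = cfg$cloud_scale,
                                      cloud_offspring = cfg$cloud_offspring,
                                      max_rounds = cfg$cloud_max_rounds))
  I <- implausibility(bank, run$targets, cand)
  run$waves[[j]] <- list(
    wave_index = j, bank = bank, threshold = cfg$thresholds[j],
    candidates = cand, implausibility = I,
    nroy_mask = I < cfg$thresholds[j],
    scores = bank$scores, n_new_sims = nrow(sims$U))
  run$ref_impl <- cbind(run$ref_impl,
                        implausibility(bank, run$targets, run$reference_set))
  run
}

#' Cumulative NROY membership of arbitrary points
#'
#' A point is "not ruled out yet" after wave `k` iff its implausibility is
#' strictly below every wave's threshold, for all waves up to `k`
#' (conjunction over waves, so membership can only shrink).
#'
#' @param run An `hm_run`.
#' @param X Unit-frame matrix of points.
#' @param upto_wave Number of waves to apply (default: all; 0 keeps all
#'   points).
#' @return Logical vector over rows of `X`.
#' @export
nroy_membership <- function(run, X, upto_wave = length(run$waves)) {
  if (upto_wave > length(run$waves))
    stop("upto_wave exceeds the number of completed waves", call. = FALSE)
  nroy_eval(run$waves, run$targets, X, upto_wave)
}

## cumulative reference-set mask through wave `upto` using cached
## implausibilities
ref_mask <- function(run, upto = length(run$waves)) {
  keep <- rep(TRUE, nrow(run$reference_set))
  for (j in seq_len(upto))
    keep <- keep & (run$ref_impl[, j] < run$waves[[j]]$threshold)
  keep
}

#' NROY size as a percentage of the original space
#'
#' Monte-Carlo estimate over the run's fixed Sobol' reference set.
#'
#' @param run An `hm_run`.
#' @param upto_wave Number of waves applied (0 gives 100%).
#' @return Percentage in \[0, 100\].
#' @export
nroy_size <- function(run, upto_wave = length(run$waves)) {
  if (upto_wave == 0) return(100)
  100 * mean(ref_mask(run, upto_wave))
}

#' Agreement between two NROY masks
#'
#' Compares two implausibility classifications of the same reference set.
#' The whole-space match is the percentage of points with equal status
#' (both NROY or both ruled out); the NROY match is the percentage of A's
#' NROY points that are also NROY in B.
#'
#' @param mask_a,mask_b Logical vectors of equal length.
#' @return List `whole_space_pct`, `nroy_pct` (the latter `NA` when A has
#'   no NROY points).
#' @export
nroy_agreement <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b))
    stop("masks must have equal length", call. = FALSE)
  list(
    whole_space_pct = 100 * mean(mask_a == mask_b),
    nroy_pct = if (!any(mask_a)) NA_real_ else
      100 * mean(mask_b[mask_a])
  )
}

#' Calibrate a new subject by reusing a trained emulator bank
#'
#' The headline cost-saving scenario: a donor subject's final-wave emulator
#' bank is applied to a new (recipient) subject's targets in a single
#' implausibility cut over a reference set, running **zero** new
#' simulations.
#'
#' @param donor_bank A `gpe_bank` (typically the donor's final wave).
#' @param recipient_targets A [target_spec()] whose biomarkers are covered
#'   by the donor bank.
#' @param reference_set Unit-frame matrix over which to evaluate.
#' @param threshold Implausibility cutoff (default 3.0, the final-wave
#'   value).
#' @param truth Optional unit-frame ground-truth point; its implausibility
#'   is reported when supplied.
#' @return List with `mask` (logical over `reference_set`) and `stats`
#'   (`nroy_pct`, `truth_implausibility`, `vq_max`, `vq_median`).
#' @export
reuse_calibrate <- function(donor_bank, recipient_targets, reference_set,
                            threshold = 3.0, truth = NULL) {
  I <- implausibility(donor_bank, recipient_targets, reference_set)
  mask <- I < threshold
  vq <- vq_stats(donor_bank, recipient_targets, reference_set, mask)
  truth_I <- if (is.null(truth)) NA_real_ else
    implausibility(donor_bank, recipient_targets,
                   matrix(truth, nrow = 1))
  list(mask = mask,
       stats = list(nroy_pct = 100 * mean(mask),
                    truth_implausibility = truth_I,
                    vq_max = vq$max, vq_median = vq$median))
}

#' Sensitivity of the calibrated space to the assumed target uncertainty
#'
#' Repeats a calibration at different proportional uncertainties `c`
#' (default the high/low pair 0.10 and 0.05) and tabulates, per `c`, the
#' final NROY size and VQ statistics, and for each pair of `c` values the
#' whole-space overlap and the mutual NROY containment percentages. All
#' runs must share the same reference set (same seed and sizes), which the
#' supplied factory guarantees by construction.
#'
#' @param run_factory Function taking a single `c` value and returning a
#'   completed `hm_run` (same seeds/simulator across calls).
#' @param c_values Numeric vector of uncertainty fractions.
#' @return List with data frames `per_c` and `pairs`.
#' @export
uncertainty_sensitivity <- function(run_factory, c_values = c(0.10, 0.05)) {
  runs <- lapply(c_values, run_factory)
  per_c <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    m <- ref_mask(r)
    vq <- vq_stats(r$waves[[length(r$waves)]]$bank, r$targets,
                   r$reference_set, m)
    data.frame(c = c_values[i], nroy_pct = nroy_size(r),
               vq_max = vq$max, vq_median = vq$median)
  }))
  pairs <- NULL
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (i >= j) next
    mi <- ref_mask(runs[[i]]); mj <- ref_mask(runs[[j]])
    ag_ij <- nroy_agreement(mi, mj)
    ag_ji <- nroy_agreement(mj, mi)
    pairs <- rbind(pairs, data.frame(
      c_a = c_values[i], c_b = c_values[j],
      whole_space_pct = ag_ij$whole_space_pct,
      nroy_a_in_b_pct = ag_ij$nroy_pct,
      nroy_b_in_a_pct = ag_ji$nroy_pct))
  }
  list(per_c = per_c, pairs = pairs)
}

#' Per-parameter frequency map of an NROY point set
#'
#' For each parameter, the proportion of NROY points falling in each of
#' `n_bins` equal-width bins spanning the parameter's full range — the
#' marginal "shape" of the surviving region.
#'
#' @param nroy_points Unit-frame matrix of NROY members.
#' @param space A [parameter_space()] (supplies names and natural-unit bin
#'   edges).
#' @param n_bins Number of bins (>= 2; default 20).
#' @return Data frame with columns `parameter`, `bin`, `lower`, `upper`
#'   (natural units) and `proportion`; proportions sum to 1 per parameter.
#'   Empty input gives an empty data frame with a warning.
#' @export
frequency_map <- function(nroy_points, space, n_bins = 20L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (is.null(dim(nroy_points))) nroy_points <- matrix(nroy_points, nrow = 1)
  if (nrow(nroy_points) == 0) {
    warning("empty NROY set: returning an empty frequency map", call. = FALSE)
    return(data.frame(parameter = character(), bin = integer(),
                      lower = numeric(), upper = numeric(),
                      proportion = numeric()))
  }
  out <- vector("list", space$d)
  for (j in seq_len(space$d)) {
    u <- pmin(pmax(nroy_points[, j], 0), 1)
    bin <- pmin(floor(u * n_bins) + 1L, n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    edges <- seq(space$lower[j], space$upper[j], length.out = n_bins + 1L)
    out[[j]] <- data.frame(parameter = space$names[j], bin = seq_len(n_bins),
                           lower = edges[-(n_bins + 1L)], upper = edges[-1L],
                           proportion = counts / nrow(nroy_points))
  }
  do.call(rbind, out)
}

#' Wrap a simulator with a call counter
#'
#' Used to assert that emulator-reuse workflows run zero simulations.
#'
#' @param simulator A simulator function.
#' @return A function with the same signature; `attr(, "count")()` returns
#'   the number of calls so far.
#' @export
counting_simulator <- function(simulator) {
  n_calls <- 0L
  f <- function(X) {
    n_calls <<- n_calls + 1L
    simulator(X)
  }
  attr(f, "count") <- function() n_calls
  f
}

#' @export
print.hm_run <- function(x, ...) {
  cat(sprintf("<hm_run: %d wave(s), %d simulations, %d biomarkers>\n",
              length(x$waves), nrow(x$ledger),
              length(x$targets$biomarker_names)))
  for (j in seq_along(x$waves))
    cat(sprintf("  wave %d: threshold %.2f, NROY %.2f%%\n",
                j, x$waves[[j]]$threshold, nroy_size(x, j)))
  invisible(x)
}
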