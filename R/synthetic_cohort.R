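#' Deterministic synthetic electrophysiology biomarker simulator
#'
#' A closed-form, smooth stand-in for finite-element reaction-eikonal
#' simulations, so the full calibration pipeline can be exercised with no
#' external simulator. The functional forms are structurally motivated:
#' activation time scales with heart size and inversely with conduction
#' velocity; cross-fibre and fast-endocardial-conduction (FEC) velocity
#' ratios modulate it; endocardial activation is a bounded fraction of
#' total activation shortened by the FEC layer; anatomy is dominated by the
#' leading shape modes, mirroring the variance ordering of a PCA shape
#' model. They make no attempt to numerically match any particular
#' finite-element model.
#'
#' With inputs `u1..u14` in the unit cube (modes 1-9, fibre angle, FEC
#' height, CV, k_xf, k_FEC):
#' \deqn{S = 1 + 0.35 (0.40 u_1 + 0.23 u_2 + 0.14 u_3 + 0.09 u_4 +
#'   0.05 u_5 + 0.04 u_6 u_7 + 0.03 u_8 + 0.02 u_9)}
#' with natural-unit `CV = 0.64 + 0.28 u12`, `k_xf = 0.11 + 0.24 u13`,
#' `k_FEC = 1.1 + 7.65 u14`:
#' \deqn{TAT = 55 S / CV \cdot (1 + 0.08 (1 - k_{xf}/0.35)) \cdot
#'   (1 - 0.10 (1 - 1/k_{FEC}))}
#' \deqn{TAT_{LVendo} = TAT (0.20 + 0.25 (1-u_{11})(1 - 0.5 u_{14}) +
#'   0.05 (1-u_{10}))}
#' \deqn{LV_{mass} = 90 S^{1.7}, \quad
#'   LV_{dim} = 42 + 18 (0.6 u_1 + 0.4 u_3)}
#'
#' Over the whole cube, TAT stays within physiologic order (about 54-122
#' ms, bracketing the literature target 76.4 +/- 8.2 ms) and
#' `TAT_LV_endo/TAT` lies in \[0.20, 0.50\], so `TAT_LV_endo < TAT` always.
#'
#' @param space A [parameter_space()] with `d = 14` (only the dimension is
#'   checked; the biomarker map is defined on the unit cube).
#' @param U Unit-frame matrix with 14 columns.
#' @return Data frame with columns `TAT`, `TAT_LV_endo` (ms), `LV_mass`
#'   (g), `LV_dim` (mm).
#' @export
simulate_biomarkers <- function(space, U) {
  if (is.null(dim(U))) U <- matrix(U, nrow = 1)
  U <- as.matrix(U)
  if (ncol(U) != 14)
    stop("the synthetic simulator expects 14 input dimensions", call. = FALSE)
  if (space$d != 14)
    stop("the synthetic simulator requires a 14-dimensional space", call. = FALSE)
  if (any(U < -1e-9) || any(U > 1 + 1e-9))
    stop("inputs must be in the unit frame", call. = FALSE)
  S <- 1 + 0.35 * (0.40 * U[, 1] + 0.23 * U[, 2] + 0.14 * U[, 3] +
                   0.09 * U[, 4] + 0.05 * U[, 5] + 0.04 * U[, 6] * U[, 7] +
                   0.03 * U[, 8] + 0.02 * U[, 9])
  cv    <- 0.64 + 0.28 * U[, 12]
  k_xf  <- 0.11 + 0.24 * U[, 13]
  k_fec <- 1.10 + 7.65 * U[, 14]
  tat <- 55 * S / cv * (1 + 0.08 * (1 - k_xf / 0.35)) *
    (1 - 0.10 * (1 - 1 / k_fec))
  tat_lv <- tat * (0.20 + 0.25 * (1 - U[, 11]) * (1 - 0.5 * U[, 14]) +
                   0.05 * (1 - U[, 10]))
  data.frame(TAT = tat, TAT_LV_endo = tat_lv,
             LV_mass = 90 * S^1.7,
             LV_dim = 42 + 18 * (0.6 * U[, 1] + 0.4 * U[, 3]))
}

#' Simulator callback over natural units
#'
#' Wraps [simulate_biomarkers()] as a callback suitable for
#' [run_history_matching()], which hands the simulator natural-unit
#' designs.
#'
#' @param space A 14-dimensional [parameter_space()].
#' @return Function mapping a natural-units design matrix to the biomarker
#'   data frame.
#' @export
synthetic_simulator <- function(space) {
  force(space)
  function(X_nat) simulate_biomarkers(space, to_unit(space, X_nat))
}

#' Create a synthetic patient with known ground truth
#'
#' Draws (or accepts) a ground-truth parameter vector `u_star`, evaluates
#' the synthetic simulator at it, and derives calibration targets with
#' `sigma = c * mu` per biomarker. Drawn truths are uniform on
#' `[0.15, 0.85]^14`, keeping them away from the cube boundary where
#' emulator extrapolation degrades.
#'
#' @param space A 14-dimensional [parameter_space()].
#' @param u_star Optional explicit unit-frame ground-truth vector.
#' @param seed Integer seed used when `u_star` is drawn.
#' @param c Proportional target uncertainty (default 0.10).
#' @param id Patient identifier string.
#' @return An object of class `synthetic_patient` with fields `id`,
#'   `u_star`, `biomarkers` (1-row data frame) and `targets`.
#' @export
make_patient <- function(space, u_star = NULL, seed = 1L, c = 0.10,
                         id = "#01") {
  if (is.null(u_star)) {
    set.seed(seed)
    u_star <- stats::runif(14, 0.15, 0.85)
  }
  u_star <- as.numeric(u_star)
  if (length(u_star) != 14 || any(u_star < 0) || any(u_star > 1))
    stop("u_star must be a 14-vector inside the unit cube", call. = FALSE)
  bio <- simulate_biomarkers(space, matrix(u_star, nrow = 1))
  mu <- unlist(bio)
  structure(list(id = id, u_star = u_star, biomarkers = bio, c = c,
                 targets = make_targets_from_values(mu, c = c,
                                                    names = names(bio))),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient %s (c = %.2f)>\n", x$id, x$c))
  print(x$biomarkers, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' `n` seeded patients with zero-padded ids `#01..#n` and independent
#' ground-truth parameter vectors.
#'
#' @param space A 14-dimensional [parameter_space()].
#' @param n Cohort size (>= 1).
#' @param seed Base seed; patient `k` uses `seed + k`.
#' @param c Proportional target uncertainty.
#' @return List of [make_patient()] objects, class `synthetic_cohort`.
#' @export
make_cohort <- function(space, n, seed = 1L, c = 0.10) {
  stopifnot(n >= 1)
  ids <- sprintf("#%02d", seq_len(n))
  cohort <- lapply(seq_len(n), function(k)
    make_patient(space, seed = seed + k, c = c, id = ids[k]))
  structure(cohort, class = "synthetic_cohort")
}

#' Find the most dissimilar cohort member
#'
#' Returns the id of the member maximizing the l1 distance from the
#' indexed member, either in input space (unit-frame ground truths) or in
#' biomarker space (z-scored across the cohort so differently scaled
#' biomarkers contribute comparably). Ties break towards the smallest id.
#'
#' @param cohort A [make_cohort()] result (length >= 2).
#' @param index Index of the query member.
#' @param mode `"input"` or `"biomarker"`.
#' @return The id string of the farthest member.
#' @export
l1_farthest <- function(cohort, index = 1L, mode = c("input", "biomarker")) {
  mode <- match.arg(mode)
  n <- length(cohort)
  if (n < 2) stop("cohort must have at least 2 members", call. = FALSE)
  if (index < 1 || index > n) stop("index out of range", call. = FALSE)
  M <- if (mode == "input") {
    t(vapply(cohort, function(p) p$u_star, numeric(length(cohort[[1]]$u_star))))
  } else {
    B <- t(vapply(cohort, function(p) unlist(p$biomarkers),
                  numeric(ncol(cohort[[1]]$biomarkers))))
    scale(B)
  }
  d <- rowSums(abs(sweep(M, 2, M[index, ], "-")))
  d[index] <- -Inf
  cohort[[which.max(d)]]$id   # which.max takes the first (smallest id) on ties
}

#' Serialize a synthetic cohort
#'
#' Writes `cohort.json` (ids, ground truths, biomarkers, targets) and
#' `cohort_biomarkers.csv` (one row per patient) to a directory.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `read_cohort()` returns the cohort.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(cohort, function(p)
    list(id = p$id, u_star = p$u_star, c = p$c,
         biomarkers = as.list(p$biomarkers),
         targets = list(biomarker = p$targets$biomarker_names,
                        mu = p$targets$mu, sigma = p$targets$sigma)))
  jsonlite::write_json(recs, file.path(dir, "cohort.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  bio <- do.call(rbind, lapply(cohort, function(p)
    cbind(data.frame(id = p$id), p$biomarkers)))
  utils::write.csv(bio, file.path(dir, "cohort_biomarkers.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  recs <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = FALSE)
  cohort <- lapply(recs, function(r) {
    structure(list(
      id = r$id, u_star = unlist(r$u_star), c = r$c,
      biomarkers = as.data.frame(r$biomarkers),
      targets = target_spec(unlist(r$targets$biomarker),
                            unlist(r$targets$mu), unlist(r$targets$sigma))),
      class = "synthetic_patient")
  })
  structure(cohort, class = "synthetic_cohort")
}
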