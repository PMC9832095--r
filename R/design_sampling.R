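#' Sampler configuration for NROY resampling
#'
#' Bundles the knobs of the stochastic samplers. `cloud_scale` is the
#' standard deviation (in unit-cube units) of the multinormal perturbation
#' used by [cloud_sample()]; `cloud_offspring` is how many perturbations
#' each parent spawns per round. The scale is multiplied by the round index
#' in successive "expanding" rounds, so later rounds probe further from the
#' current NROY members.
#'
#' @param seed Integer seed; reproducibly determines all draws.
#' @param sobol_skip Non-negative integer; number of leading Sobol' points
#'   to skip.
#' @param cloud_scale Positive standard deviation of the cloud perturbation
#'   in unit-cube units (default 0.05).
#' @param cloud_offspring Offspring per parent per round (default 5).
#' @param max_rounds Iteration cap for the expanding cloud search.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(seed = 1L, sobol_skip = 0L, cloud_scale = 0.05,
                           cloud_offspring = 5L, max_rounds = 50L) {
  stopifnot(cloud_scale >= 0, cloud_offspring >= 1, max_rounds >= 1,
            sobol_skip >= 0)
  structure(list(seed = as.integer(seed), sobol_skip = as.integer(sobol_skip),
                 cloud_scale = cloud_scale,
                 cloud_offspring = as.integer(cloud_offspring),
                 max_rounds = as.integer(max_rounds)),
            class = "sampler_config")
}

#' Latin hypercube design on the unit cube
#'
#' Draws `n` points in `[0, 1]^d` such that every column has exactly one
#' point in each of the `n` equal-width strata. Deterministic given `seed`.
#'
#' @param space A [parameter_space()] (supplies the dimension and column
#'   names).
#' @param n Number of points (>= 1).
#' @param seed Integer seed.
#' @return An `n x d` unit-frame design matrix.
#' @export
latin_hypercube <- function(space, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  U <- lhs::randomLHS(as.integer(n), space$d)
  colnames(U) <- space$names
  attr(U, "frame") <- "unit"
  U
}

#' Sobol' sequence design on the unit cube
#'
#' The first `n` points of the (unscrambled) d-dimensional Sobol' sequence
#' after skipping `skip` points. Fully deterministic; the unskipped
#' sequence starts at the origin.
#'
#' @param space A [parameter_space()].
#' @param n Number of points (>= 1).
#' @param skip Number of leading points to skip (default 0).
#' @return An `n x d` unit-frame design matrix.
#' @export
sobol_points <- function(space, n, skip = 0L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  U <- sobol_matrix(n, space$d, skip)
  colnames(U) <- space$names
  attr(U, "frame") <- "unit"
  U
}

#' Repopulate an NROY region by the expanding "cloud" technique
#'
#' Generates candidate points inside an implicitly defined region by
#' perturbing known members ("parents") with centred multinormal noise and
#' keeping perturbations that (a) stay in the unit cube and (b) satisfy the
#' membership predicate. Rounds escalate: in round `r` the perturbation
#' standard deviation is `r * cloud_scale`, so the search expands towards
#' the NROY boundary as rounds proceed. Stops when `target_n` points have
#' been collected or `max_rounds` is exhausted (in which case fewer points
#' are returned, with a warning and a `capped` attribute).
#'
#' @param parents Non-empty unit-frame matrix of known region members.
#' @param target_n Number of points wanted.
#' @param membership Function taking a unit-frame matrix and returning a
#'   logical vector (`TRUE` = inside the region).
#' @param config A [sampler_config()].
#' @return A unit-frame matrix with up to `target_n` rows, all satisfying
#'   `membership`; attribute `capped` is `TRUE` if the round cap was hit.
#' @export
cloud_sample <- function(parents, target_n, membership, config = sampler_config()) {
  if (is.null(dim(parents))) parents <- matrix(parents, nrow = 1)
  n_par <- nrow(parents)
  d <- ncol(parents)
  if (n_par == 0)
    stop("empty NROY: no parent points to sample around", call. = FALSE)
  stopifnot(target_n >= 1)
  set.seed(config$seed)
  kept <- matrix(numeric(0), 0, d)
  capped <- TRUE
  for (round in seq_len(config$max_rounds)) {
    sc <- config$cloud_scale * round
    n_off <- n_par * config$cloud_offspring
    Z <- matrix(stats::rnorm(n_off * d), n_off, d)
    P <- parents[rep(seq_len(n_par), each = config$cloud_offspring), , drop = FALSE]
    X <- P + sc * Z
    inside <- rowSums(X < 0 | X > 1) == 0
    X <- X[inside, , drop = FALSE]
    if (nrow(X)) {
      ok <- membership(X)
      kept <- rbind(kept, X[ok, , drop = FALSE])
    }
    if (nrow(kept) >= target_n) {
      kept <- kept[seq_len(target_n), , drop = FALSE]
      capped <- FALSE
      break
    }
  }
  if (capped)
    warning(sprintf("cloud_sample: round cap reached with %d of %d points",
                    nrow(kept), target_n), call. = FALSE)
  colnames(kept) <- colnames(parents)
  attr(kept, "frame") <- "unit"
  attr(kept, "capped") <- capped
  kept
}

#' Greedy maximin batch selection
#'
#' Selects `k` rows of a design by farthest-point traversal: starting from
#' a (seed-chosen or supplied) row, repeatedly add the row whose minimum
#' Euclidean distance to the already-selected rows is largest. Keeps a
#' simulation batch space-filling inside the current NROY region. If the
#' design has fewer than `k` rows, all rows are returned.
#'
#' @param points Design matrix with at least one row.
#' @param k Batch size (>= 1).
#' @param seed Integer seed for the starting row (ignored when `start`
#'   given).
#' @param start Optional starting row index.
#' @return A matrix of `min(k, nrow(points))` rows of `points`.
#' @export
select_batch <- function(points, k, seed = 1L, start = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 1) stop("points must have at least one row", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= n) return(points)
  if (is.null(start)) {
    set.seed(seed)
    start <- sample.int(n, 1)
  }
  sel <- integer(k)
  sel[1] <- start
  ## min squared distance from each point to the selected set
  mind <- rowSums(sweep(points, 2, points[start, ], "-")^2)
  for (j in 2:k) {
    nxt <- which.max(mind)
    sel[j] <- nxt
    d2 <- rowSums(sweep(points, 2, points[nxt, ], "-")^2)
    mind <- pmin(mind, d2)
  }
  out <- points[sel, , drop = FALSE]
  attr(out, "frame") <- attr(points, "frame")
  out
}
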