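#' Define a bounded, named calibration parameter space
#'
#' A `parameter_space` describes the input dimensions of a calibration
#' problem: parameter names, lower/upper bounds in natural units, and unit
#' labels. All internal computation (sampling, emulation, implausibility)
#' happens on the unit hypercube; natural units appear only at the simulator
#' boundary and in reports, so that GP length-scales are comparable across
#' dimensions and uniform sampling is uniform in every coordinate.
#'
#' @param names Character vector of unique parameter names.
#' @param lower,upper Numeric vectors of bounds in natural units,
#'   elementwise `lower < upper`.
#' @param units Optional character vector of unit labels (default `""`).
#' @return An object of class `parameter_space` with fields `names`,
#'   `lower`, `upper`, `units` and dimension `d`.
#' @seealso [make_default_space()], [to_unit()], [from_unit()]
#' @export
parameter_space <- function(names, lower, upper, units = NULL) {
  names <- as.character(names)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (is.null(units)) units <- rep("", length(names))
  units <- as.character(units)
  d <- length(names)
  if (length(lower) != d || length(upper) != d || length(units) != d)
    stop("names, lower, upper and units must have equal length", call. = FALSE)
  if (anyDuplicated(names))
    stop("parameter names must be unique", call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  bad <- which(lower >= upper)
  if (length(bad))
    stop("lower bound must be strictly below upper bound for: ",
         paste(names[bad], collapse = ", "), call. = FALSE)
  structure(
    list(names = names, lower = lower, upper = upper, units = units, d = d),
    class = "parameter_space"
  )
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space: %d dimensions>\n", x$d))
  print(data.frame(name = x$names, lower = x$lower, upper = x$upper,
                   unit = x$units, row.names = NULL))
  invisible(x)
}

#' The default 14-dimensional cardiac EP calibration space
#'
#' Nine statistical-shape-model (SSM) mode weights followed by the five
#' functional electrophysiology parameters: fibre angle alpha (40--90
#' degrees), fast-endocardial-conduction (FEC) layer height (33--100 % of
#' the apico-basal extension), fibre-direction conduction velocity CV
#' (0.64--0.92 m/s), cross-fibre velocity ratio k_xf (0.11--0.35) and FEC
#' velocity ratio k_FEC (1.1--8.75). Mode-weight bounds default to
#' \[-3, 3\] (interpretable as standard deviations of a PCA mode weight)
#' and are configurable, since cohort-specific intervals depend on the
#' shape model at hand.
#'
#' @param mode_bounds Length-2 numeric vector of bounds shared by the nine
#'   SSM mode weights.
#' @return A [parameter_space()] with `d = 14`.
#' @examples
#' sp <- make_default_space()
#' sp$upper[sp$names == "CV"]
#' @export
make_default_space <- function(mode_bounds = c(-3, 3)) {
  stopifnot(length(mode_bounds) == 2, mode_bounds[1] < mode_bounds[2])
  mode_names <- sprintf("mode%d", 1:9)
  parameter_space(
    names = c(mode_names, "alpha", "FEC_height", "CV", "k_xf", "k_FEC"),
    lower = c(rep(mode_bounds[1], 9), 40, 33, 0.64, 0.11, 1.10),
    upper = c(rep(mode_bounds[2], 9), 90, 100, 0.92, 0.35, 8.75),
    units = c(rep("sd", 9), "deg", "% apico-basal", "m/s", "", "")
  )
}

## internal: coerce a design to a plain numeric matrix with d columns
as_design_matrix <- function(space, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!is.numeric(X)) stop("design matrix must be numeric", call. = FALSE)
  if (ncol(X) != space$d)
    stop(sprintf("design has %d columns but the space has %d dimensions",
                 ncol(X), space$d), call. = FALSE)
  X
}

#' Map a design between natural units and the unit hypercube
#'
#' `to_unit()` applies the affine map `u = (x - lower) / (upper - lower)`
#' column-wise; `from_unit()` is its inverse. The two are mutually inverse
#' to floating precision on any in-bounds design.
#'
#' @param space A [parameter_space()].
#' @param X Numeric matrix (or data frame) with one column per parameter;
#'   natural units for `to_unit()`, unit-cube values for `from_unit()`.
#' @return A numeric matrix of the same shape, columns named after the
#'   parameters, with a `frame` attribute of `"unit"` or `"natural"`.
#' @export
to_unit <- function(space, X) {
  X <- as_design_matrix(space, X)
  for (j in seq_len(space$d)) {
    out_of <- X[, j] < space$lower[j] - 1e-12 | X[, j] > space$upper[j] + 1e-12
    if (any(out_of))
      stop(sprintf("value out of bounds for parameter '%s': %g not in [%g, %g]",
                   space$names[j], X[which(out_of)[1], j],
                   space$lower[j], space$upper[j]), call. = FALSE)
  }
  U <- sweep(sweep(X, 2, space$lower, "-"), 2, space$upper - space$lower, "/")
  colnames(U) <- space$names
  attr(U, "frame") <- "unit"
  U
}

#' @rdname to_unit
#' @export
from_unit <- function(space, X) {
  U <- as_design_matrix(space, X)
  if (any(U < -1e-12) || any(U > 1 + 1e-12))
    stop("unit-frame design has entries outside [0, 1]", call. = FALSE)
  X <- sweep(sweep(U, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(X) <- space$names
  attr(X, "frame") <- "natural"
  X
}

#' Serialize a parameter space to / from JSON
#'
#' The on-disk form is a JSON array of `{name, lower, upper, unit}` records.
#'
#' @param space A [parameter_space()].
#' @param path File path.
#' @return `read_space()` returns a [parameter_space()]; `write_space()`
#'   returns `path` invisibly.
#' @export
write_space <- function(space, path) {
  df <- data.frame(name = space$names, lower = space$lower,
                   upper = space$upper, unit = space$units)
  jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  parameter_space(df$name, df$lower, df$upper, df$unit)
}
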