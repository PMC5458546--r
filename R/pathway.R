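#' Chain-of-states pathway
#'
#' A pathway is an ordered chain of `P + 1` replicas `x_0 .. x_P` separated by
#' a fixed time step `dt` (ps), with total transition time `t = P * dt`. The
#' two end replicas are the fixed endpoint configurations and are never moved
#' by any operation in this package. Torsion-space pathways store angles in
#' radians on (-pi, pi]; all replica-to-replica displacements for such
#' pathways use minimum-image angle differences so that velocities never jump
#' across the branch cut.
#'
#' @param replicas numeric matrix with `P + 1` rows (replicas) and `dim`
#'   columns (coordinates).
#' @param dt time step between successive replicas (ps).
#' @param kind coordinate convention, `"cartesian"` or `"torsion"`.
#' @return an object of class `"pathway"`: the replica matrix with `dt` and
#'   `kind` attributes.
#' @export
pathway <- function(replicas, dt, kind = c("cartesian", "torsion")) {
  kind <- match.arg(kind)
  replicas <- as.matrix(replicas)
  storage.mode(replicas) <- "double"
  if (nrow(replicas) < 3L)
    stop("a pathway needs at least P = 2 slices (3 replicas)", call. = FALSE)
  if (!all(is.finite(replicas)))
    stop("pathway coordinates must be finite", call. = FALSE)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  if (kind == "torsion") replicas[] <- wrap_angle(replicas)
  structure(replicas, dt = dt, kind = kind, class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway>  P = %d slices, dim = %d, dt = %g ps (t = %g ps), %s coordinates\n",
              nrow(x) - 1L, ncol(x), path_dt(x), (nrow(x) - 1L) * path_dt(x),
              path_kind(x)))
  invisible(x)
}

#' Accessors for pathway attributes
#' @param path a pathway.
#' @return `path_dt()` the time step (ps); `path_kind()` the coordinate
#'   convention; `path_interior()` the interior replica matrix (rows
#'   `1..P-1`).
#' @name pathway_accessors
#' @export
path_dt <- function(path) attr(path, "dt")

#' @rdname pathway_accessors
#' @export
path_kind <- function(path) attr(path, "kind")

#' Number of time slices P of a pathway
#' @param path a pathway.
#' @return integer P (the pathway has P + 1 replicas).
#' @export
n_slices <- function(path) nrow(path) - 1L

#' Wrap angles to the principal interval (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# replica-to-replica displacement rows: d_j = x_{j+1} - x_j (minimum image
# for torsion coordinates); matrix with P rows
path_displacements <- function(path) {
  d <- diff(unclass(path))
  if (path_kind(path) == "torsion") d[] <- wrap_angle(d)
  d
}

# displacement between two configuration matrices/vectors of one kind
coord_diff <- function(a, b, kind) {
  d <- a - b
  if (kind == "torsion") d <- wrap_angle(d)
  d
}

#' Straight-line interpolation pathway between two endpoints
#'
#' Linear interpolation with `P - 1` interior replicas; for torsion
#' coordinates the interpolation follows the minimum-image displacement from
#' the initial to the final angle of each coordinate.
#'
#' @param x_initial,x_final endpoint coordinate vectors.
#' @param P number of time slices (the path has `P + 1` replicas).
#' @param dt time step (ps).
#' @param kind coordinate convention.
#' @return a pathway.
#' @export
interpolate_path <- function(x_initial, x_final, P, dt,
                             kind = c("cartesian", "torsion")) {
  kind <- match.arg(kind)
  stopifnot(P >= 2, length(x_initial) == length(x_final))
  step <- coord_diff(x_final, x_initial, kind)
  frac <- seq(0, 1, length.out = P + 1L)
  reps <- outer(frac, step) + rep(x_initial, each = P + 1L)
  pathway(reps, dt = dt, kind = kind)
}

#' Replace the interior replicas of a pathway
#'
#' Endpoints and attributes are preserved; the replacement must have
#' `P - 1` rows.
#'
#' @param path a pathway.
#' @param interior replacement matrix for replicas `1..P-1`.
#' @return a pathway.
#' @export
set_interior <- function(path, interior) {
  p <- unclass(path)
  p[2:(nrow(p) - 1L), ] <- interior
  pathway(p, dt = path_dt(path), kind = path_kind(path))
}

#' @rdname pathway_accessors
#' @export
path_interior <- function(path) {
  unclass(path)[2:(nrow(path) - 1L), , drop = FALSE]
}

stopifnot_same_frame <- function(a, b) {
  if (ncol(a) != ncol(b) || path_kind(a) != path_kind(b))
    stop("pathways have different dimension or coordinate kind", call. = FALSE)
}
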