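#' Discrete Frechet distance between two pathways
#'
#' Dynamic programming over monotone couplings of the two replica sequences;
#' the per-point distance is the Euclidean norm (Cartesian coordinates) or
#' the Euclidean norm of minimum-image angle differences (torsion
#' coordinates). Replica counts may differ; time steps are ignored -- the
#' distance compares pathway geometry only.
#'
#' @param a,b pathways of the same dimension and coordinate kind.
#' @param return_witness also backtrack one optimal coupling.
#' @return a list of class `"path_distance"` with `value` and, on request,
#'   `witness` (a two-column matrix of coupled replica indices).
#' @export
frechet_distance <- function(a, b, return_witness = FALSE) {
  stopifnot_same_frame(a, b)
  A <- unclass(a); B <- unclass(b)
  n <- nrow(A); m <- nrow(B)
  # pairwise point distances from per-coordinate differences (exact for
  # identical points, unlike the expanded inner-product form)
  tor <- path_kind(a) == "torsion"
  d2 <- matrix(0, n, m)
  for (k in seq_len(ncol(A))) {
    dk <- outer(A[, k], B[, k], `-`)
    if (tor) dk <- wrap_angle(dk)
    d2 <- d2 + dk^2
  }
  dmat <- sqrt(d2)
  f <- matrix(Inf, n, m)
  f[1L, 1L] <- dmat[1L, 1L]
  for (j in 2:m) f[1L, j] <- max(f[1L, j - 1L], dmat[1L, j])
  for (i in 2:n) {
    f[i, 1L] <- max(f[i - 1L, 1L], dmat[i, 1L])
    for (j in 2:m) {
      f[i, j] <- max(min(f[i - 1L, j], f[i, j - 1L], f[i - 1L, j - 1L]),
                     dmat[i, j])
    }
  }
  out <- list(value = f[n, m])
  if (return_witness) {
    w <- matrix(c(n, m), ncol = 2L)
    i <- n; j <- m
    while (i > 1L || j > 1L) {
      opts <- rbind(c(i - 1L, j - 1L), c(i - 1L, j), c(i, j - 1L))
      opts <- opts[opts[, 1L] >= 1L & opts[, 2L] >= 1L, , drop = FALSE]
      vals <- f[opts]
      k <- which.min(vals)
      i <- opts[k, 1L]; j <- opts[k, 2L]
      w <- rbind(c(i, j), w)
    }
    out$witness <- w
  }
  class(out) <- "path_distance"
  out
}

#' @export
print.path_distance <- function(x, ...) {
  cat(sprintf("<path distance>  Frechet = %g\n", x$value))
  invisible(x)
}

# unwrap a torsion path into a continuous angle trace (cumulative
# minimum-image increments from the first replica)
unwrap_path <- function(m) {
  d <- wrap_angle(diff(m))
  rbind(m[1L, , drop = FALSE],
        sweep(apply(d, 2L, cumsum), 2L, m[1L, ], `+`))
}

#' Resample a pathway to a new replica count
#'
#' Arc-length-uniform piecewise-linear resampling. Endpoints are preserved
#' exactly; torsion paths are unwrapped to a continuous angle trace before
#' interpolation and wrapped back afterwards. The time step is rescaled so
#' the total transition time is unchanged.
#'
#' @param a a pathway.
#' @param P_new new number of slices (>= 2).
#' @return a pathway with `P_new + 1` replicas.
#' @export
resample_path <- function(a, P_new) {
  stopifnot(P_new >= 2)
  m <- unclass(a)
  tor <- path_kind(a) == "torsion"
  if (tor) m <- unwrap_path(m)
  seg <- sqrt(rowSums(diff(m)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  tgt <- seq(0, total, length.out = P_new + 1L)
  if (total <= 0) {
    out <- matrix(rep(m[1L, ], each = P_new + 1L), ncol = ncol(m))
  } else {
    out <- apply(m, 2L, function(col) stats::approx(s, col, xout = tgt,
                                                    ties = "ordered")$y)
  }
  out[1L, ] <- m[1L, ]
  out[P_new + 1L, ] <- m[nrow(m), ]
  if (tor) out <- wrap_angle(out)
  pathway(out, dt = path_dt(a) * n_slices(a) / P_new, kind = path_kind(a))
}

#' Assign a trajectory to its nearest reference pathway
#'
#' The trajectory is resampled to each reference's replica count and the
#' discrete Frechet distance is computed; the reference of minimum distance
#' wins, ties going to the lowest index.
#'
#' @param traj a pathway (e.g. a transition segment of a simulated
#'   trajectory).
#' @param refs non-empty list of reference pathways.
#' @return a list with `index` (1-based) and `distance`.
#' @export
assign_nearest_reference <- function(traj, refs) {
  stopifnot(length(refs) >= 1L)
  dists <- vapply(refs, function(r) {
    a <- if (n_slices(traj) == n_slices(r)) traj else
      resample_path(traj, n_slices(r))
    frechet_distance(a, r)$value
  }, numeric(1L))
  i <- which.min(dists)   # which.min returns the first (lowest-index) min
  list(index = i, distance = dists[i])
}
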