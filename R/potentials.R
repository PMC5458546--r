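#' Analytic potential-energy surfaces
#'
#' Pluggable analytic surfaces used as desk-scale stand-ins for molecular force
#' fields. Each potential knows its dimension, coordinate convention
#' (`"cartesian"` or `"torsion"`), and whether an analytic Hessian is available.
#' Energies are in kcal/mol-equivalent units, lengths are dimensionless
#' Cartesian coordinates or radians, time is in ps.
#'
#' Built-in surfaces:
#' * [harmonic_well()] -- separable quadratic well, the exactly solvable case;
#' * [muller_brown()] -- the classic four-Gaussian 2D benchmark surface;
#' * [two_channel_2d()] -- two Gaussian wells connected by two saddle channels
#'   of unequal height (configurable gap), for pathway rank-order experiments;
#' * [torsional_chain()] -- `n` uncoupled dihedral angles, each with
#'   gauche(-)/trans/gauche(+) minima and the cis barrier strictly highest,
#'   for sampling-completeness experiments on rotamer chains.
#'
#' @param pot a potential object.
#' @param x a numeric coordinate vector of length `dim(pot)`, or a matrix with
#'   `dim(pot)` columns (one row per configuration; energy and gradient are
#'   vectorized over rows).
#' @return `evaluate_energy()` returns a numeric scalar (or vector for matrix
#'   input); `evaluate_gradient()` a vector of length `dim` (or a matrix);
#'   `evaluate_hessian()` a symmetric `dim x dim` matrix.
#' @name potentials
NULL

new_potential <- function(name, dim, coord_kind, params, hessian = TRUE,
                          class) {
  structure(
    list(name = name, dim = as.integer(dim), coord_kind = coord_kind,
         params = params, hessian_supported = hessian),
    class = c(class, "acsa_potential"))
}

#' @export
print.acsa_potential <- function(x, ...) {
  cat(sprintf("<potential '%s'>  dim = %d, coordinates = %s, analytic Hessian: %s\n",
              x$name, x$dim, x$coord_kind,
              if (isTRUE(x$hessian_supported)) "yes" else "no"))
  invisible(x)
}

pot_dim <- function(pot) pot$dim

as_row_matrix <- function(pot, x) {
  if (is.matrix(x)) {
    if (ncol(x) != pot$dim)
      stop(sprintf("coordinate matrix has %d columns, potential '%s' has dim %d",
                   ncol(x), pot$name, pot$dim), call. = FALSE)
    x
  } else {
    if (length(x) != pot$dim)
      stop(sprintf("coordinate vector has length %d, potential '%s' has dim %d",
                   length(x), pot$name, pot$dim), call. = FALSE)
    matrix(x, nrow = 1L)
  }
}

#' @rdname potentials
#' @export
evaluate_energy <- function(pot, x) UseMethod("evaluate_energy")

#' @rdname potentials
#' @export
evaluate_gradient <- function(pot, x) UseMethod("evaluate_gradient")

#' @rdname potentials
#' @export
evaluate_hessian <- function(pot, x) UseMethod("evaluate_hessian")

#' @export
evaluate_hessian.default <- function(pot, x) {
  stop(sprintf("potential '%s' does not support analytic Hessians", pot$name),
       call. = FALSE)
}

drop_if_single <- function(x, m) if (nrow(m) == 1L && !is.matrix(x)) m[1L, ] else m

## ---------------------------------------------------------------- harmonic

#' Harmonic well
#'
#' Separable quadratic well `V(x) = sum(kappa * (x - center)^2) / 2`.
#'
#' @param kappa force constant(s), scalar or one per coordinate.
#' @param dim number of degrees of freedom.
#' @param center location of the minimum.
#' @return a potential object.
#' @export
harmonic_well <- function(kappa = 1, dim = 1, center = rep(0, dim)) {
  stopifnot(dim >= 1, all(kappa > 0), length(center) == dim)
  kappa <- rep_len(kappa, dim)
  new_potential("harmonic_well", dim, "cartesian",
                list(kappa = kappa, center = center),
                class = "acsa_harmonic")
}

#' @export
evaluate_energy.acsa_harmonic <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  dx <- sweep(m, 2L, pot$params$center)
  as.numeric(dx^2 %*% (pot$params$kappa / 2))
}

#' @export
evaluate_gradient.acsa_harmonic <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  dx <- sweep(m, 2L, pot$params$center)
  drop_if_single(x, sweep(dx, 2L, pot$params$kappa, `*`))
}

#' @export
evaluate_hessian.acsa_harmonic <- function(pot, x) {
  as_row_matrix(pot, x)
  diag(pot$params$kappa, nrow = pot$dim)
}

## ------------------------------------------------------------ Muller-Brown

#' Muller-Brown surface
#'
#' The standard four-term Gaussian benchmark surface in two dimensions, with
#' three minima and two saddle points.
#'
#' @param scale multiplies all term amplitudes; the conventional surface has
#'   barriers of order 100 energy units, `scale` lets the surface be brought
#'   to kcal/mol magnitudes.
#' @return a potential object.
#' @export
muller_brown <- function(scale = 1) {
  p <- list(A  = scale * c(-200, -100, -170, 15),
            a  = c(-1, -1, -6.5, 0.7),
            b  = c(0, 0, 11, 0.6),
            cc = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))
  new_potential("muller_brown", 2L, "cartesian", p, class = "acsa_mb")
}

mb_terms <- function(pot, m) {
  p <- pot$params
  xs <- m[, 1L]; ys <- m[, 2L]
  lapply(seq_along(p$A), function(k) {
    dx <- xs - p$x0[k]; dy <- ys - p$y0[k]
    e <- p$A[k] * exp(p$a[k] * dx^2 + p$b[k] * dx * dy + p$cc[k] * dy^2)
    list(e = e, dx = dx, dy = dy)
  })
}

#' @export
evaluate_energy.acsa_mb <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  Reduce(`+`, lapply(mb_terms(pot, m), `[[`, "e"))
}

#' @export
evaluate_gradient.acsa_mb <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  p <- pot$params
  gx <- gy <- numeric(nrow(m))
  for (k in seq_along(p$A)) {
    dx <- m[, 1L] - p$x0[k]; dy <- m[, 2L] - p$y0[k]
    e <- p$A[k] * exp(p$a[k] * dx^2 + p$b[k] * dx * dy + p$cc[k] * dy^2)
    gx <- gx + e * (2 * p$a[k] * dx + p$b[k] * dy)
    gy <- gy + e * (p$b[k] * dx + 2 * p$cc[k] * dy)
  }
  drop_if_single(x, cbind(gx, gy, deparse.level = 0L))
}

#' @export
evaluate_hessian.acsa_mb <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  stopifnot(nrow(m) == 1L)
  p <- pot$params
  h <- matrix(0, 2L, 2L)
  for (k in seq_along(p$A)) {
    dx <- m[1L, 1L] - p$x0[k]; dy <- m[1L, 2L] - p$y0[k]
    e <- p$A[k] * exp(p$a[k] * dx^2 + p$b[k] * dx * dy + p$cc[k] * dy^2)
    u <- 2 * p$a[k] * dx + p$b[k] * dy
    v <- p$b[k] * dx + 2 * p$cc[k] * dy
    h[1L, 1L] <- h[1L, 1L] + e * (u^2 + 2 * p$a[k])
    h[2L, 2L] <- h[2L, 2L] + e * (v^2 + 2 * p$cc[k])
    h[1L, 2L] <- h[1L, 2L] + e * (u * v + p$b[k])
  }
  h[2L, 1L] <- h[1L, 2L]
  h
}

## ---------------------------------------------------------- two-channel 2D

#' Two-channel double-well surface
#'
#' A sum-of-Gaussians surface with two minima near (-1, 0) and (+1, 0)
#' connected by two saddle channels, one below (y < 0) and one above (y > 0)
#' the central wall. The upper channel carries an extra Gaussian bump of
#' height `barrier_gap`, so the two channel barriers differ by approximately
#' that amount and the lower channel is always the easier one. This is the
#' surface used for pathway rank-order experiments: a correct search must find
#' both channels and rank the lower-barrier one first.
#'
#' @param barrier_gap approximate difference between the upper- and
#'   lower-channel barrier heights (kcal/mol); must be >= 0.
#' @param well_depth depth of the two Gaussian wells.
#' @param wall_height height of the central wall separating the channels.
#' @param confinement harmonic confinement constant keeping the surface bounded.
#' @return a potential object.
#' @export
two_channel_2d <- function(barrier_gap = 1.5, well_depth = 3,
                           wall_height = 8, confinement = 0.5) {
  stopifnot(barrier_gap >= 0, well_depth > 0, wall_height > 0, confinement > 0)
  # anisotropic Gaussian terms: amplitude, center, standard deviations;
  # the bump is elongated along y so the upper saddle cannot slide off it
  terms <- list(
    list(A = -well_depth, cx = -1, cy = 0,   sx = 0.55, sy = 0.55),
    list(A = -well_depth, cx =  1, cy = 0,   sx = 0.55, sy = 0.55),
    list(A = wall_height, cx =  0, cy = 0,   sx = 0.50, sy = 0.50),
    list(A = barrier_gap, cx =  0, cy = 1.5, sx = 0.45, sy = 1.00))
  new_potential("two_channel_2d", 2L, "cartesian",
                list(terms = terms, confinement = confinement,
                     barrier_gap = barrier_gap),
                class = "acsa_twochannel")
}

#' @export
evaluate_energy.acsa_twochannel <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  v <- pot$params$confinement * 0.5 * (m[, 1L]^2 + m[, 2L]^2)
  for (tm in pot$params$terms) {
    v <- v + tm$A * exp(-(m[, 1L] - tm$cx)^2 / (2 * tm$sx^2) -
                          (m[, 2L] - tm$cy)^2 / (2 * tm$sy^2))
  }
  v
}

#' @export
evaluate_gradient.acsa_twochannel <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  gx <- pot$params$confinement * m[, 1L]
  gy <- pot$params$confinement * m[, 2L]
  for (tm in pot$params$terms) {
    dx <- m[, 1L] - tm$cx; dy <- m[, 2L] - tm$cy
    e <- tm$A * exp(-dx^2 / (2 * tm$sx^2) - dy^2 / (2 * tm$sy^2))
    gx <- gx - e * dx / tm$sx^2
    gy <- gy - e * dy / tm$sy^2
  }
  drop_if_single(x, cbind(gx, gy, deparse.level = 0L))
}

#' @export
evaluate_hessian.acsa_twochannel <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  stopifnot(nrow(m) == 1L)
  h <- diag(pot$params$confinement, 2L)
  for (tm in pot$params$terms) {
    dx <- m[1L, 1L] - tm$cx; dy <- m[1L, 2L] - tm$cy
    e <- tm$A * exp(-dx^2 / (2 * tm$sx^2) - dy^2 / (2 * tm$sy^2))
    h[1L, 1L] <- h[1L, 1L] + e * (dx^2 / tm$sx^4 - 1 / tm$sx^2)
    h[2L, 2L] <- h[2L, 2L] + e * (dy^2 / tm$sy^4 - 1 / tm$sy^2)
    h[1L, 2L] <- h[1L, 2L] + e * dx * dy / (tm$sx^2 * tm$sy^2)
  }
  h[2L, 1L] <- h[1L, 2L]
  h
}

## --------------------------------------------------------- torsional chain

#' Uncoupled torsional chain
#'
#' `n` dihedral angles, each feeling the same five-term cosine series
#' `u(phi) = c0 + sum_{k=1}^{5} a_k cos(k phi)`. The coefficients are the
#' minimum-norm solution of the linear system that places exact stationary
#' points at -60, +60 and 180 degrees (gauche(-), gauche(+), trans minima)
#' and prescribes three energies relative to trans: the gauche offset, the
#' gauche/trans barrier at +-120 degrees, and the cis barrier at 0 degrees,
#' which must be strictly highest. The defaults (0.9 / 3.0 / 8.0 kcal/mol)
#' mimic an alkane C-C torsion, where the cis barrier is high enough that
#' optimized transition pathways go through trans rather than over cis.
#' The construction is verified at build time: exactly six stationary points
#' per period, positive curvature at the three minima. Coordinates are
#' radians on (-pi, pi]; energy and gradient are exactly 2*pi-periodic per
#' coordinate.
#'
#' @param n number of dihedral angles.
#' @param gauche_offset energy of the gauche minima above trans (kcal/mol).
#' @param tg_barrier height of the gauche/trans barrier above trans
#'   (kcal/mol).
#' @param cis_barrier height of the cis barrier above trans (kcal/mol);
#'   must exceed `tg_barrier`.
#' @return a potential object.
#' @export
torsional_chain <- function(n, gauche_offset = 0.9, tg_barrier = 3.0,
                            cis_barrier = 8.0) {
  stopifnot(n >= 1, gauche_offset > 0, tg_barrier > gauche_offset,
            cis_barrier > tg_barrier)
  k <- seq_len(5)
  cosk <- function(deg) cos(k * deg * pi / 180)
  A <- rbind(-k * sin(k * pi / 3),            # u'(60 deg) = 0
             cosk(60) - cosk(180),
             cosk(120) - cosk(180),
             cosk(0) - cosk(180))
  a <- as.numeric(t(A) %*% qr.solve(A %*% t(A),
                                    c(0, gauche_offset, tg_barrier,
                                      cis_barrier)))
  c0 <- -sum(a * cosk(180))                   # trans minimum at zero energy
  # verify the series has no spurious stationary points and true minima
  phis <- seq(-pi, pi, length.out = 2000L)
  du <- vapply(phis, function(p) -sum(k * a * sin(k * p)), numeric(1L))
  if (sum(diff(sign(du)) != 0) > 5L)
    stop("torsional series has spurious stationary points; ",
         "choose less extreme energies", call. = FALSE)
  d2 <- function(p) -sum(k^2 * a * cos(k * p))
  stopifnot(d2(pi / 3) > 0, d2(pi) > 0, d2(0) < 0)
  new_potential("torsional_chain", n, "torsion",
                list(a = a, c0 = c0, gauche_offset = gauche_offset,
                     tg_barrier = tg_barrier, cis_barrier = cis_barrier),
                class = "acsa_torchain")
}

#' @export
evaluate_energy.acsa_torchain <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  a <- pot$params$a
  u <- pot$params$c0
  for (k in 1:5) u <- u + a[k] * cos(k * m)
  rowSums(matrix(u, nrow = nrow(m)))
}

#' @export
evaluate_gradient.acsa_torchain <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  a <- pot$params$a
  g <- 0
  for (k in 1:5) g <- g - k * a[k] * sin(k * m)
  drop_if_single(x, matrix(g, nrow = nrow(m)))
}

#' @export
evaluate_hessian.acsa_torchain <- function(pot, x) {
  m <- as_row_matrix(pot, x)
  stopifnot(nrow(m) == 1L)
  a <- pot$params$a
  d2 <- 0
  for (k in 1:5) d2 <- d2 - k^2 * a[k] * cos(k * m[1L, ])
  diag(d2, nrow = pot$dim)
}

## --------------------------------------------------- stationary-point tools

#' Locate a stationary point by Newton iteration on the gradient
#'
#' @param pot a potential with analytic Hessian.
#' @param x0 starting coordinates.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return a list with `x`, `energy`, `grad_norm`, `converged`, and `index`
#'   (number of negative Hessian eigenvalues: 0 for a minimum, 1 for a
#'   first-order saddle).
#' @export
find_stationary <- function(pot, x0, tol = 1e-10, max_iter = 100) {
  x <- as.numeric(x0)
  for (i in seq_len(max_iter)) {
    g <- evaluate_gradient(pot, x)
    if (sqrt(sum(g^2)) <= tol) break
    h <- evaluate_hessian(pot, x)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(x = x, energy = evaluate_energy(pot, x),
                  grad_norm = sqrt(sum(g^2)), converged = FALSE, index = NA_integer_))
    }
    if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))  # damped
    x <- x - step
  }
  g <- evaluate_gradient(pot, x)
  ev <- eigen(evaluate_hessian(pot, x), symmetric = TRUE, only.values = TRUE)$values
  list(x = x, energy = evaluate_energy(pot, x), grad_norm = sqrt(sum(g^2)),
       converged = sqrt(sum(g^2)) <= tol, index = sum(ev < -1e-8))
}

#' Grid-scan all stationary points of a 2D potential
#'
#' Newton iterations started from a regular grid, deduplicated. Used to
#' document minima and saddle channels of the shipped 2D surfaces.
#'
#' @param pot a 2D potential with analytic Hessian.
#' @param lower,upper corners of the scanned box.
#' @param n_grid grid points per axis.
#' @return a data.frame with columns x, y, energy, index.
#' @export
stationary_points <- function(pot, lower = c(-2, -2), upper = c(2, 2),
                              n_grid = 15) {
  stopifnot(pot$dim == 2L)
  xs <- seq(lower[1L], upper[1L], length.out = n_grid)
  ys <- seq(lower[2L], upper[2L], length.out = n_grid)
  found <- list()
  for (x0 in xs) for (y0 in ys) {
    st <- find_stationary(pot, c(x0, y0))
    if (!st$converged) next
    if (st$x[1L] < lower[1L] - 0.5 || st$x[1L] > upper[1L] + 0.5 ||
        st$x[2L] < lower[2L] - 0.5 || st$x[2L] > upper[2L] + 0.5) next
    dup <- any(vapply(found, function(f) sqrt(sum((f$x - st$x)^2)) < 1e-5,
                      logical(1L)))
    if (!dup) found[[length(found) + 1L]] <- st
  }
  out <- do.call(rbind, lapply(found, function(f)
    data.frame(x = f$x[1L], y = f$x[2L], energy = f$energy, index = f$index)))
  out[order(out$index, out$energy), , drop = FALSE]
}

#' Pair of endpoint configurations
#'
#' Validates that both endpoints are local minima of the potential within a
#' gradient-norm tolerance.
#'
#' @param pot a potential.
#' @param x_initial,x_final coordinate vectors.
#' @param labels basin labels.
#' @param grad_tol maximum allowed gradient norm at each endpoint.
#' @return a list of class `"endpoint_pair"`.
#' @export
endpoint_pair <- function(pot, x_initial, x_final,
                          labels = c("initial", "final"), grad_tol = 1e-6) {
  x_initial <- as.numeric(x_initial); x_final <- as.numeric(x_final)
  stopifnot(length(x_initial) == pot$dim, length(x_final) == pot$dim,
            all(is.finite(x_initial)), all(is.finite(x_final)))
  for (x in list(x_initial, x_final)) {
    gn <- sqrt(sum(evaluate_gradient(pot, x)^2))
    if (gn > grad_tol)
      stop(sprintf("endpoint is not a stationary point: |grad| = %.3g > %.3g",
                   gn, grad_tol), call. = FALSE)
  }
  structure(list(x_initial = x_initial, x_final = x_final,
                 basin_labels = labels), class = "endpoint_pair")
}
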