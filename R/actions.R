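#' Thermodynamic parameters
#'
#' @param gamma collision frequency of the overdamped Langevin dynamics
#'   (ps^-1).
#' @param temperature temperature (K).
#' @param kB Boltzmann constant (kcal mol^-1 K^-1).
#' @return a list of class `"thermo_params"`.
#' @export
thermo_params <- function(gamma = 1.0, temperature = 350, kB = 0.0019872) {
  stopifnot(gamma > 0, temperature > 0, kB > 0)
  structure(list(gamma = gamma, temperature = temperature, kB = kB),
            class = "thermo_params")
}

#' Weights of the restrained classical-action objective
#'
#' The local-optimization objective is
#' `Theta = mu_A * S_classical + mu_E * sum_j (E_j - E_target)^2`,
#' where `E_j` is the total (kinetic + potential) energy of slice `j`. The
#' conventional weights are `mu_A = -1`, `mu_E = 1`: the classical action is
#' driven towards a maximum subject to the quadratic total-energy restraint,
#' which keeps the objective bounded and its minimizers close to
#' energy-conserving Newtonian paths.
#'
#' @param mu_A weight of the classical action.
#' @param mu_E weight (>= 0) of the total-energy restraint.
#' @param E_target target total energy (kcal/mol); see
#'   [compute_reference_energy()].
#' @return a list of class `"action_weights"`.
#' @export
action_weights <- function(mu_A = -1.0, mu_E = 1.0, E_target = 0) {
  stopifnot(mu_E >= 0, is.finite(mu_A), is.finite(E_target))
  structure(list(mu_A = mu_A, mu_E = mu_E, E_target = E_target),
            class = "action_weights")
}

# gradient rows for every replica, with an error that names the replica
path_gradients <- function(path, pot) {
  g <- evaluate_gradient(pot, unclass(path))
  if (!is.matrix(g)) g <- matrix(g, nrow = nrow(path))
  bad <- which(!is.finite(rowSums(g)))
  if (length(bad))
    stop(sprintf("non-finite potential gradient at replica %d", bad[1L] - 1L),
         call. = FALSE)
  g
}

#' Discretized Onsager-Machlup action (gradient-only)
#'
#' Second-order discretization of the symmetric Onsager-Machlup action for
#' overdamped Langevin dynamics `gamma * dx/dt = -grad V + R`,
#'
#' \deqn{S_{OM} = \frac{\Delta V}{2}
#'   + \sum_{j=0}^{P-1} \frac{\gamma\, |x_{j+1}-x_j|^2}{4\,\Delta t}
#'   + \frac{\Delta t}{4\gamma} \sum_{j=0}^{P} w_j\, |\nabla V(x_j)|^2,}
#'
#' with trapezoidal weights `w = (1/2, 1, ..., 1, 1/2)` and
#' `DeltaV = V(x_P) - V(x_0)`. Only potential gradients are evaluated, never
#' Hessians; the cross term of the expanded square telescopes exactly to the
#' endpoint potential difference, making the discretization second order in
#' `dt` for smooth paths. Lower values identify more probable pathways; see
#' [path_probability_ratio()].
#'
#' @param path a [pathway()].
#' @param pot a potential.
#' @param th [thermo_params()].
#' @return the action (kcal/mol units of energy x dimensionless time scaling).
#' @seealso [om_action_continuous()] for the fine-quadrature oracle including
#'   the entropic (trace-of-Hessian) term.
#' @export
om_action <- function(path, pot, th) {
  stopifnot(inherits(path, "pathway"), inherits(th, "thermo_params"))
  if (ncol(path) != pot$dim)
    stop("pathway dimension does not match potential", call. = FALSE)
  dt <- path_dt(path)
  d <- path_displacements(path)
  g <- path_gradients(path, pot)
  g2 <- rowSums(g^2)
  w <- c(0.5, rep(1, nrow(path) - 2L), 0.5)
  dV <- evaluate_energy(pot, unclass(path)[nrow(path), ]) -
    evaluate_energy(pot, unclass(path)[1L, ])
  dV / 2 +
    th$gamma * sum(d^2) / (4 * dt) +
    dt * sum(w * g2) / (4 * th$gamma)
}

#' Fine-quadrature Onsager-Machlup action along a piecewise-linear path
#'
#' Quadrature approximation of the continuous generalized Onsager-Machlup
#' action
#' \deqn{S = \frac{\Delta V}{2} + \int_0^t \Big[ \frac{\gamma}{4}|\dot x|^2
#'   + \frac{|\nabla V|^2}{4\gamma}
#'   - \frac{k_B T}{2\gamma}\,\mathrm{tr}\,\nabla^2 V \Big] dt'}
#' evaluated along the piecewise-linear interpolant of the chain, with
#' `refine` sub-steps per slice (trapezoidal rule on each slice). The last
#' (trace-of-Hessian) term is the entropic correction accounting for the
#' width of the tube of trajectories around the path; it requires the
#' analytic Hessian and is therefore available only as a testing oracle, not
#' inside the search. Setting `include_entropic = FALSE` gives the quadrature
#' of the symmetric (gradient-only) formula that [om_action()] discretizes.
#'
#' @inheritParams om_action
#' @param refine sub-steps per slice (>= 1).
#' @param include_entropic include the trace-of-Hessian term.
#' @return the action.
#' @export
om_action_continuous <- function(path, pot, th, refine = 20,
                                 include_entropic = TRUE) {
  stopifnot(inherits(path, "pathway"), refine >= 1)
  if (include_entropic && !isTRUE(pot$hessian_supported))
    stop(sprintf("potential '%s' does not support analytic Hessians", pot$name),
         call. = FALSE)
  dt <- path_dt(path)
  d <- path_displacements(path)
  P <- n_slices(path)
  h <- dt / refine
  total <- 0
  for (j in seq_len(P)) {
    x0 <- unclass(path)[j, ]
    v <- d[j, ] / dt                      # constant velocity on the slice
    ke <- th$gamma * sum(v^2) / 4
    # trapezoid over refine+1 quadrature nodes on this slice
    wq <- c(0.5, rep(1, refine - 1L), 0.5)
    for (k in 0:refine) {
      xk <- x0 + v * (k * h)
      val <- ke + sum(evaluate_gradient(pot, xk)^2) / (4 * th$gamma)
      if (include_entropic)
        val <- val - th$kB * th$temperature *
          sum(diag(evaluate_hessian(pot, xk))) / (2 * th$gamma)
      total <- total + wq[k + 1L] * val * h
    }
  }
  dV <- evaluate_energy(pot, unclass(path)[P + 1L, ]) -
    evaluate_energy(pot, unclass(path)[1L, ])
  dV / 2 + total
}

#' Discretized classical action
#'
#' \deqn{S_{cl} = \sum_{j=0}^{P-1} \Delta t \Big[
#'   \frac{|x_{j+1}-x_j|^2}{2\,\Delta t^2}
#'   - \frac{V(x_j) + V(x_{j+1})}{2} \Big]}
#' with unit masses and forward (slice) velocities; the potential term uses
#' trapezoidal weights. Stationary chains of this action satisfy the discrete
#' Newton equations.
#'
#' @inheritParams om_action
#' @return the classical action.
#' @export
classical_action <- function(path, pot) {
  stopifnot(inherits(path, "pathway"))
  dt <- path_dt(path)
  d <- path_displacements(path)
  v <- evaluate_energy(pot, unclass(path))
  if (any(!is.finite(v)))
    stop(sprintf("non-finite potential energy at replica %d",
                 which(!is.finite(v))[1L] - 1L), call. = FALSE)
  w <- c(0.5, rep(1, nrow(path) - 2L), 0.5)
  sum(d^2) / (2 * dt) - dt * sum(w * v)
}

#' Total energy of one time slice of a pathway
#'
#' `E_j = |x_{j+1} - x_j|^2 / (2 dt^2) + V(x_j)` for `j = 0..P-1`, using the
#' same forward-difference velocity convention as [classical_action()] and
#' the restraint term of [theta_objective()]. For `j = P` the backward
#' difference is used, so the last replica reports the energy of the final
#' slice with its own potential energy.
#'
#' @inheritParams om_action
#' @param j replica index in `0..P`.
#' @return total energy (kcal/mol).
#' @export
replica_total_energy <- function(path, pot, j) {
  P <- n_slices(path)
  if (length(j) != 1L || j < 0 || j > P)
    stop(sprintf("replica index %s out of range 0..%d", format(j), P),
         call. = FALSE)
  d <- path_displacements(path)
  dt <- path_dt(path)
  kin <- if (j < P) sum(d[j + 1L, ]^2) else sum(d[P, ]^2)
  kin / (2 * dt^2) + evaluate_energy(pot, unclass(path)[j + 1L, ])
}

# slice energies E_0..E_{P-1} (vectorized internal form)
slice_energies <- function(path, pot) {
  d <- path_displacements(path)
  dt <- path_dt(path)
  v <- evaluate_energy(pot, unclass(path))
  rowSums(d^2) / (2 * dt^2) + v[seq_len(nrow(d))]
}

#' Restrained classical-action objective Theta
#'
#' `Theta = mu_A * S_classical + mu_E * sum_{j=0}^{P-1} (E_j - E_target)^2`
#' where `E_j` are the slice total energies of [replica_total_energy()].
#' With the conventional weights `mu_A = -1`, `mu_E = 1` the minimizers are
#' approximately energy-conserving stationary paths of the classical action.
#' Minimizing Theta requires only first derivatives of the potential.
#'
#' @inheritParams om_action
#' @param w [action_weights()].
#' @return the objective value.
#' @export
theta_objective <- function(path, pot, w) {
  stopifnot(inherits(w, "action_weights"))
  s <- classical_action(path, pot)
  pen <- if (w$mu_E > 0) sum((slice_energies(path, pot) - w$E_target)^2) else 0
  w$mu_A * s + w$mu_E * pen
}

#' Analytic gradient of Theta over the interior replicas
#'
#' Endpoints are fixed, so the gradient is taken with respect to
#' `x_1 .. x_{P-1}` only. Uses potential gradients only.
#'
#' @inheritParams theta_objective
#' @return a `(P-1) x dim` matrix of derivatives.
#' @export
theta_gradient <- function(path, pot, w) {
  stopifnot(inherits(w, "action_weights"))
  dt <- path_dt(path)
  P <- n_slices(path)
  d <- path_displacements(path)           # P x dim
  g <- path_gradients(path, pot)          # (P+1) x dim
  idx <- 2:P                              # interior replica rows
  # d S_cl / d x_k = (d_{k-1} - d_k)/dt - dt * grad V(x_k)   (interior k)
  gs <- (d[idx - 1L, , drop = FALSE] - d[idx, , drop = FALSE]) / dt -
    dt * g[idx, , drop = FALSE]
  out <- w$mu_A * gs
  if (w$mu_E > 0) {
    e <- slice_energies(path, pot) - w$E_target   # length P
    # d E_k / d x_k = -d_k/dt^2 + grad V(x_k);  d E_{k-1} / d x_k = d_{k-1}/dt^2
    pen <- 2 * e[idx] * (-d[idx, , drop = FALSE] / dt^2 + g[idx, , drop = FALSE]) +
      2 * e[idx - 1L] * d[idx - 1L, , drop = FALSE] / dt^2
    out <- out + w$mu_E * pen
  }
  out
}

#' Relative path weight from two action values
#'
#' The relative probability of observing a pathway with Onsager-Machlup
#' action `S1` against one with action `S2` is
#' `exp(-(S1 - S2) / (c * kB * T))`. The package's action normalization
#' corresponds to `c = 1`; the constant only rescales weights and never
#' changes the rank order of pathways.
#'
#' @param S1,S2 action values.
#' @param th [thermo_params()].
#' @param c positive scale constant of the exponential.
#' @return the relative weight of pathway 1 against pathway 2.
#' @export
path_probability_ratio <- function(S1, S2, th, c = 1) {
  stopifnot(is.finite(S1), is.finite(S2), c > 0)
  exp(-(S1 - S2) / (c * th$kB * th$temperature))
}
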