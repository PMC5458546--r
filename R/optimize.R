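#' Local optimization settings
#'
#' @param grad_tol RMS-per-free-variable gradient tolerance declaring
#'   convergence.
#' @param max_iter iteration cap for the quasi-Newton optimizer.
#' @param step_init initial step scale of the gradient-descent fallback.
#' @param record_history record the Theta value of every accepted iterate.
#' @return a list of class `"local_opt_settings"`.
#' @export
local_opt_settings <- function(grad_tol = 1e-6, max_iter = 2000,
                               step_init = 0.1, record_history = FALSE) {
  stopifnot(grad_tol > 0, max_iter >= 1, step_init > 0)
  structure(list(grad_tol = grad_tol, max_iter = max_iter,
                 step_init = step_init, record_history = record_history),
            class = "local_opt_settings")
}

#' Locally optimize a pathway by minimizing Theta
#'
#' Limited-memory quasi-Newton (L-BFGS-B) minimization of
#' [theta_objective()] over the interior replicas, endpoints held fixed,
#' using the analytic [theta_gradient()]. If the quasi-Newton run fails
#' (non-finite objective during its line search), a backtracking
#' gradient-descent fallback continues from the best point seen. The
#' returned pathway always has the same endpoints as the input and a Theta
#' value no larger than the input's.
#'
#' @param path a [pathway()]; degenerate inputs (coincident neighbouring
#'   replicas, e.g. raw crossover products) are legal.
#' @param pot a potential.
#' @param w [action_weights()].
#' @param s [local_opt_settings()].
#' @return a list with `path` (optimized pathway), `theta`, `converged`
#'   (TRUE iff the RMS gradient met `grad_tol`), `n_evals` (objective
#'   evaluations) and, when requested, `history` of Theta values.
#' @export
minimize_theta <- function(path, pot, w, s = local_opt_settings()) {
  stopifnot(inherits(path, "pathway"), inherits(s, "local_opt_settings"))
  P <- n_slices(path)
  nd <- ncol(path)
  nfree <- (P - 1L) * nd
  shape <- function(v) matrix(v, nrow = P - 1L, ncol = nd)

  env <- new.env(parent = emptyenv())
  env$n_evals <- 0L

  # fused objective: Theta and its interior gradient in one pass over the
  # replica matrix; algebra identical to theta_objective / theta_gradient
  tor <- path_kind(path) == "torsion"
  reps0 <- unclass(path)
  dt <- path_dt(path)
  core <- function(v) {
    env$n_evals <- env$n_evals + 1L
    reps <- reps0
    reps[2:P, ] <- shape(v)
    d <- diff(reps)
    if (tor) d <- wrap_angle(d)
    vv <- evaluate_energy(pot, reps)
    g <- evaluate_gradient(pot, reps)
    if (!is.matrix(g)) g <- matrix(g, nrow = P + 1L)
    if (any(!is.finite(vv)) || any(!is.finite(g))) return(NULL)
    wts <- c(0.5, rep(1, P - 1L), 0.5)
    s_cl <- sum(d^2) / (2 * dt) - dt * sum(wts * vv)
    idx <- 2:P
    grad <- w$mu_A * ((d[idx - 1L, , drop = FALSE] - d[idx, , drop = FALSE]) /
                        dt - dt * g[idx, , drop = FALSE])
    val <- w$mu_A * s_cl
    if (w$mu_E > 0) {
      e <- rowSums(d^2) / (2 * dt^2) + vv[seq_len(P)] - w$E_target
      val <- val + w$mu_E * sum(e^2)
      grad <- grad + w$mu_E *
        (2 * e[idx] * (-d[idx, , drop = FALSE] / dt^2 +
                         g[idx, , drop = FALSE]) +
           2 * e[idx - 1L] * d[idx - 1L, , drop = FALSE] / dt^2)
    }
    list(val = val, grad = as.numeric(grad))
  }
  cached <- function(v) {
    if (!is.null(env$last_v) && identical(v, env$last_v)) return(env$last)
    out <- core(v)
    env$last_v <- v
    env$last <- out
    if (!is.null(out) && is.finite(out$val) && out$val < env$best_val) {
      env$best_val <- out$val
      env$best_par <- v
      if (s$record_history) env$history <- c(env$history, out$val)
    }
    out
  }

  start <- as.numeric(path_interior(path))
  env$best_par <- start
  env$best_val <- Inf
  first <- cached(start)
  if (is.null(first))
    stop("non-finite Theta at the starting pathway", call. = FALSE)
  if (s$record_history) env$history <- env$best_val

  fn <- function(v) {
    out <- cached(v)
    if (is.null(out) || !is.finite(out$val)) .Machine$double.xmax else out$val
  }
  gr <- function(v) {
    out <- cached(v)
    if (is.null(out) || any(!is.finite(out$grad))) rep(0, nfree) else out$grad
  }

  ok <- tryCatch({
    stats::optim(env$best_par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = s$max_iter, factr = 1e6, pgtol = 0))
    TRUE
  }, error = function(e) FALSE)

  grad_rms <- function(v) {
    out <- cached(v)
    if (is.null(out)) Inf else sqrt(mean(out$grad^2))
  }

  if (!ok || !is.finite(env$best_val) || grad_rms(env$best_par) > s$grad_tol) {
    # backtracking gradient descent from the best point seen
    v <- env$best_par
    step <- s$step_init
    for (i in seq_len(s$max_iter)) {
      out <- cached(v)
      if (is.null(out) || any(!is.finite(out$grad))) break
      if (sqrt(mean(out$grad^2)) <= s$grad_tol) break
      g <- out$grad
      repeat {
        cand <- v - step * g
        val <- fn(cand)
        if (val < env$best_val + 1e-15 || step < 1e-14) break
        step <- step / 2
      }
      if (step < 1e-14) break
      v <- env$best_par
      step <- min(step * 2, 1e3)
    }
  }

  out_path <- set_interior(path, shape(env$best_par))
  rms <- grad_rms(env$best_par)
  list(path = out_path,
       theta = env$best_val,
       converged = is.finite(rms) && rms <= s$grad_tol,
       n_evals = env$n_evals,
       history = env$history)
}
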