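#' Settings of the overdamped Langevin simulator
#'
#' @param dt_sim integrator time step (ps). The Euler-Maruyama update is
#'   stable for `dt_sim < 2 * gamma / max_curvature`; the shipped 2D surfaces
#'   have curvatures below ~40 kcal/mol per unit length squared, so the
#'   default is comfortably stable at `gamma = 1` ps^-1.
#' @param n_steps number of integration steps.
#' @param stride record every `stride`-th configuration.
#' @param gamma collision frequency (ps^-1).
#' @param temperature temperature (K).
#' @param kB Boltzmann constant.
#' @return a list of class `"ld_settings"`.
#' @export
ld_settings <- function(dt_sim = 2e-3, n_steps = 10000, stride = 1,
                        gamma = 1.0, temperature = 350, kB = 0.0019872) {
  stopifnot(dt_sim > 0, n_steps >= 1, stride >= 1, gamma > 0, temperature >= 0)
  structure(list(dt_sim = dt_sim, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), gamma = gamma,
                 temperature = temperature, kB = kB),
            class = "ld_settings")
}

#' Overdamped Langevin (Brownian dynamics) trajectories
#'
#' Euler-Maruyama integration of `gamma * dx = -grad V dt + R` with Gaussian
#' noise of per-coordinate variance `2 kB T dt / gamma` per step (unit
#' masses). Several independent walkers are propagated simultaneously when
#' `x0` is a matrix with one row per walker. Torsion coordinates are wrapped
#' to (-pi, pi] at every step.
#'
#' @param pot a potential.
#' @param x0 start configuration (vector) or matrix of start configurations
#'   (walkers in rows).
#' @param s [ld_settings()].
#' @return an object of class `"ld_trajectory"`: a list with `times`
#'   (recorded times, ps), `coords` (array `frames x walkers x dim`),
#'   `kind`, and the settings.
#' @export
simulate_overdamped <- function(pot, x0, s) {
  stopifnot(inherits(s, "ld_settings"))
  x <- if (is.matrix(x0)) x0 else matrix(x0, nrow = 1L)
  if (ncol(x) != pot$dim) stop("x0 does not match potential dim", call. = FALSE)
  if (!all(is.finite(x))) stop("x0 must be finite", call. = FALSE)
  tor <- pot$coord_kind == "torsion"
  nw <- nrow(x); nd <- ncol(x)
  nrec <- s$n_steps %/% s$stride
  coords <- array(NA_real_, c(nrec + 1L, nw, nd))
  coords[1L, , ] <- x
  noise_sd <- sqrt(2 * s$kB * s$temperature * s$dt_sim / s$gamma)
  drift <- s$dt_sim / s$gamma
  rec <- 1L
  for (step in seq_len(s$n_steps)) {
    g <- evaluate_gradient(pot, x)
    if (!is.matrix(g)) g <- matrix(g, nrow = nw)
    x <- x - drift * g
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(nw * nd, sd = noise_sd),
                                      nw, nd)
    if (tor) x <- wrap_angle(x)
    if (any(!is.finite(x)))
      stop(sprintf("trajectory diverged at step %d", step), call. = FALSE)
    if (step %% s$stride == 0L) {
      rec <- rec + 1L
      coords[rec, , ] <- x
    }
  }
  structure(list(times = seq(0L, nrec) * s$stride * s$dt_sim,
                 coords = coords, kind = pot$coord_kind, settings = s),
            class = "ld_trajectory")
}

#' Basin membership specification
#'
#' A basin is a ball (Euclidean, or minimum-image angular Euclidean for
#' torsions) around a center; the *core* is a concentric smaller ball used
#' for transition counting, so that boundary recrossings do not produce
#' spurious events.
#'
#' @param label basin name.
#' @param center basin center coordinates.
#' @param radius basin radius.
#' @param core_radius core radius (<= radius); default half the radius.
#' @param kind coordinate convention.
#' @return a list of class `"basin_spec"`.
#' @export
basin_spec <- function(label, center, radius, core_radius = radius / 2,
                       kind = c("cartesian", "torsion")) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, core_radius > 0, core_radius <= radius)
  structure(list(label = label, center = as.numeric(center), radius = radius,
                 core_radius = core_radius, kind = kind),
            class = "basin_spec")
}

in_core <- function(b, m) {
  d <- sweep(m, 2L, b$center)
  if (b$kind == "torsion") d <- wrap_angle(d)
  sqrt(rowSums(d^2)) <= b$core_radius
}

#' Detect source-to-target transitions in a trajectory
#'
#' Events are counted by the last-exit / first-entry convention: a
#' transition starts at the last recorded frame inside the source core
#' before the trajectory first reaches the target core, and ends at that
#' first target-core frame. Dwell time inside the cores is thereby excluded
#' from the transit time. Each walker of an ensemble trajectory is scanned
#' independently.
#'
#' @param traj an `"ld_trajectory"`.
#' @param source,target disjoint-core [basin_spec()]s.
#' @return a data.frame of class `"transition_records"` with columns
#'   `walker`, `t_exit`, `t_entry`, `transit_time`, `i_exit`, `i_entry`
#'   (frame indices); the trajectory is kept as an attribute so segments can
#'   be extracted with [transition_segment()].
#' @export
detect_transitions <- function(traj, source, target) {
  dcore <- sqrt(sum(coord_diff(source$center, target$center,
                               source$kind)^2))
  if (dcore <= source$core_radius + target$core_radius)
    stop("source and target cores must be disjoint", call. = FALSE)
  out <- list()
  nw <- dim(traj$coords)[2L]
  for (wk in seq_len(nw)) {
    m <- traj$coords[, wk, , drop = FALSE]
    dim(m) <- dim(traj$coords)[c(1L, 3L)]
    in_s <- in_core(source, m)
    in_t <- in_core(target, m)
    last_exit <- NA_integer_
    for (i in seq_along(in_s)) {
      if (in_s[i]) {
        last_exit <- i
      } else if (in_t[i]) {
        if (!is.na(last_exit)) {
          out[[length(out) + 1L]] <-
            data.frame(walker = wk,
                       t_exit = traj$times[last_exit],
                       t_entry = traj$times[i],
                       transit_time = traj$times[i] - traj$times[last_exit],
                       i_exit = last_exit, i_entry = i)
          last_exit <- NA_integer_
        }
      }
    }
  }
  recs <- if (length(out)) do.call(rbind, out) else
    data.frame(walker = integer(), t_exit = numeric(), t_entry = numeric(),
               transit_time = numeric(), i_exit = integer(),
               i_entry = integer())
  structure(recs, traj = traj, class = c("transition_records", "data.frame"))
}

#' Extract the trajectory segment of one transition record
#'
#' @param records output of [detect_transitions()].
#' @param k record number.
#' @return the transition segment as a [pathway()].
#' @export
transition_segment <- function(records, k) {
  traj <- attr(records, "traj")
  r <- records[k, ]
  m <- traj$coords[r$i_exit:r$i_entry, r$walker, , drop = FALSE]
  dim(m) <- c(r$i_entry - r$i_exit + 1L, dim(traj$coords)[3L])
  pathway(m, dt = traj$times[2L] - traj$times[1L], kind = traj$kind)
}

#' Rank-order comparison of simulated transitions against a pathway bank
#'
#' Each detected transition segment is assigned to its nearest reference
#' pathway by [assign_nearest_reference()]; the per-reference counts give a
#' frequency ranking which is compared against the ranking by
#' Onsager-Machlup action (lower action = expected higher frequency) via
#' Kendall's tau.
#'
#' @param refs list of reference pathways (e.g. class representatives of a
#'   bank).
#' @param ref_som Onsager-Machlup actions of the references.
#' @param records transitions from [detect_transitions()].
#' @return a list of class `"rank_order_report"` with `counts`,
#'   `rank_by_count`, `rank_by_som`, `kendall_tau`, `assignments`,
#'   `transit_times` (list per reference), and `insufficient_sampling`.
#' @export
rank_order_comparison <- function(refs, ref_som, records) {
  stopifnot(length(refs) == length(ref_som))
  n <- nrow(records)
  if (n == 0L) {
    return(structure(list(counts = rep(0L, length(refs)),
                          rank_by_count = integer(), rank_by_som = order(ref_som),
                          kendall_tau = NA_real_, assignments = integer(),
                          transit_times = vector("list", length(refs)),
                          insufficient_sampling = TRUE),
                     class = "rank_order_report"))
  }
  assignments <- integer(n)
  for (k in seq_len(n)) {
    seg <- transition_segment(records, k)
    assignments[k] <- assign_nearest_reference(seg, refs)$index
  }
  counts <- tabulate(assignments, nbins = length(refs))
  tt <- lapply(seq_along(refs),
               function(i) records$transit_time[assignments == i])
  tau <- if (length(refs) >= 2L)
    stats::cor(-counts, ref_som, method = "kendall") else NA_real_
  structure(list(counts = counts,
                 rank_by_count = order(-counts),
                 rank_by_som = order(ref_som),
                 kendall_tau = tau,
                 assignments = assignments,
                 transit_times = tt,
                 insufficient_sampling = n < 10L),
            class = "rank_order_report")
}

#' @export
print.rank_order_report <- function(x, ...) {
  cat("Rank-order comparison (simulation counts vs S_OM):\n")
  print(data.frame(ref = seq_along(x$counts), count = x$counts,
                   rank_by_count = match(seq_along(x$counts), x$rank_by_count),
                   rank_by_som = match(seq_along(x$counts), x$rank_by_som)),
        row.names = FALSE)
  cat(sprintf("Kendall tau = %.3f%s\n", x$kendall_tau,
              if (isTRUE(x$insufficient_sampling))
                "  (insufficient sampling)" else ""))
  invisible(x)
}

#' Minimum-action profile over total transition times
#'
#' Runs [action_csa()] for each total time in `t_grid` (the number of slices
#' is adjusted as `P = t / dt`, keeping the time step fixed), classifies the
#' final bank with a caller-supplied function, and reports the lowest
#' Onsager-Machlup action per pathway class at each time. The per-class
#' argmin over `t` is the predicted characteristic transition time of that
#' class.
#'
#' @param pot,ep,th,w,cfg,opt as in [action_csa()].
#' @param t_grid vector of total transition times (ps).
#' @param dt time step (ps).
#' @param classify function mapping a pathway to a class label; default: one
#'   class for everything.
#' @param seed RNG seed (one independent stream per grid point).
#' @return a data.frame with columns `t`, `class`, `min_som`.
#' @export
som_vs_time_profile <- function(pot, ep, t_grid, dt, th, w,
                                cfg = csa_config(),
                                opt = local_opt_settings(grad_tol = 1e-2,
                                                         max_iter = 300),
                                classify = function(p) "all", seed = 1L) {
  out <- list()
  for (i in seq_along(t_grid)) {
    P <- max(2L, as.integer(round(t_grid[i] / dt)))
    fit <- action_csa(pot, ep, P, dt, th, w, cfg, opt,
                      seed = seed + i - 1L)
    cls <- vapply(fit$bank$paths, classify, character(1L))
    for (cl in unique(cls)) {
      out[[length(out) + 1L]] <-
        data.frame(t = P * dt, class = cl,
                   min_som = min(fit$bank$som[cls == cl]))
    }
  }
  if (!length(out))
    return(data.frame(t = numeric(), class = character(),
                      min_som = numeric()))
  do.call(rbind, out)
}
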