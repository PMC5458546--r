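# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: finite differences instead of analytic
# derivatives, exhaustive enumeration instead of dynamic programming, naive
# re-summation instead of vectorized formulas.

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    a <- x; b <- x
    a[i] <- a[i] + h; b[i] <- b[i] - h
    (f(a) - f(b)) / (2 * h)
  }, numeric(1L))
}

# finite-difference Hessian from the analytic gradient
num_hess_from_grad <- function(g, x, h = 1e-5) {
  d <- length(x)
  m <- matrix(NA_real_, d, d)
  for (i in seq_len(d)) {
    a <- x; b <- x
    a[i] <- a[i] + h; b[i] <- b[i] - h
    m[i, ] <- (g(a) - g(b)) / (2 * h)
  }
  (m + t(m)) / 2
}

# exhaustive discrete Frechet distance: minimax over all monotone couplings,
# enumerated recursively
brute_frechet <- function(A, B, dist_fun) {
  n <- nrow(A); m <- nrow(B)
  rec <- function(i, j) {
    d <- dist_fun(A[i, ], B[j, ])
    if (i == 1L && j == 1L) return(d)
    cands <- c(
      if (i > 1L) rec(i - 1L, j),
      if (j > 1L) rec(i, j - 1L),
      if (i > 1L && j > 1L) rec(i - 1L, j - 1L))
    max(d, min(cands))
  }
  rec(n, m)
}

# iterated dense-grid coordinate descent for Theta over <= 3 interior
# replicas of a 1D problem; grid shrinks geometrically around the incumbent
grid_minimize_theta <- function(path, pot, w, n_grid = 201, levels = 40) {
  reps <- unclass(path)
  P <- nrow(reps) - 1L
  width <- max(abs(reps)) + 2
  obj <- function(r) theta_objective(
    pathway(matrix(r, ncol = 1L), dt = attr(path, "dt")), pot, w)
  best <- obj(reps)
  for (lev in seq_len(levels)) {
    # cyclic coordinate descent until stable at this grid resolution
    repeat {
      moved <- FALSE
      for (k in 2:P) {
        grid <- seq(reps[k] - width, reps[k] + width, length.out = n_grid)
        vals <- vapply(grid, function(v) {
          r <- reps; r[k] <- v; obj(r)
        }, numeric(1L))
        j <- which.min(vals)
        if (vals[j] < best - 1e-300 && grid[j] != reps[k]) {
          reps[k] <- grid[j]
          best <- vals[j]
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    width <- width * 0.5
  }
  list(reps = reps, theta = best)
}

# independent re-implementation of the two-branch bank-update rule
replay_update <- function(paths, soms, dcut, cand_path, cand_som) {
  d <- vapply(paths, function(p) frechet_distance(p, cand_path)$value,
              numeric(1L))
  i <- which.min(d)
  if (d[i] <= dcut) {
    if (cand_som < soms[i]) {
      paths[[i]] <- cand_path; soms[i] <- cand_som
    }
  } else {
    wst <- which.max(soms)
    if (cand_som < soms[wst]) {
      paths[[wst]] <- cand_path; soms[wst] <- cand_som
    }
  }
  list(paths = paths, soms = soms)
}

# brute-force enumeration of monotone rotamer-lattice pathways by recursive
# search over the 3^n-state graph (independent of the package's enumerator)
brute_enum <- function(n, forbid_clash = TRUE) {
  ok <- function(s) !forbid_clash || n < 2L || all(abs(diff(s)) != 2L)
  res <- list()
  rec <- function(state, ev) {
    if (all(state == 2L)) {
      res[[length(res) + 1L]] <<- ev
      return(invisible())
    }
    for (i in seq_len(n)) if (state[i] < 2L) {
      ns <- state; ns[i] <- ns[i] + 1L
      if (ok(ns)) rec(ns, c(ev, i))
    }
  }
  rec(rep(0L, n), integer())
  res
}

# orbit computation over event strings under the declared symmetry group,
# written independently of the package's union-find
brute_orbits <- function(event_lists, n) {
  key <- function(v) paste(v, collapse = ".")
  orbit <- function(v) {
    sort(unique(c(key(v), key(rev(v)), key(n + 1L - v), key(rev(n + 1L - v)))))
  }
  unique(lapply(event_lists, orbit))
}

# geometric channel label of a two-channel-surface pathway
channel_of <- function(p) {
  m <- unclass(p)
  if (m[which.min(abs(m[, 1L])), 2L] >= 0) "upper" else "lower"
}

# straight interpolation with Gaussian interior roughness, for fixed-path
# functional tests
rough_path <- function(pot, P = 24, dt = 0.02, seed = 1, amp = 0.1,
                       from = NULL, to = NULL) {
  set.seed(seed)
  d <- pot$dim
  if (is.null(from)) from <- rep(-0.8, d)
  if (is.null(to)) to <- rep(0.8, d)
  p <- interpolate_path(from, to, P, dt, kind = pot$coord_kind)
  set_interior(p, path_interior(p) + amp * matrix(stats::rnorm((P - 1) * d),
                                                  P - 1, d))
}

# shared small objects
tc_pot <- two_channel_2d()
tc_ep <- two_channel_endpoints(tc_pot)
default_th <- thermo_params()
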