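th <- thermo_params()

small_fit <- function(seed = 1, bank = 6, rounds = 6) {
  pot <- two_channel_2d()
  E <- compute_reference_energy(pot, tc_ep$x_initial, 5, th)
  w <- action_weights(-1, 1, E)
  cfg <- csa_config(bank_size = bank, n_seeds_per_round = 3,
                    n_trials_per_seed = 2, init_scale = 1.2,
                    mutation_magnitude = 0.5, max_rounds = rounds,
                    patience = 3)
  action_csa(pot, tc_ep, P = 24, dt = 0.0625, th, w, cfg, seed = seed)
}

test_that("initial pathways interpolate, perturb mean-zero, and respect scale", {
  set.seed(51)
  base <- interpolate_path(tc_ep$x_initial, tc_ep$x_final, 100, 0.01)
  # zero scale: exact straight interpolation
  p0 <- generate_initial_paths(3, tc_ep, P = 100, dt = 0.01, scale = 0)
  for (p in p0) expect_equal(unclass(p), unclass(base))
  # mean-zero bridge: average interior displacement within 3 standard errors
  ps <- generate_initial_paths(200, tc_ep, P = 100, dt = 0.01, scale = 0.5)
  devs <- vapply(ps, function(p)
    mean(path_interior(p) - path_interior(base)), numeric(1L))
  expect_lt(abs(mean(devs)), 3 * stats::sd(devs) / sqrt(length(devs)))
  # equal endpoints: replicas stay in a scale-sized neighbourhood
  pot1 <- harmonic_well(kappa = 1, dim = 2)
  epe <- endpoint_pair(pot1, c(0, 0), c(0, 0), grad_tol = 1e-8)
  pe <- generate_initial_paths(50, epe, P = 30, dt = 0.01, scale = 0.2)
  maxdev <- max(vapply(pe, function(p) max(abs(unclass(p))), numeric(1L)))
  expect_lt(maxdev, 5 * 0.2)
})

test_that("torsional initial ensembles populate both winding classes", {
  pot <- torsional_chain(1)
  ep <- endpoint_pair(pot, -pi / 3, pi / 3, grad_tol = 1e-8)
  set.seed(52)
  ps <- generate_initial_paths(200, ep, P = 30, dt = 0.1, scale = 0.3,
                               kind = "torsion")
  winding <- vapply(ps, function(p) sum(wrap_angle(diff(unclass(p)))),
                    numeric(1L))
  short <- sum(abs(winding - 2 * pi / 3) < 1)
  long <- sum(abs(winding + 4 * pi / 3) < 1)
  expect_equal(short + long, 200L)
  expect_gt(short, 60L)    # roughly half each
  expect_gt(long, 60L)
})

test_that("crossover swaps exactly one contiguous interior window", {
  set.seed(53)
  seed_p <- interpolate_path(c(0, 0), c(1, 0), P = 12, dt = 0.1)
  partner <- set_interior(seed_p, path_interior(seed_p) + 1)
  # identical partner: offspring equals the seed
  expect_equal(unclass(crossover(seed_p, seed_p)), unclass(seed_p))
  for (k in 1:50) {
    off <- crossover(seed_p, partner)
    m <- unclass(off)
    from_partner <- which(m[, 1L] != unclass(seed_p)[, 1L] |
                            m[, 2L] != unclass(seed_p)[, 2L])
    expect_gte(length(from_partner), 1L)
    expect_true(all(diff(from_partner) == 1L))          # contiguous
    expect_true(all(from_partner >= 2L & from_partner <= 12L))
    expect_equal(m[from_partner, ], unclass(partner)[from_partner, ])
  }
  expect_error(crossover(pathway(matrix(0, 3, 2), dt = 1),
                         pathway(matrix(0, 3, 2), dt = 1)), "interior")
})

test_that("crossover windows cover every interior position", {
  set.seed(54)
  P <- 8L
  seed_p <- interpolate_path(0, 1, P = P, dt = 0.1)
  partner <- set_interior(seed_p, path_interior(seed_p) + 1)
  seen <- matrix(FALSE, P - 1L, P - 1L)  # (a, b) windows over replicas 1..P-1
  for (k in 1:1000) {
    off <- crossover(seed_p, partner)
    idx <- which(unclass(off)[, 1L] != unclass(seed_p)[, 1L]) - 1L
    seen[min(idx), max(idx)] <- TRUE
  }
  expect_true(all(seen[upper.tri(seen, diag = TRUE)]))
})

test_that("mutation respects the degree-of-freedom bound and covers positions", {
  set.seed(55)
  p <- interpolate_path(c(0, 0), c(1, 0), P = 21, dt = 0.1)
  cfg <- csa_config(bank_size = 4, mutation_dof_fraction = 0.05,
                    mutation_magnitude = 0.1)
  bound <- ceiling(0.05 * 20 * 2)
  touched <- rep(FALSE, 40L)
  for (k in 1:1000) {
    m <- mutate(p, cfg)
    changed <- which(path_interior(m) != path_interior(p))
    expect_gte(length(changed), 1L)
    expect_lte(length(changed), bound)
    touched[changed] <- TRUE
  }
  expect_true(all(touched))
})

test_that("bank updates replay an independent implementation of the two-branch rule", {
  set.seed(56)
  mk <- function() {
    m <- matrix(stats::rnorm(12), 6, 2)
    m[1L, ] <- c(-1, 0); m[6L, ] <- c(1, 0)
    pathway(m, dt = 0.1)
  }
  paths <- replicate(5, mk(), simplify = FALSE)
  soms <- stats::rnorm(5, mean = 10)
  bank <- structure(list(paths = paths, som = soms,
                         prov = rep("first_bank", 5), dcut_current = 1.2),
                    class = "pathway_bank")
  ref_paths <- paths; ref_soms <- soms
  reasons <- character(500)
  for (k in 1:500) {
    cand <- mk()
    csom <- stats::rnorm(1, mean = 10)
    upd <- update_bank(bank, cand, csom)
    bank <- upd$bank
    reasons[k] <- upd$reason
    ref <- replay_update(ref_paths, ref_soms, 1.2, cand, csom)
    ref_paths <- ref$paths; ref_soms <- ref$soms
    expect_equal(bank$som, ref_soms)
    expect_equal(length(bank$paths), 5L)
  }
  for (i in seq_along(bank$paths))
    expect_equal(unclass(bank$paths[[i]]), unclass(ref_paths[[i]]))
  expect_true(all(reasons %in% c("replaced_neighbor",
                                 "rejected_neighbor_better",
                                 "replaced_worst", "rejected_not_better")))
  expect_gt(length(unique(reasons)), 2L)
})

test_that("ties keep the incumbent and far-but-worse candidates are rejected", {
  p <- interpolate_path(c(0, 0), c(1, 0), P = 5, dt = 0.1)
  bank <- structure(list(paths = list(p), som = 3, prov = "first_bank",
                         dcut_current = 0.5),
                    class = "pathway_bank")
  same <- update_bank(bank, p, 3)
  expect_false(same$admitted)
  expect_equal(same$reason, "rejected_neighbor_better")
  far <- pathway(rbind(unclass(p)[1L, ], unclass(p)[2:5, ] + 5,
                       unclass(p)[6L, ]), dt = 0.1)
  worse <- update_bank(bank, far, 9)
  expect_false(worse$admitted)
  expect_equal(worse$reason, "rejected_not_better")
})

test_that("the diversity cutoff anneals geometrically and then stays constant", {
  cfg <- csa_config(bank_size = 4, dcut_init_factor = 0.5,
                    dcut_final_factor = 0.1, dcut_rounds = 6)
  d0 <- 2
  expect_equal(anneal_dcut(0, cfg, d0), 1.0)
  expect_equal(anneal_dcut(6, cfg, d0), 0.2)
  expect_equal(anneal_dcut(20, cfg, d0), 0.2)
  vals <- vapply(0:6, anneal_dcut, numeric(1L), cfg = cfg, d_avg_init = d0)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[4L] / vals[3L], vals[5L] / vals[4L], tolerance = 1e-10)
})

test_that("identical seeds reproduce the whole run and the first bank is immutable", {
  f1 <- small_fit(seed = 7)
  f2 <- small_fit(seed = 7)
  expect_equal(f1$bank$som, f2$bank$som)
  expect_equal(f1$report, f2$report)
  for (i in seq_along(f1$bank$paths))
    expect_identical(unclass(f1$bank$paths[[i]]), unclass(f2$bank$paths[[i]]))
  # first bank of a run equals the first bank recomputed in isolation
  set.seed(f1$seed)
  init <- generate_initial_paths(f1$cfg$n_initial, tc_ep, f1$P, f1$dt,
                                 scale = f1$cfg$init_scale)
  redo <- lapply(init, function(p)
    minimize_theta(p, f1$pot, f1$w,
                   local_opt_settings(grad_tol = 1e-2, max_iter = 300))$path)
  for (i in seq_along(redo))
    expect_identical(unclass(f1$first_bank$paths[[i]]), unclass(redo[[i]]))
})

test_that("bank size stays constant and best action is non-increasing", {
  fit <- small_fit(seed = 9, rounds = 8)
  expect_equal(length(fit$bank$paths), 6L)
  expect_true(all(diff(fit$report$best_som) <= 1e-10))
  expect_true(all(is.finite(fit$bank$som)))
})

test_that("a single-member bank degenerates to elitist hill descent", {
  pot <- two_channel_2d()
  E <- compute_reference_energy(pot, tc_ep$x_initial, 5, th)
  w <- action_weights(-1, 1, E)
  cfg <- csa_config(bank_size = 1, n_seeds_per_round = 1,
                    n_trials_per_seed = 2, crossover_fraction = 0,
                    init_scale = 1, mutation_magnitude = 0.5,
                    max_rounds = 6, patience = 3)
  fit <- action_csa(pot, tc_ep, P = 16, dt = 0.09, th, w, cfg, seed = 3)
  expect_equal(length(fit$bank$paths), 1L)
  expect_true(all(diff(fit$report$best_som) <= 1e-10))
})

test_that("the search on the two-channel surface keeps both channels and ranks them", {
  fit <- small_fit(seed = 5, bank = 10, rounds = 10)
  cls <- vapply(fit$bank$paths, channel_of, character(1L))
  expect_setequal(unique(cls), c("lower", "upper"))
  # the lowest-action member transits the lower channel, verified by which
  # saddle neighbourhood it visits
  best <- best_path(fit)
  sp <- stationary_points(fit$pot, c(-2.2, -2.2), c(2.2, 2.2), n_grid = 13)
  sads <- sp[sp$index == 1L, ]
  low_saddle <- unlist(sads[which.min(sads$energy), c("x", "y")])
  m <- unclass(best)
  dmin <- min(sqrt((m[, 1L] - low_saddle[1L])^2 +
                     (m[, 2L] - low_saddle[2L])^2))
  expect_lt(dmin, 0.5)
  # exhaustive cross-check: locally optimized per-channel paths have the
  # same rank order as the bank classes
  expect_lt(min(fit$bank$som[cls == "lower"]),
            min(fit$bank$som[cls == "upper"]))
})
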