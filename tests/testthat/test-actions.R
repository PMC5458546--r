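th <- thermo_params()

test_that("discrete OM action matches fine quadrature of the symmetric formula", {
  # free particle: flat potential, straight uniform path
  flat <- harmonic_well(kappa = 1e-14, dim = 2)
  p <- interpolate_path(c(-1, 0), c(1, 1), P = 30, dt = 0.01)
  s6 <- om_action(p, flat, th)
  s5 <- om_action_continuous(p, flat, th, refine = 100,
                             include_entropic = FALSE)
  expect_lt(abs(s6 - s5) / abs(s5), 1e-4)
  # analytic value of the kinetic-only action: gamma * L^2 / (4 t)
  L2 <- sum((c(1, 1) - c(-1, 0))^2)
  expect_equal(s6, th$gamma * L2 / (4 * 0.3), tolerance = 1e-10)
})

test_that("OM discretization error decays as O(dt^2) under refinement", {
  for (pot in list(harmonic_well(kappa = 3, dim = 2), two_channel_2d())) {
    # a fixed smooth path, re-discretized at P, 2P, 4P
    t_total <- 0.4
    curve <- function(s) rbind(c(-1 + 2 * s, 0.8 * sin(pi * s)))
    errs <- vapply(c(16L, 32L, 64L), function(P) {
      s <- seq(0, 1, length.out = P + 1L)
      p <- pathway(t(vapply(s, function(si) curve(si)[1L, ], numeric(2L))),
                   dt = t_total / P)
      abs(om_action(p, pot, th) -
            om_action_continuous(p, pot, th, refine = 64,
                                 include_entropic = FALSE))
    }, numeric(1L))
    # halving dt should cut the error by about 4; allow slack
    expect_gt(errs[1L] / errs[2L], 2.5)
    expect_gt(errs[2L] / errs[3L], 2.5)
  }
})

test_that("stationary path at a critical point has zero action", {
  pot <- harmonic_well(kappa = 2, dim = 2)
  p <- pathway(matrix(0, 11, 2), dt = 0.01)
  expect_equal(om_action(p, pot, th), 0)
  expect_equal(classical_action(p, pot), 0)
})

test_that("entropic term of the continuous action has its closed form for a harmonic well", {
  pot <- harmonic_well(kappa = c(2, 5), dim = 2)
  p <- rough_path(pot, P = 16, seed = 3)
  with_h <- om_action_continuous(p, pot, th, refine = 8)
  without <- om_action_continuous(p, pot, th, refine = 8,
                                  include_entropic = FALSE)
  t_total <- n_slices(p) * 0.02
  expect_equal(with_h - without,
               -th$kB * th$temperature / (2 * th$gamma) * (2 + 5) * t_total,
               tolerance = 1e-10)
  # flat potential: entropic term contributes nothing
  flat <- harmonic_well(kappa = 1e-14, dim = 2)
  expect_equal(om_action_continuous(p, flat, th, refine = 4),
               om_action_continuous(p, flat, th, refine = 4,
                                    include_entropic = FALSE),
               tolerance = 1e-12)
})

test_that("continuous-action quadrature is self-convergent in refine", {
  pot <- two_channel_2d()
  p <- rough_path(pot, P = 20, dt = 0.005, seed = 4, amp = 0.05,
                  from = tc_ep$x_initial, to = tc_ep$x_final)
  a1 <- om_action_continuous(p, pot, th, refine = 1)
  a100 <- om_action_continuous(p, pot, th, refine = 100)
  expect_lt(abs(a1 - a100) / abs(a100), 0.01)
})

test_that("classical action reproduces hand-evaluated sums and scaling laws", {
  flat <- harmonic_well(kappa = 1e-14, dim = 1)
  p <- pathway(matrix(c(0, 0.5, 1), 3, 1), dt = 1)
  # two slices, each dt * (0.5/1)^2 / 2
  expect_equal(classical_action(p, flat), 0.25, tolerance = 1e-12)
  # quadratic homogeneity of the kinetic term
  p2 <- pathway(2 * matrix(c(0, 0.5, 1), 3, 1), dt = 1)
  expect_equal(classical_action(p2, flat), 4 * classical_action(p, flat),
               tolerance = 1e-9)
  # identical replicas at zero potential
  expect_equal(classical_action(pathway(matrix(1, 5, 1), dt = 0.1), flat), 0,
               tolerance = 1e-12)
})

test_that("slice total energies use the documented forward-difference convention", {
  flat <- harmonic_well(kappa = 1e-14, dim = 1)
  p <- interpolate_path(0, 1, P = 4, dt = 0.2)     # uniform spacing 0.25
  for (j in 0:4)
    expect_equal(replica_total_energy(p, flat, j), 0.25^2 / (2 * 0.2^2),
                 tolerance = 1e-9)
  expect_error(replica_total_energy(p, flat, 5), "range")
  # stationary replica at a potential minimum
  pot <- harmonic_well(kappa = 3, dim = 1)
  expect_equal(replica_total_energy(pathway(matrix(0, 4, 1), dt = 0.1),
                                    pot, 2), 0)
})

test_that("slice energies are conserved along an exact harmonic trajectory", {
  # x(t) = cos(omega t), omega = sqrt(kappa), unit mass: E = kappa / 2
  kappa <- 4
  pot <- harmonic_well(kappa = kappa, dim = 1)
  errs <- vapply(c(40L, 80L), function(P) {
    tt <- seq(0, 1, length.out = P + 1L)
    p <- pathway(matrix(cos(sqrt(kappa) * tt), ncol = 1L), dt = 1 / P)
    e <- vapply(0:(P - 1L), function(j) replica_total_energy(p, pot, j),
                numeric(1L))
    max(abs(e - kappa / 2))
  }, numeric(1L))
  expect_lt(errs[2L], errs[1L])
  expect_gt(errs[1L] / errs[2L], 1.8)   # O(dt) bias halves, O(dt^2) quarters
})

test_that("Theta decouples and matches naive re-summation", {
  pot <- two_channel_2d()
  p <- rough_path(pot, P = 12, seed = 5, amp = 0.2,
                  from = tc_ep$x_initial, to = tc_ep$x_final)
  w0 <- action_weights(mu_A = -1, mu_E = 0)
  expect_equal(theta_objective(p, pot, w0), -classical_action(p, pot))
  # naive independent summation of the printed formula
  w <- action_weights(mu_A = -1, mu_E = 1, E_target = 2)
  P <- n_slices(p); dt <- path_dt(p)
  m <- unclass(p)
  kin <- pen <- 0
  scl <- 0
  for (j in seq_len(P)) {
    vj <- evaluate_energy(pot, m[j, ]); vj1 <- evaluate_energy(pot, m[j + 1L, ])
    d2 <- sum((m[j + 1L, ] - m[j, ])^2)
    scl <- scl + dt * (d2 / (2 * dt^2) - (vj + vj1) / 2)
    pen <- pen + (d2 / (2 * dt^2) + vj - 2)^2
  }
  expect_equal(theta_objective(p, pot, w), -scl + pen, tolerance = 1e-10)
})

test_that("Theta penalty vanishes for the exact trajectory as dt -> 0", {
  kappa <- 4
  pot <- harmonic_well(kappa = kappa, dim = 1)
  pen <- vapply(c(30L, 240L), function(P) {
    tt <- seq(0, 1, length.out = P + 1L)
    p <- pathway(matrix(cos(sqrt(kappa) * tt), ncol = 1L), dt = 1 / P)
    w <- action_weights(mu_A = 0, mu_E = 1, E_target = kappa / 2)
    theta_objective(p, pot, w)
  }, numeric(1L))
  expect_lt(pen[2L], pen[1L] / 4)
})

test_that("theta_gradient is the exact derivative of theta_objective", {
  set.seed(21)
  cases <- list(
    list(pot = harmonic_well(kappa = 2, dim = 2), amp = 0.3),
    list(pot = two_channel_2d(), amp = 0.2),
    list(pot = torsional_chain(2), amp = 0.3))
  for (cs in cases) {
    for (k in 1:7) {
      p <- rough_path(cs$pot, P = 8, seed = 100 + k, amp = cs$amp)
      w <- action_weights(mu_A = -1, mu_E = 1, E_target = 1.5)
      g <- as.numeric(theta_gradient(p, cs$pot, w))
      f <- function(v) theta_objective(
        set_interior(p, matrix(v, ncol = cs$pot$dim)), cs$pot, w)
      fd <- num_grad(f, as.numeric(path_interior(p)))
      expect_lt(max(abs(g - fd)) / max(abs(fd), 1), 1e-6)
    }
  }
})

test_that("kinetic-only gradient vanishes on the uniform straight path", {
  flat <- harmonic_well(kappa = 1e-14, dim = 2)
  p <- interpolate_path(c(0, 0), c(1, 2), P = 10, dt = 0.1)
  w <- action_weights(mu_A = 1, mu_E = 0)
  expect_lt(max(abs(theta_gradient(p, flat, w))), 1e-10)
})

test_that("path reversal shifts the OM action by exactly the potential difference", {
  # near-linear tilt: a wide harmonic well centered far away, so |grad V| is
  # nearly constant along the path and the kinetic and gradient-squared
  # terms are reversal-invariant; only DeltaV/2 flips sign
  pot <- harmonic_well(kappa = 1e-3, dim = 2, center = c(1000, 0))
  p <- interpolate_path(c(-1, 0), c(1, 0.5), P = 16, dt = 0.02)
  pr <- pathway(unclass(p)[17:1, ], dt = 0.02)
  dV <- evaluate_energy(pot, c(1, 0.5)) - evaluate_energy(pot, c(-1, 0))
  expect_equal(om_action(p, pot, th) - om_action(pr, pot, th), dV,
               tolerance = 1e-8)
})

test_that("the OM action is additive over sub-paths on a flat potential", {
  flat <- harmonic_well(kappa = 1e-14, dim = 2)
  set.seed(22)
  m <- apply(matrix(stats::rnorm(42), 21, 2), 2L, cumsum)
  p <- pathway(m, dt = 0.01)
  left <- pathway(m[1:11, ], dt = 0.01)
  right <- pathway(m[11:21, ], dt = 0.01)
  expect_equal(om_action(p, flat, th),
               om_action(left, flat, th) + om_action(right, flat, th),
               tolerance = 1e-10)
})

test_that("path weights are monotone and rank-invariant in the scale constant", {
  expect_equal(path_probability_ratio(3, 3, th), 1)
  expect_gt(path_probability_ratio(1, 2, th), 1)
  expect_lt(path_probability_ratio(2, 1, th), 1)
  soms <- c(5, 2, 9, 4.4)
  r1 <- vapply(soms, path_probability_ratio, numeric(1L), S2 = 0, th = th,
               c = 1)
  r2 <- vapply(soms, path_probability_ratio, numeric(1L), S2 = 0, th = th,
               c = 7)
  expect_equal(order(r1), order(r2))
})

test_that("non-finite potential values along a path name the offending replica", {
  bad <- harmonic_well(kappa = 1, dim = 1)
  class(bad) <- c("acsa_bad", class(bad))
  assign("evaluate_gradient.acsa_bad",
         function(pot, x) {
           m <- if (is.matrix(x)) x else matrix(x, 1L)
           g <- m
           g[m > 0.5] <- NaN
           if (is.matrix(x)) g else g[1L, ]
         }, envir = globalenv())
  on.exit(rm("evaluate_gradient.acsa_bad", envir = globalenv()))
  p <- interpolate_path(0, 1, P = 4, dt = 0.1)
  expect_error(om_action(p, bad, th), "replica")
})
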