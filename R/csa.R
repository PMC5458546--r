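#' Configuration of the conformational-space-annealing search
#'
#' @param bank_size number of pathways kept in the bank (>= 2, or 1 for the
#'   degenerate hill-descent mode).
#' @param n_initial number of random initial pathways locally optimized to
#'   form the first bank (>= bank_size). The default equals `bank_size`, so
#'   the bank starts as a copy of the whole first bank and inherits its full
#'   diversity; with `n_initial > bank_size` only the lowest-action members
#'   are copied.
#' @param n_seeds_per_round bank members used as seeds each round.
#' @param n_trials_per_seed trial pathways generated per seed.
#' @param crossover_fraction fraction of trials generated by crossover (the
#'   rest by mutation).
#' @param mutation_dof_fraction maximum fraction of the interior degrees of
#'   freedom perturbed by one mutation (default 0.05, i.e. up to 5%).
#' @param mutation_magnitude per-coordinate scale of mutation perturbations.
#' @param init_scale amplitude of the stochastic-bridge perturbation used for
#'   the initial random pathways.
#' @param dcut_init_factor,dcut_final_factor diversity-cutoff schedule
#'   endpoints, as fractions of the initial average pairwise Frechet distance
#'   of the bank.
#' @param dcut_rounds rounds over which the cutoff anneals geometrically.
#' @param max_rounds hard cap on the number of rounds.
#' @param patience stop after this many consecutive rounds in which no
#'   admission lowered the best or the mean bank action.
#' @return a list of class `"csa_config"`.
#' @export
csa_config <- function(bank_size = 12, n_initial = bank_size,
                       n_seeds_per_round = max(2L, bank_size %/% 2L),
                       n_trials_per_seed = 2,
                       crossover_fraction = 0.5,
                       mutation_dof_fraction = 0.05,
                       mutation_magnitude = 0.3,
                       init_scale = 0.5,
                       dcut_init_factor = 0.5, dcut_final_factor = 0.2,
                       dcut_rounds = 10, max_rounds = 60, patience = 5) {
  stopifnot(bank_size >= 1, n_initial >= bank_size,
            n_seeds_per_round >= 1, n_trials_per_seed >= 1,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_dof_fraction > 0, mutation_dof_fraction <= 1,
            mutation_magnitude > 0, init_scale >= 0,
            dcut_init_factor > dcut_final_factor, dcut_final_factor > 0,
            dcut_rounds >= 1, max_rounds >= 1, patience >= 1)
  structure(as.list(environment()), class = "csa_config")
}

#' Random initial pathways
#'
#' Straight-line interpolation between the endpoints plus a mean-zero
#' stochastic bridge (a cumulative Gaussian walk pinned to zero at both
#' endpoints, normalized so its mid-path standard deviation is `scale`) on
#' every interior replica. For torsion coordinates each coordinate's winding
#' direction is additionally drawn at random between the minimum-image
#' rotation and its complement (the long way around the circle), so that the
#' initial ensemble populates both homotopy classes of every dihedral --
#' without this, every random pathway would start in the short-way (cis)
#' class. With `scale = 0` the perturbation and the winding randomization
#' are both switched off and all paths equal the minimum-image straight
#' interpolation.
#'
#' @param n number of pathways.
#' @param ep an [endpoint_pair()].
#' @param P number of slices.
#' @param dt time step (ps).
#' @param scale bridge amplitude; `0` gives exact straight interpolations.
#' @param kind coordinate convention.
#' @return a list of pathways.
#' @export
generate_initial_paths <- function(n, ep, P, dt, scale,
                                   kind = c("cartesian", "torsion")) {
  kind <- match.arg(kind)
  base <- interpolate_path(ep$x_initial, ep$x_final, P, dt, kind)
  step0 <- coord_diff(ep$x_final, ep$x_initial, kind)
  frac <- seq(0, 1, length.out = P + 1L)
  lapply(seq_len(n), function(i) {
    if (scale == 0) return(base)
    nd <- ncol(base)
    step <- step0
    if (kind == "torsion") {
      flip <- stats::runif(nd) < 0.5 & abs(step0) > 1e-12
      step[flip] <- step0[flip] - 2 * pi * sign(step0[flip])
    }
    reps <- outer(frac, step) + rep(ep$x_initial, each = P + 1L)
    walk <- apply(matrix(stats::rnorm((P + 1L) * nd), P + 1L, nd), 2L, cumsum)
    bridge <- (walk - outer(frac, walk[P + 1L, ])) * (2 / sqrt(P))
    reps[2:P, ] <- reps[2:P, , drop = FALSE] +
      scale * bridge[2:P, , drop = FALSE]
    pathway(reps, dt = dt, kind = kind)
  })
}

#' Crossover of two pathways
#'
#' One contiguous window of interior replicas, chosen uniformly at random
#' among all interior windows, is copied from the partner into the seed.
#' Endpoints are untouched.
#'
#' @param seed,partner pathways with identical P, dt and endpoints.
#' @return a new pathway.
#' @export
crossover <- function(seed, partner) {
  stopifnot_same_frame(seed, partner)
  P <- n_slices(seed)
  if (P < 3L)
    stop("crossover needs at least two interior replicas (P >= 3)",
         call. = FALSE)
  if (n_slices(partner) != P || path_dt(partner) != path_dt(seed))
    stop("crossover partners must share P and dt", call. = FALSE)
  # window [a, b] over interior replicas 1..P-1, uniform over all windows
  k <- sample.int((P - 1L) * P / 2L, 1L)
  a <- 1L
  while (k > P - a) { k <- k - (P - a); a <- a + 1L }
  b <- a + k - 1L
  a <- a + 1L; b <- b + 1L                  # interior rows are 2..P
  out <- unclass(seed)
  out[a:b, ] <- unclass(partner)[a:b, ]
  pathway(out, dt = path_dt(seed), kind = path_kind(seed))
}

#' Mutation of a pathway
#'
#' A random subset of at most
#' `ceiling(mutation_dof_fraction * (P-1) * dim)` interior scalar degrees of
#' freedom (at least one) receives independent Gaussian perturbations of
#' scale `mutation_magnitude`. Endpoints are untouched.
#'
#' @param seed a pathway.
#' @param cfg a [csa_config()].
#' @return a new pathway.
#' @export
mutate <- function(seed, cfg) {
  P <- n_slices(seed)
  nd <- ncol(seed)
  nfree <- (P - 1L) * nd
  kmax <- max(1L, ceiling(cfg$mutation_dof_fraction * nfree))
  k <- sample.int(kmax, 1L)
  idx <- sample.int(nfree, k)
  interior <- path_interior(seed)
  interior[idx] <- interior[idx] + stats::rnorm(k, sd = cfg$mutation_magnitude)
  set_interior(seed, interior)
}

new_bank <- function(paths, som, prov) {
  structure(list(paths = paths, som = som, prov = prov,
                 dcut_current = NA_real_),
            class = "pathway_bank")
}

#' @export
print.pathway_bank <- function(x, ...) {
  cat(sprintf("<pathway bank>  %d members, S_OM in [%.4g, %.4g], D_cut = %.4g\n",
              length(x$paths), min(x$som), max(x$som), x$dcut_current))
  invisible(x)
}

#' Two-branch diversity-preserving bank update
#'
#' For a locally optimized candidate, the Frechet distances to all bank
#' members are computed. If the closest member is nearer than the current
#' cutoff `D_cut` (ties count as near), the candidate competes with that
#' member only and replaces it if its action is strictly lower. Otherwise
#' the candidate counts as a new pathway class and replaces the worst bank
#' member if its action is lower than that member's. The bank size never
#' changes; at equal action the incumbent is kept.
#'
#' @param bank a pathway bank.
#' @param cand_path locally optimized candidate pathway.
#' @param cand_som its Onsager-Machlup action.
#' @return a list with the updated `bank`, `admitted` flag and `reason`, one
#'   of `"replaced_neighbor"`, `"rejected_neighbor_better"`,
#'   `"replaced_worst"`, `"rejected_not_better"`.
#' @export
update_bank <- function(bank, cand_path, cand_som) {
  d <- vapply(bank$paths,
              function(p) frechet_distance(p, cand_path)$value, numeric(1L))
  nearest <- which.min(d)
  if (d[nearest] <= bank$dcut_current) {
    if (cand_som < bank$som[nearest]) {
      bank$paths[[nearest]] <- cand_path
      bank$som[nearest] <- cand_som
      bank$prov[nearest] <- "replaced_neighbor"
      return(list(bank = bank, admitted = TRUE, reason = "replaced_neighbor"))
    }
    return(list(bank = bank, admitted = FALSE,
                reason = "rejected_neighbor_better"))
  }
  worst <- which.max(bank$som)
  if (cand_som < bank$som[worst]) {
    bank$paths[[worst]] <- cand_path
    bank$som[worst] <- cand_som
    bank$prov[worst] <- "replaced_worst"
    return(list(bank = bank, admitted = TRUE, reason = "replaced_worst"))
  }
  list(bank = bank, admitted = FALSE, reason = "rejected_not_better")
}

#' Annealed diversity cutoff
#'
#' Geometric interpolation from `dcut_init_factor * d_avg_init` down to
#' `dcut_final_factor * d_avg_init` over `dcut_rounds` rounds, constant
#' thereafter.
#'
#' @param round round index (0-based).
#' @param cfg a [csa_config()].
#' @param d_avg_init mean pairwise Frechet distance of the initial bank.
#' @return the cutoff distance for this round.
#' @export
anneal_dcut <- function(round, cfg, d_avg_init) {
  stopifnot(round >= 0)
  frac <- min(round / cfg$dcut_rounds, 1)
  d_avg_init * cfg$dcut_init_factor *
    (cfg$dcut_final_factor / cfg$dcut_init_factor)^frac
}

mean_pairwise_frechet <- function(paths) {
  n <- length(paths)
  if (n < 2L) return(0)
  tot <- 0; cnt <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + frechet_distance(paths[[i]], paths[[j]])$value
    cnt <- cnt + 1L
  }
  tot / cnt
}

#' Global pathway search by conformational space annealing
#'
#' The main fitting-style entry point. Starting from `n_initial` random
#' pathways, each locally optimized by [minimize_theta()], the best
#' `bank_size` form the immutable *first bank* and an evolving copy, the
#' *bank*. Each round, seed pathways are combined by [crossover()] with
#' partners drawn with equal probability from the bank or the first bank, or
#' perturbed by [mutate()]; trials are locally optimized against Theta, their
#' Onsager-Machlup action is evaluated once, and the bank is updated by the
#' two-branch rule of [update_bank()] under the annealed diversity cutoff.
#' The run stops when `patience` consecutive rounds bring no improvement of
#' the best or mean bank action, or after `max_rounds`.
#'
#' @param pot a potential.
#' @param ep an [endpoint_pair()].
#' @param P number of slices.
#' @param dt time step (ps).
#' @param th [thermo_params()].
#' @param w [action_weights()].
#' @param cfg [csa_config()].
#' @param opt [local_opt_settings()] for the local minimizations.
#' @param seed integer RNG seed; identical seeds give identical runs.
#' @param verbose print one line per round.
#' @return an object of class `"action_csa"` with components `bank`,
#'   `first_bank`, `report` (per-round data.frame), `pot`, `th`, `w`, `cfg`,
#'   `P`, `dt` and `seed`.
#' @export
action_csa <- function(pot, ep, P, dt, th, w, cfg = csa_config(),
                       opt = local_opt_settings(grad_tol = 1e-2,
                                                max_iter = 300),
                       seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ep, "endpoint_pair"), inherits(cfg, "csa_config"))
  set.seed(seed)
  kind <- pot$coord_kind

  init <- generate_initial_paths(cfg$n_initial, ep, P, dt,
                                 scale = cfg$init_scale, kind = kind)
  first <- lapply(init, function(p) minimize_theta(p, pot, w, opt)$path)
  first_som <- vapply(first, function(p) om_action(p, pot, th), numeric(1L))

  ord <- order(first_som)[seq_len(cfg$bank_size)]
  bank <- new_bank(first[ord], first_som[ord],
                   rep("first_bank", cfg$bank_size))
  d_avg_init <- mean_pairwise_frechet(bank$paths)
  if (d_avg_init <= 0) d_avg_init <- .Machine$double.eps

  used <- rep(FALSE, cfg$bank_size)
  report <- list()
  stall <- 0L
  for (round in seq_len(cfg$max_rounds) - 1L) {
    bank$dcut_current <- anneal_dcut(round, cfg, d_avg_init)
    best_before <- min(bank$som)
    mean_before <- mean(bank$som)

    if (all(used)) used[] <- FALSE
    avail <- which(!used)
    seeds <- avail[seq_len(min(cfg$n_seeds_per_round, length(avail)))]
    used[seeds] <- TRUE

    n_adm <- 0L
    for (si in seeds) {
      for (k in seq_len(cfg$n_trials_per_seed)) {
        trial <- if (stats::runif(1) < cfg$crossover_fraction && P >= 3L) {
          partner <- if (stats::runif(1) < 0.5) {
            bank$paths[[sample.int(length(bank$paths), 1L)]]
          } else {
            first[[sample.int(length(first), 1L)]]
          }
          crossover(bank$paths[[si]], partner)
        } else {
          mutate(bank$paths[[si]], cfg)
        }
        res <- minimize_theta(trial, pot, w, opt)
        som <- om_action(res$path, pot, th)
        upd <- update_bank(bank, res$path, som)
        bank <- upd$bank
        if (upd$admitted) n_adm <- n_adm + 1L
      }
    }

    tol <- 1e-7 * (1 + abs(mean_before))
    improved <- min(bank$som) < best_before - tol ||
      mean(bank$som) < mean_before - tol
    stall <- if (improved) 0L else stall + 1L
    report[[length(report) + 1L]] <-
      data.frame(round = round, best_som = min(bank$som),
                 mean_som = mean(bank$som), n_admitted = n_adm,
                 dcut = bank$dcut_current)
    if (verbose)
      cat(sprintf("round %3d  best %.6g  mean %.6g  admitted %d  dcut %.3g\n",
                  round, min(bank$som), mean(bank$som), n_adm,
                  bank$dcut_current))
    if (stall >= cfg$patience) break
  }

  structure(list(bank = bank,
                 first_bank = list(paths = first, som = first_som),
                 report = do.call(rbind, report),
                 pot = pot, ep = ep, th = th, w = w, cfg = cfg,
                 P = P, dt = dt, seed = seed),
            class = "action_csa")
}

#' Best pathway of a search
#' @param fit an `"action_csa"` object.
#' @return the bank pathway with the lowest Onsager-Machlup action.
#' @export
best_path <- function(fit) {
  stopifnot(inherits(fit, "action_csa"))
  fit$bank$paths[[which.min(fit$bank$som)]]
}

#' @export
print.action_csa <- function(x, ...) {
  cat(sprintf("Pathway search by conformational space annealing ('%s', dim %d)\n",
              x$pot$name, x$pot$dim))
  cat(sprintf("  %d slices of %g ps (t = %g ps), bank of %d pathways\n",
              x$P, x$dt, x$P * x$dt, length(x$bank$paths)))
  cat(sprintf("  %d rounds, best S_OM = %.6g, bank mean = %.6g\n",
              nrow(x$report), min(x$bank$som), mean(x$bank$som)))
  invisible(x)
}

#' @export
summary.action_csa <- function(object, ...) {
  ord <- order(object$bank$som)
  out <- data.frame(rank = seq_along(ord),
                    som = object$bank$som[ord],
                    provenance = object$bank$prov[ord])
  kbt <- object$th$kB * object$th$temperature
  out$rel_weight <- exp(-(out$som - out$som[1L]) / kbt)
  cat("Bank pathways by Onsager-Machlup action:\n")
  print(out, row.names = FALSE, digits = 6)
  invisible(out)
}

#' @export
plot.action_csa <- function(x, ...) {
  rep <- x$report
  graphics::plot(rep$round, rep$best_som, type = "b", pch = 16,
                 xlab = "round", ylab = expression(S[OM]),
                 ylim = range(c(rep$best_som, rep$mean_som)), ...)
  graphics::lines(rep$round, rep$mean_som, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", c("bank best", "bank mean"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
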