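#' Pathway file input and output
#'
#' Cartesian pathways are written as multi-frame XYZ (one frame per replica:
#' atom-count line, comment line, then `element x y z` rows; coordinates are
#' packed three per pseudo-atom `X`, zero-padded when the dimension is not a
#' multiple of three). Torsion pathways are written as a whitespace-delimited
#' angle table in degrees, one row per replica, one column per dihedral.
#' Both formats carry a header recording format version, coordinate kind,
#' dimension, number of slices, time step and provenance; `read_path()`
#' refuses files whose frame count disagrees with the header.
#'
#' @param file file path.
#' @param path a [pathway()].
#' @param provenance free-text provenance string stored in the header.
#' @return `read_path()` returns a [pathway()]; `write_path()` returns
#'   `file` invisibly.
#' @name path_io
NULL

path_header <- function(path, provenance) {
  sprintf("actioncsa-path v1 kind=%s dim=%d P=%d dt=%.12g provenance=%s",
          path_kind(path), ncol(path), n_slices(path), path_dt(path),
          provenance)
}

parse_header <- function(line, file) {
  if (!grepl("^#? ?actioncsa-path v1 ", line))
    stop(sprintf("%s:1: missing actioncsa path header", file), call. = FALSE)
  get <- function(key, conv) {
    m <- regmatches(line, regexpr(sprintf("%s=[^ ]+", key), line))
    if (!length(m)) stop(sprintf("%s:1: header lacks %s", file, key),
                         call. = FALSE)
    conv(sub(sprintf("%s=", key), "", m))
  }
  list(kind = get("kind", as.character), dim = get("dim", as.integer),
       P = get("P", as.integer), dt = get("dt", as.numeric))
}

#' @rdname path_io
#' @export
write_path <- function(path, file, provenance = "actioncsa") {
  stopifnot(inherits(path, "pathway"))
  con <- file(file, "w"); on.exit(close(con))
  if (path_kind(path) == "torsion") {
    writeLines(paste0("# ", path_header(path, provenance)), con)
    writeLines("# angles in degrees, one row per replica", con)
    utils::write.table(unclass(path) * 180 / pi, con, row.names = FALSE,
                       col.names = FALSE)
  } else {
    m <- unclass(path)
    natoms <- ceiling(ncol(m) / 3)
    padded <- cbind(m, matrix(0, nrow(m), natoms * 3L - ncol(m)))
    for (r in seq_len(nrow(m))) {
      writeLines(as.character(natoms), con)
      writeLines(sprintf("replica=%d %s", r - 1L,
                         path_header(path, provenance)), con)
      for (a in seq_len(natoms)) {
        writeLines(sprintf("X %.17g %.17g %.17g",
                           padded[r, 3L * a - 2L], padded[r, 3L * a - 1L],
                           padded[r, 3L * a]), con)
      }
    }
  }
  invisible(file)
}

#' @rdname path_io
#' @export
read_path <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop(sprintf("%s: empty file", file), call. = FALSE)
  if (grepl("^# ?actioncsa-path", lines[1L])) {
    h <- parse_header(lines[1L], file)
    if (h$kind != "torsion")
      stop(sprintf("%s:1: angle table with kind=%s", file, h$kind),
           call. = FALSE)
    dat <- lines[!grepl("^#", lines)]
    rows <- lapply(seq_along(dat), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(dat[i]), "[ \t]+")[[1L]]))
      if (any(is.na(v)) || length(v) != h$dim)
        stop(sprintf("%s:%d: malformed angle row", file,
                     which(!grepl("^#", lines))[i]), call. = FALSE)
      v
    })
    if (length(rows) != h$P + 1L)
      stop(sprintf("%s: %d angle rows but header says P+1 = %d", file,
                   length(rows), h$P + 1L), call. = FALSE)
    ang <- do.call(rbind, rows) * pi / 180
    oob <- abs(do.call(rbind, rows)) > 180
    if (any(oob))
      message(sprintf("%s: %d angle(s) outside (-180, 180] normalized on read",
                      file, sum(oob)))
    pathway(wrap_angle(ang), dt = h$dt, kind = "torsion")
  } else {
    # multi-frame XYZ
    natoms <- suppressWarnings(as.integer(lines[1L]))
    if (is.na(natoms) || natoms < 1L)
      stop(sprintf("%s:1: expected an atom count", file), call. = FALSE)
    h <- parse_header(sub("^replica=\\d+ ", "", lines[2L]), file)
    frame_len <- natoms + 2L
    if (length(lines) %% frame_len != 0L)
      stop(sprintf("%s: truncated XYZ frame near line %d", file,
                   (length(lines) %/% frame_len) * frame_len + 1L),
           call. = FALSE)
    nframes <- length(lines) %/% frame_len
    if (nframes != h$P + 1L)
      stop(sprintf("%s: %d frames but header says P+1 = %d", file, nframes,
                   h$P + 1L), call. = FALSE)
    reps <- matrix(NA_real_, nframes, h$dim)
    for (f in seq_len(nframes)) {
      base <- (f - 1L) * frame_len
      coords <- numeric(0)
      for (a in seq_len(natoms)) {
        parts <- strsplit(trimws(lines[base + 2L + a]), "[ \t]+")[[1L]]
        v <- suppressWarnings(as.numeric(parts[2:4]))
        if (length(parts) < 4L || any(is.na(v)))
          stop(sprintf("%s:%d: malformed atom row", file, base + 2L + a),
               call. = FALSE)
        coords <- c(coords, v)
      }
      reps[f, ] <- coords[seq_len(h$dim)]
    }
    pathway(reps, dt = h$dt, kind = "cartesian")
  }
}

#' Reference total energy for the Theta restraint
#'
#' The potential energy of the initial configuration plus the equipartition
#' kinetic energy `3 N kB T / 2` of an `N`-atom system.
#'
#' @param pot a potential.
#' @param x_initial initial configuration.
#' @param N_atoms number of atoms of the modelled system (>= 1). For the
#'   abstract toy surfaces a natural choice is `dim/3` rounded up, or
#'   equivalently use `dim * kB * T / 2` directly via
#'   `kinetic_part = FALSE` bookkeeping by the caller.
#' @param th [thermo_params()].
#' @return `V(x_initial) + 3 * N_atoms * kB * T / 2` (kcal/mol).
#' @export
compute_reference_energy <- function(pot, x_initial, N_atoms, th) {
  stopifnot(N_atoms >= 1)
  evaluate_energy(pot, x_initial) +
    3 * N_atoms * th$kB * th$temperature / 2
}

#' Read a run configuration file
#'
#' YAML configuration with blocks `potential` (name + parameters),
#' `endpoints`, `pathway` (P, dt), `thermo`, `weights`, `csa`, `ld` and
#' `output`. Unknown top-level keys are rejected.
#'
#' @param file YAML file path.
#' @return a named list with constructed package objects.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("potential", "endpoints", "pathway", "thermo", "weights",
             "csa", "ld", "basins", "output", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  pot <- do.call(cfg$potential$name,
                 cfg$potential[setdiff(names(cfg$potential), "name")])
  th <- do.call(thermo_params, if (is.null(cfg$thermo)) list() else cfg$thermo)
  ep <- endpoint_pair(pot, cfg$endpoints$x_initial, cfg$endpoints$x_final,
                      grad_tol = if (is.null(cfg$endpoints$grad_tol)) 1e-6
                      else cfg$endpoints$grad_tol)
  wdef <- if (is.null(cfg$weights)) list() else cfg$weights
  if (is.null(wdef$E_target)) {
    natoms <- max(1L, ceiling(pot$dim / 3))
    wdef$E_target <- compute_reference_energy(pot, ep$x_initial, natoms, th)
  }
  w <- do.call(action_weights, wdef)
  csa <- do.call(csa_config, if (is.null(cfg$csa)) list() else cfg$csa)
  ld <- if (is.null(cfg$ld)) NULL else do.call(ld_settings, cfg$ld)
  list(pot = pot, ep = ep, P = cfg$pathway$P, dt = cfg$pathway$dt,
       th = th, w = w, csa = csa, ld = ld, basins = cfg$basins,
       output = cfg$output, seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Write a search result to disk
#'
#' Bank members as numbered path files, `bank.jsonl` (one JSON record per
#' member with file name, S_OM, provenance), and `run_report.json` with the
#' per-round trace, configuration echo and seed.
#'
#' @param fit an `"action_csa"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bank <- function(fit, dir) {
  stopifnot(inherits(fit, "action_csa"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (fit$pot$coord_kind == "torsion") "dat" else "xyz"
  files <- character(length(fit$bank$paths))
  for (i in seq_along(fit$bank$paths)) {
    files[i] <- sprintf("bank_%03d.%s", i, ext)
    write_path(fit$bank$paths[[i]], file.path(dir, files[i]),
               provenance = sprintf("action_csa seed=%d", fit$seed))
  }
  con <- file(file.path(dir, "bank.jsonl"), "w")
  for (i in seq_along(files)) {
    writeLines(jsonlite::toJSON(list(file = files[i], som = fit$bank$som[i],
                                     provenance = fit$bank$prov[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  jsonlite::write_json(
    list(seed = fit$seed, P = fit$P, dt = fit$dt,
         potential = fit$pot$name,
         rounds = fit$report,
         best_som = min(fit$bank$som)),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}

#' Deterministic test fixtures
#'
#' @param kind one of `"random_paths"`, `"two_channel_endpoints"`,
#'   `"torsional_endpoints"`, `"planted_transitions"`.
#' @param dir output directory.
#' @param seed RNG seed; identical seeds give identical files.
#' @return list of created file paths, invisibly; the fixture objects are
#'   returned in the `objects` attribute for direct use.
#' @export
make_fixture <- function(kind, dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- character(); objects <- list()
  if (kind == "random_paths") {
    pot <- two_channel_2d()
    ep <- two_channel_endpoints(pot)
    paths <- generate_initial_paths(3L, ep, P = 20L, dt = 0.005, scale = 0.3)
    for (i in seq_along(paths)) {
      f <- file.path(dir, sprintf("random_path_%d.xyz", i))
      write_path(paths[[i]], f, provenance = sprintf("fixture seed=%d", seed))
      files <- c(files, f)
    }
    objects$paths <- paths
  } else if (kind == "two_channel_endpoints") {
    pot <- two_channel_2d()
    ep <- two_channel_endpoints(pot)
    f <- file.path(dir, "two_channel_endpoints.yaml")
    yaml::write_yaml(list(x_initial = ep$x_initial, x_final = ep$x_final), f)
    files <- f; objects$ep <- ep
  } else if (kind == "torsional_endpoints") {
    n <- 2L
    f <- file.path(dir, "torsional_endpoints.yaml")
    yaml::write_yaml(list(x_initial = rep(-pi / 3, n),
                          x_final = rep(pi / 3, n)), f)
    files <- f
    objects$ep <- endpoint_pair(torsional_chain(n), rep(-pi / 3, n),
                                rep(pi / 3, n), grad_tol = 1e-8)
  } else if (kind == "planted_transitions") {
    # piecewise trajectory visiting A-core, saddle, B-core with known timing
    a <- c(-1, 0); b <- c(1, 0)
    seg <- function(from, to, k) {
      t(vapply(seq(0, 1, length.out = k), function(f) from + f * (to - from),
               numeric(2L)))
    }
    m <- rbind(seg(a, a, 5L), seg(a, c(0, -1), 10L), seg(c(0, -1), b, 10L),
               seg(b, b, 5L))
    traj <- structure(list(times = seq_len(nrow(m)) * 0.01 - 0.01,
                           coords = array(m, c(nrow(m), 1L, 2L)),
                           kind = "cartesian",
                           settings = ld_settings(dt_sim = 0.01)),
                      class = "ld_trajectory")
    f <- file.path(dir, "planted_transitions.tsv")
    utils::write.table(data.frame(t = traj$times, x = m[, 1L], y = m[, 2L]),
                       f, sep = "\t", row.names = FALSE)
    files <- f; objects$traj <- traj; objects$n_planted <- 1L
  } else {
    stop(sprintf("unknown fixture kind '%s'", kind), call. = FALSE)
  }
  out <- invisible(files)
  attr(out, "objects") <- objects
  out
}

#' Polished endpoints of the two-channel surface
#'
#' Newton-refines the two well minima of [two_channel_2d()] so they satisfy
#' the endpoint gradient tolerance exactly.
#'
#' @param pot a [two_channel_2d()] potential.
#' @return an [endpoint_pair()] between the left and right minima.
#' @export
two_channel_endpoints <- function(pot = two_channel_2d()) {
  left <- find_stationary(pot, c(-1.1, 0))
  right <- find_stationary(pot, c(1.1, 0))
  stopifnot(left$converged, right$converged, left$index == 0L,
            right$index == 0L)
  endpoint_pair(pot, left$x, right$x, labels = c("left_well", "right_well"),
                grad_tol = 1e-8)
}
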