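#' Exhaustive enumeration of torsional transition pathways
#'
#' Enumerates all transition pathways of an `n`-dihedral rotamer chain from
#' the all-gauche(-) state to the all-gauche(+) state. Each dihedral has the
#' three rotameric states g- / t / g+ (coded 0 / 1 / 2) and a pathway is a
#' sequence of elementary barrier crossings, one dihedral at a time. Under
#' the default scheme each dihedral must travel g- -> t -> g+ (the cis
#' barrier is never crossed and no torsional barrier is crossed more than
#' once, so crossings are monotone), and intermediate chain states placing
#' two *adjacent* dihedrals in opposite gauche states (g+g- or g-g+, the
#' steric clash familiar from syn-pentane) are excluded. For a three-dihedral
#' chain this scheme yields 44 pathways.
#'
#' With `forbid_cis = FALSE` a dihedral may also hop g- <-> g+ directly over
#' the cis barrier (each barrier still at most once).
#'
#' @param n number of dihedrals (>= 1).
#' @param forbid_cis disallow direct g- <-> g+ crossings.
#' @param single_crossing require each torsional barrier to be crossed at
#'   most once (must currently be TRUE; the unrestricted pathway space is
#'   infinite).
#' @param forbid_adjacent_clash exclude intermediate states with adjacent
#'   dihedrals in opposite gauche states.
#' @return a list of class `"torsion_pathways"`; each element has `events`
#'   (data.frame with columns `dihedral`, `from`, `to`) and `states` (matrix
#'   of visited states, one row per state, coded 0/1/2).
#' @export
enumerate_pathways <- function(n, forbid_cis = TRUE, single_crossing = TRUE,
                               forbid_adjacent_clash = TRUE) {
  stopifnot(n >= 1)
  if (!single_crossing)
    stop("only the single-crossing scheme is enumerable (infinite otherwise)",
         call. = FALSE)
  state_ok <- function(s) {
    !forbid_adjacent_clash || n < 2L || all(abs(diff(s)) != 2L)
  }
  # barriers per dihedral: 1 = g-/t, 2 = t/g+, 3 = cis (g-/g+)
  res <- list()
  rec <- function(state, crossed, states, events) {
    if (all(state == 2L)) {
      res[[length(res) + 1L]] <<- list(
        events = if (nrow(events)) events else
          data.frame(dihedral = integer(), from = integer(), to = integer()),
        states = states)
      return(invisible())
    }
    for (i in seq_len(n)) {
      moves <- list()
      if (state[i] == 0L && !crossed[i, 1L])
        moves <- c(moves, list(c(to = 1L, barrier = 1L)))
      if (state[i] == 1L && !crossed[i, 2L])
        moves <- c(moves, list(c(to = 2L, barrier = 2L)))
      if (!forbid_cis) {
        if (state[i] == 0L && !crossed[i, 3L])
          moves <- c(moves, list(c(to = 2L, barrier = 3L)))
        if (state[i] == 2L && !crossed[i, 3L])
          moves <- c(moves, list(c(to = 0L, barrier = 3L)))
      }
      for (mv in moves) {
        ns <- state; ns[i] <- mv[["to"]]
        if (!state_ok(ns)) next
        nc <- crossed; nc[i, mv[["barrier"]]] <- TRUE
        rec(ns, nc, rbind(states, ns),
            rbind(events, data.frame(dihedral = i, from = state[i],
                                     to = mv[["to"]])))
      }
    }
  }
  rec(rep(0L, n), matrix(FALSE, n, 3L), matrix(rep(0L, n), nrow = 1L),
      data.frame(dihedral = integer(), from = integer(), to = integer()))
  structure(res, n = n, class = "torsion_pathways")
}

#' @export
print.torsion_pathways <- function(x, ...) {
  cat(sprintf("<torsion pathways>  %d pathways for %d dihedrals\n",
              length(x), attr(x, "n")))
  invisible(x)
}

#' Canonical event string of a torsional pathway
#'
#' The dot-separated sequence of moved dihedral indices; under the
#' single-crossing scheme this is bijective with the visited state sequence.
#'
#' @param pw one element of an [enumerate_pathways()] result.
#' @return a character scalar such as `"1.2.1.2"`.
#' @export
event_string <- function(pw) paste(pw$events$dihedral, collapse = ".")

# symmetry images at the event-string level: mirror (g- <-> g+) combined
# with time reversal acts as sequence reversal; chain reversal relabels
# dihedral i -> n + 1 - i
string_images <- function(str, n, symmetries) {
  v <- as.integer(strsplit(str, ".", fixed = TRUE)[[1L]])
  imgs <- list(v)
  if ("mirror_time_reversal" %in% symmetries)
    imgs <- c(imgs, lapply(imgs, rev))
  if ("chain_reversal" %in% symmetries)
    imgs <- c(imgs, lapply(imgs, function(u) n + 1L - u))
  unique(vapply(imgs, paste, character(1L), collapse = "."))
}

# transit interval [first, last] event positions of each dihedral
transit_intervals <- function(v, n) {
  t(vapply(seq_len(n), function(i) range(which(v == i)), numeric(2L)))
}

# eligible concerted swaps: adjacent events of two non-interacting dihedrals
# whose transits mutually overlap and are both enclosed by the transit of a
# common neighbouring dihedral (the crossed concerted motif); returns the
# swapped strings
concerted_images <- function(str, n) {
  v <- as.integer(strsplit(str, ".", fixed = TRUE)[[1L]])
  if (!length(v)) return(character())
  ti <- transit_intervals(v, n)
  ok_pair <- function(u, i, j) {
    t2 <- transit_intervals(u, n)
    overlap <- t2[i, 1L] < t2[j, 2L] && t2[j, 1L] < t2[i, 2L]
    if (!overlap) return(FALSE)
    for (k in seq_len(n)) {
      if (abs(k - i) == 1L && abs(k - j) == 1L &&
          t2[k, 1L] < min(t2[i, 1L], t2[j, 1L]) &&
          t2[k, 2L] > max(t2[i, 2L], t2[j, 2L])) return(TRUE)
    }
    FALSE
  }
  out <- character()
  for (p in seq_len(length(v) - 1L)) {
    i <- v[p]; j <- v[p + 1L]
    if (abs(i - j) < 2L) next
    w <- v; w[c(p, p + 1L)] <- w[c(p + 1L, p)]
    if (ok_pair(v, i, j) && ok_pair(w, i, j))
      out <- c(out, paste(w, collapse = "."))
  }
  unique(out)
}

#' Reduce enumerated pathways to symmetry classes
#'
#' Partitions the pathway set into equivalence classes under the declared
#' symmetries of the rotamer chain: the mirror symmetry of the dihedral
#' potential (g- <-> g+, which maps a forward pathway onto a time-reversed
#' one) and the reversal of the atomic chain order (dihedral `i -> n+1-i`).
#' Optionally, interleaving orders of the crossed concerted motif -- two
#' non-interacting dihedrals whose transits overlap each other and are both
#' enclosed within the transit of a common neighbouring dihedral -- are
#' identified (`merge_enclosed_concerted`), since they describe a single
#' concerted mechanism rather than distinguishable pathways. Under the
#' default scheme the 44 three-dihedral pathways reduce to 14 types.
#'
#' @param pathways a `"torsion_pathways"` list from [enumerate_pathways()].
#' @param symmetries character vector among `"mirror_time_reversal"`,
#'   `"chain_reversal"`; empty for identity-only classes.
#' @param merge_enclosed_concerted identify interleavings of the enclosed
#'   crossed concerted motif.
#' @return a list of class `"pathway_classes"`; each element has `members`
#'   (integer indices into `pathways`), `representative` (lowest member
#'   index) and `label` (`"type01"`, ...).
#' @export
reduce_by_symmetry <- function(pathways,
                               symmetries = c("mirror_time_reversal",
                                              "chain_reversal"),
                               merge_enclosed_concerted = TRUE) {
  stopifnot(inherits(pathways, "torsion_pathways"))
  n <- attr(pathways, "n")
  strs <- vapply(pathways, event_string, character(1L))
  idx_of <- seq_along(strs); names(idx_of) <- strs
  # union-find
  parent <- seq_along(strs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_along(strs)) {
    for (img in string_images(strs[i], n, symmetries)) {
      j <- idx_of[img]
      if (!is.na(j)) union_(i, j)
    }
    if (merge_enclosed_concerted) {
      for (img in concerted_images(strs[i], n)) {
        j <- idx_of[img]
        if (!is.na(j)) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_along(strs), find, integer(1L))
  classes <- lapply(sort(unique(roots)), function(r) which(roots == r))
  out <- lapply(seq_along(classes), function(k)
    list(members = classes[[k]], representative = classes[[k]][1L],
         label = sprintf("type%02d", k)))
  structure(out, n = n, class = "pathway_classes")
}

#' @export
print.pathway_classes <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1L))
  cat(sprintf("<pathway classes>  %d classes of sizes %s (total %d)\n",
              length(x), paste(sizes, collapse = ","), sum(sizes)))
  invisible(x)
}

# classify one angle (radians) into rotamer code 0 (g-), 1 (t), 2 (g+);
# boundaries are the barrier positions 0 and +-120 degrees
rotamer_code <- function(phi) {
  out <- integer(length(phi))
  out[phi > -2 * pi / 3 & phi < 0] <- 0L
  out[phi >= 0 & phi < 2 * pi / 3] <- 2L
  out[phi >= 2 * pi / 3 | phi <= -2 * pi / 3] <- 1L
  out
}

#' Barrier-crossing events along a torsion pathway
#'
#' Classifies every replica of every dihedral into the rotamer basins
#' (boundaries at the barrier angles 0 and +-120 degrees) and reports the
#' basin-change events in replica order.
#'
#' @param path a torsion-space pathway.
#' @return a data.frame with columns `dihedral`, `from`, `to` (rotamer codes
#'   0 = gauche(-), 1 = trans, 2 = gauche(+)).
#' @export
trace_events <- function(path) {
  stopifnot(path_kind(path) == "torsion")
  codes <- apply(unclass(path), 2L, rotamer_code)
  ev <- list()
  for (r in 2:nrow(codes)) {
    ch <- which(codes[r, ] != codes[r - 1L, ])
    for (i in ch)
      ev[[length(ev) + 1L]] <- data.frame(dihedral = i,
                                          from = codes[r - 1L, i],
                                          to = codes[r, i])
  }
  if (length(ev)) do.call(rbind, ev) else
    data.frame(dihedral = integer(), from = integer(), to = integer())
}

#' Coverage of the enumerated pathway set by a search result
#'
#' Maps every bank pathway of a torsional-chain search onto its
#' barrier-crossing event sequence and matches it against the enumerated
#' pathways. Members whose traces cross some torsional barrier more than
#' once (or cross cis) are reported in a separate multi-crossing bin, never
#' dropped silently.
#'
#' @param bank_paths list of torsion-space pathways (e.g. `fit$bank$paths`).
#' @param pathways enumeration from [enumerate_pathways()].
#' @param classes classes from [reduce_by_symmetry()].
#' @return a list of class `"coverage_report"`: `found_pathways`,
#'   `total_pathways`, `found_classes`, `total_classes`,
#'   `pathway_of_member` (index or NA), `multi_crossing` (member indices
#'   whose traces re-cross a barrier or cross cis), `unmatched` (monotone
#'   traces outside the enumerated scheme, e.g. through adjacent-clash
#'   states that the uncoupled chain potential does not penalize),
#'   `coverage_fraction`, `class_coverage_fraction`.
#' @export
coverage_report <- function(bank_paths, pathways, classes) {
  strs <- vapply(pathways, event_string, character(1L))
  idx_of <- seq_along(strs); names(idx_of) <- strs
  class_of <- integer(length(strs))
  for (k in seq_along(classes)) class_of[classes[[k]]$members] <- k
  member_pw <- rep(NA_integer_, length(bank_paths))
  multi <- integer(); unmatched <- integer()
  for (m in seq_along(bank_paths)) {
    ev <- trace_events(bank_paths[[m]])
    # the trace is an enumerated pathway only if every crossing is a
    # monotone g- -> t or t -> g+ step (no cis hops, no back-crossings)
    monotone <- nrow(ev) == 0L || all(ev$to == ev$from + 1L)
    if (!monotone) { multi <- c(multi, m); next }
    hit <- idx_of[paste(ev$dihedral, collapse = ".")]
    if (!is.na(hit)) member_pw[m] <- hit else unmatched <- c(unmatched, m)
  }
  found_pw <- sort(unique(member_pw[!is.na(member_pw)]))
  found_cl <- sort(unique(class_of[found_pw]))
  structure(list(found_pathways = found_pw,
                 total_pathways = length(pathways),
                 found_classes = found_cl,
                 total_classes = length(classes),
                 pathway_of_member = member_pw,
                 multi_crossing = multi,
                 unmatched = unmatched,
                 coverage_fraction = length(found_pw) / length(pathways),
                 class_coverage_fraction =
                   length(found_cl) / length(classes)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d / %d pathways, %d / %d classes; %d multi-crossing member(s)\n",
              length(x$found_pathways), x$total_pathways,
              length(x$found_classes), x$total_classes,
              length(x$multi_crossing)))
  invisible(x)
}
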