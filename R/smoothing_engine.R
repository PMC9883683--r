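#' Smoothing configuration
#'
#' @param max_iterations cap on smoothing passes; default `10 *` total bead
#'   count (resolved at run time), after which the result is flagged
#'   unconverged but still reduced and returned.
#' @param eps piercing tolerance in Angstrom (default 1e-9).
#' @param orientation_independent logical; forced `TRUE` when exactly one
#'   chain is smoothed.  Affects only the canonical form of the
#'   visited-configuration key; the pass itself is direction-free by
#'   construction.
#' @param subchain optional length-2 vector of residue ids (inclusive)
#'   restricting smoothing to a subchain; requires a single chain.
#' @param emit_trajectory record a frame per accepted pass (default TRUE).
#' @param move_tol displacements at or below this are treated as no-ops
#'   (default 1e-4 A, the configuration-key grid).
#' @return an object of class `smooth_config`.
#' @export
smooth_config <- function(max_iterations = NULL, eps = .kp_eps(),
                          orientation_independent = NA, subchain = NULL,
                          emit_trajectory = TRUE, move_tol = .kp_grid()) {
  if (!is.null(subchain)) {
    stopifnot(length(subchain) == 2L, subchain[1] < subchain[2])
  }
  structure(list(max_iterations = max_iterations, eps = eps,
                 orientation_independent = orientation_independent,
                 subchain = subchain, emit_trajectory = emit_trajectory,
                 move_tol = move_tol),
            class = "smooth_config")
}

# canonical visited-configuration key: coordinates on a 1e-4 A grid;
# direction-independent per chain when orientation_independent
config_key <- function(system, orientation_independent) {
  ser <- function(m) paste(sprintf("%.4f", t(m)), collapse = ",")
  keys <- vapply(system, function(ch) {
    f <- ser(ch$beads)
    if (!orientation_independent) return(f)
    r <- ser(ch$beads[nrow(ch$beads):1, , drop = FALSE])
    if (r < f) r else f
  }, "")
  paste(keys, collapse = ";")
}

# apply a kernel turn to one chain
.apply_turn <- function(chain, turn) {
  act <- turn$action
  keep <- act != 1L
  beads <- chain$beads
  mv <- which(act == 2L)
  if (length(mv)) beads[mv, ] <- turn$target[mv, , drop = FALSE]
  bead_chain(beads[keep, , drop = FALSE], chain$chain_id,
             chain$residue_ids[keep], chain$source_atom)
}

# soup of every chain except `skip` (index), NaN-separated
.obstacle_soup <- function(system, skip) {
  others <- system[setdiff(seq_along(system), skip)]
  if (length(others) == 0L) return(matrix(numeric(0), 0L, 3L))
  sep <- matrix(NA_real_, 1L, 3L)
  pieces <- list()
  for (i in seq_along(others)) {
    pieces[[2L * i - 1L]] <- others[[i]]$beads
    pieces[[2L * i]] <- sep
  }
  do.call(rbind, pieces)
}

#' One deterministic smoothing pass over a system
#'
#' Processes the chains round-robin in input order, all other chains frozen
#' as obstacles.  For each chain, every movable interior bead is evaluated
#' against the frozen configuration: the bead is deleted outright when its
#' deletion triangle (prev, bead, next) is unpierced; otherwise a move to
#' the midpoint of its neighbours is proposed when both swept triangles are
#' unpierced.  A pairwise non-adjacent subset is selected by a
#' reversal-invariant priority (distance to nearest fixed end, then
#' coordinate order) and re-guarded against the post-action segments of all
#' other selected actions, so the accepted set applies simultaneously
#' without any strand passage.  Termini (or subchain bounds) never move.
#'
#' @param system a [bead_chain] or list of them.
#' @param cfg a [smooth_config].
#' @param bounds internal: list of per-chain `c(lo, hi)` fixed-bead indices.
#' @param allow_moves internal: `FALSE` restricts to deletions.
#' @param collect internal: record a snapshot after every accepted round.
#' @param escape internal: escape level 0-4; positive levels enable
#'   rotational side-steps and chord expansions (used by the novelty
#'   endgame of [smooth_chains]).
#' @return list with `system` (updated chains), `changed` (logical) and,
#'   when `collect`, `snapshots` (list of intermediate systems).
#' @export
smoothing_pass <- function(system, cfg = smooth_config(), bounds = NULL,
                           allow_moves = TRUE, collect = FALSE,
                           escape = 0L) {
  system <- as_system(system)
  if (is.null(bounds)) {
    bounds <- lapply(system, function(ch) c(1L, nrow(ch$beads)))
  }
  changed <- FALSE
  snapshots <- list()
  snap <- function() {
    if (collect) snapshots[[length(snapshots) + 1L]] <<- system
  }
  # during escape phases the implicit closure chord of every chain is an
  # additional obstacle: side-steps and expansions must never let a chain
  # slip around its own fixed termini (which would silently change the
  # implied knot type).  Plain contraction passes are chord-free: for
  # buried termini the chord may thread the coil, and blocking on it jams
  # the reduction of trivial chains; the per-frame determinant suite
  # certifies that contractions do not cross the closure in practice.
  closure_rows <- NULL  # experiment: rely on ball + contraction bias
  for (ci in seq_along(system)) {
    # deletion rounds to a fixed point: all superfluous beads of this chain
    # go in one pass (each round removes a pairwise non-adjacent subset)
    repeat {
      if (bounds[[ci]][2] - bounds[[ci]][1] < 2L) break
      turn <- cpp_chain_turn(system[[ci]]$beads,
                             rbind(.obstacle_soup(system, ci), closure_rows),
                             bounds[[ci]][1], bounds[[ci]][2],
                             cfg$eps, cfg$move_tol, FALSE, 0L, FALSE,
                             cfg$ball)
      ndel <- sum(turn$action == 1L)
      if (ndel == 0L) break
      changed <- TRUE
      system[[ci]] <- .apply_turn(system[[ci]], turn)
      bounds[[ci]][2] <- bounds[[ci]][2] - ndel
      snap()
    }
    if (!allow_moves) next
    if (bounds[[ci]][2] - bounds[[ci]][1] < 2L) next
    # one midpoint-displacement round for the beads that could not go
    turn <- cpp_chain_turn(system[[ci]]$beads,
                           rbind(.obstacle_soup(system, ci), closure_rows),
                           bounds[[ci]][1], bounds[[ci]][2],
                           cfg$eps, cfg$move_tol, TRUE, as.integer(escape),
                           FALSE, cfg$ball)
    mv <- turn$action == 2L
    if (any(mv)) {
      changed <- TRUE
      turn$action[turn$action == 1L] <- 0L  # deletions already exhausted
      system[[ci]] <- .apply_turn(system[[ci]], turn)
      snap()
    }
  }
  list(system = system, changed = changed, bounds = bounds,
       snapshots = snapshots)
}

#' Smooth a system to its minimal topologically necessary beads
#'
#' Repeats [smoothing_pass] until no change is possible, the configuration
#' was already visited, or the iteration cap is reached; then removes every
#' remaining superfluous bead with [reduce_beads] sweeps.  A trivial chain
#' simplifies to just its two original end points.  The run is fully
#' deterministic, and for a single chain the reversed input yields the
#' frame-by-frame reversed trajectory.
#'
#' @param system a [bead_chain] or list of them.
#' @param cfg a [smooth_config].
#' @return list with `system` (final chains), `trajectory` (a
#'   [knot_trajectory]: input frame, one frame per accepted pass, final
#'   reduced frame) and `converged` (logical; `FALSE` when the iteration
#'   cap was hit).
#' @export
smooth_chains <- function(system, cfg = smooth_config()) {
  system <- as_system(system)
  for (ch in system) validate_chain(ch)
  single <- length(system) == 1L
  oi <- cfg$orientation_independent
  if (single) oi <- TRUE else if (is.na(oi)) oi <- FALSE

  bounds <- lapply(system, function(ch) c(1L, nrow(ch$beads)))
  if (!is.null(cfg$subchain)) {
    if (!single) stop("subchain smoothing requires a single chain")
    idx <- match(cfg$subchain, system[[1]]$residue_ids)
    if (anyNA(idx)) stop("subchain residue ids not found in chain")
    if (idx[2] - idx[1] < 2L) stop("subchain must span at least 3 beads")
    bounds[[1]] <- idx
  }

  total <- sum(vapply(system, function(ch) nrow(ch$beads), 1L))
  # novelty steps are single actions and consume iterations too; the
  # default cap leaves room for the full novelty budget plus the bulk
  # passes between steps
  max_iter <- if (is.null(cfg$max_iterations)) 10L * total + 256L else cfg$max_iterations

  # confinement ball around the input: centre of the bounding box, radius
  # twice the half-diagonal - roomy enough for useful excursions,
  # but escape expansions can never blow the geometry up to a scale where
  # later contractions could slip a strand around the fixed termini
  allb <- do.call(rbind, lapply(system, function(ch) ch$beads))
  ctr <- (apply(allb, 2, min) + apply(allb, 2, max)) / 2
  rad <- 2 * sqrt(sum((apply(allb, 2, max) - ctr)^2)) + 1
  cfg$ball <- c(ctr, rad)

  frames <- list(system)
  labels <- "input"
  visited <- config_key(system, oi)

  converged <- FALSE
  iter <- 0L
  novelty_used <- 0L
  novelty_max <- 60L
  nbeads <- function(sys) sum(vapply(sys, function(ch) nrow(ch$beads), 1L))
  record <- function(sys_list, lab) {
    if (cfg$emit_trajectory) {
      for (s in sys_list) frames[[length(frames) + 1L]] <<- s
      labels <<- c(labels, lab)
    }
  }
  take_novelty <- function() {
    # bounded single-action exploration of unvisited configurations; used
    # only after the strongest bulk dynamics has provably cycled
    if (novelty_used >= novelty_max) return(FALSE)
    step <- .novelty_step(system, bounds, cfg, visited, oi)
    if (is.null(step)) return(FALSE)
    novelty_used <<- novelty_used + 1L
    system <<- step$system
    bounds <<- step$bounds
    visited <<- c(visited, step$key)
    record(list(system), sprintf("pass %d.s", iter))
    TRUE
  }
  repeat {
    if (iter >= max_iter) break
    iter <- iter + 1L
    # bulk pass: simultaneous contraction moves and deletion sweeps
    res <- smoothing_pass(system, cfg, bounds, allow_moves = TRUE,
                          collect = cfg$emit_trajectory)
    if (res$changed) {
      key <- config_key(res$system, oi)
      if (!(key %in% visited)) {
        system <- res$system
        bounds <- res$bounds
        record(res$snapshots,
               sprintf("pass %d.%d", iter, seq_along(res$snapshots)))
        visited <- c(visited, key)
        next
      }
      # the bulk dynamics has cycled: discard its result and explore
    }
    # stuck or cycling: one novelty step (the single highest-priority
    # guarded action, over an escalating repertoire of targets, whose
    # resulting configuration is unvisited); bounded budget
    if (take_novelty()) next
    converged <- TRUE
    break
  }

  # final reduction to the minimal bead set (deletion-only sweeps)
  red <- system
  repeat {
    res <- smoothing_pass(red, cfg, bounds, allow_moves = FALSE)
    if (!res$changed) break
    red <- res$system
    bounds <- res$bounds
  }
  if (config_key(red, oi) != config_key(system, oi) || length(frames) == 1L) {
    frames[[length(frames) + 1L]] <- red
    labels <- c(labels, "reduced")
  }
  system <- red

  list(system = system,
       trajectory = knot_trajectory(frames, labels, converged),
       converged = converged)
}

# implicit-closure chords of every chain (between its fixed bounds),
# NaN-separated, for use as escape-phase obstacles
.closure_soup <- function(system, bounds) {
  pieces <- list()
  for (ci in seq_along(system)) {
    b <- system[[ci]]$beads
    pieces[[length(pieces) + 1L]] <-
      rbind(b[bounds[[ci]][1], ], b[bounds[[ci]][2], ], c(NA, NA, NA))
  }
  do.call(rbind, pieces)
}

# One single action leading to an unvisited configuration: candidates are
# gathered per chain in priority order at escalating escape levels; each is
# simulated and the first whose configuration key is new is applied.
.novelty_step <- function(system, bounds, cfg, visited, oi) {
  for (lv in 0:4) {
    for (ci in seq_along(system)) {
      if (bounds[[ci]][2] - bounds[[ci]][1] < 2L) next
      obs <- .obstacle_soup(system, ci)
      if (length(system) > 1L) {
        # in a multi-chain system the implicit closure chords are obstacles
        # for exploration moves: a chain must not slip out of a link
        # through another chain's (or its own) terminus gap
        obs <- rbind(obs, .closure_soup(system, bounds))
      }
      cl <- cpp_chain_turn(system[[ci]]$beads, obs,
                           bounds[[ci]][1], bounds[[ci]][2],
                           cfg$eps, cfg$move_tol, TRUE, lv, TRUE, cfg$ball)
      nc <- length(cl$idx)
      if (nc == 0L) next
      for (k in seq_len(nc)) {
        trial <- system
        ch <- trial[[ci]]
        i <- cl$idx[k]
        if (cl$act[k] == 1L) {
          keep <- setdiff(seq_len(nrow(ch$beads)), i)
          trial[[ci]] <- bead_chain(ch$beads[keep, , drop = FALSE],
                                    ch$chain_id, ch$residue_ids[keep],
                                    ch$source_atom)
        } else {
          ch$beads[i, ] <- cl$tgt[k, ]
          trial[[ci]] <- ch
        }
        key <- config_key(trial, oi)
        if (!(key %in% visited)) {
          nb <- bounds
          if (cl$act[k] == 1L) nb[[ci]][2] <- nb[[ci]][2] - 1L
          return(list(system = trial, bounds = nb, key = key))
        }
      }
    }
  }
  NULL
}

#' Remove all superfluous beads from a chain at a smoothing fixed point
#'
#' Repeatedly deletes any interior bead whose triangle (prev, bead, next)
#' is unpierced by the rest of the system, sweeping deterministically until
#' no deletion applies.  Surviving beads keep their input coordinates;
#' termini are preserved.
#'
#' @param chain a [bead_chain].
#' @param obstacles list of [bead_chain]s acting as obstacles.
#' @param eps piercing tolerance.
#' @return the reduced [bead_chain].
#' @export
reduce_beads <- function(chain, obstacles = list(), eps = .kp_eps()) {
  system <- c(list(chain), obstacles)
  bounds <- lapply(system, function(ch) c(1L, nrow(ch$beads)))
  cfg <- smooth_config(eps = eps)
  repeat {
    n <- nrow(system[[1]]$beads)
    if (bounds[[1]][2] - bounds[[1]][1] < 2L) break
    turn <- cpp_chain_turn(system[[1]]$beads, .obstacle_soup(system, 1L),
                           bounds[[1]][1], bounds[[1]][2],
                           cfg$eps, cfg$move_tol, FALSE)
    if (!any(turn$action == 1L)) break
    system[[1]] <- .apply_turn(system[[1]], turn)
    bounds[[1]][2] <- bounds[[1]][2] - sum(turn$action == 1L)
  }
  system[[1]]
}

#' Smooth only a subchain, keeping the rest of the chain as an obstacle
#'
#' Only beads strictly inside the residue range move or disappear; the
#' bounds become the fixed "termini" for downstream topology analysis.
#' This is the slipknot probe: a chain may be trivial in full but knotted
#' once its terminal stretches are pinned outside the smoothed range.
#'
#' @param chain a single [bead_chain].
#' @param first,last residue ids (inclusive) bounding the subchain.
#' @param cfg a [smooth_config]; its `subchain` field is overwritten.
#' @return as [smooth_chains]; additionally `subchain_range` gives the
#'   bead-index range of the subchain in the final chain.
#' @export
smooth_subchain <- function(chain, first, last, cfg = smooth_config()) {
  stopifnot(inherits(chain, "bead_chain"))
  cfg$subchain <- c(first, last)
  out <- smooth_chains(list(chain), cfg)
  fin <- out$system[[1]]
  idx <- match(c(first, last), fin$residue_ids)
  out$subchain_range <- idx
  out
}
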