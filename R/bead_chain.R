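#' Bead chain: the backbone trace of one polymer chain
#'
#' A bead chain is an ordered sequence of 3D coordinates (in Angstrom), one
#' bead per traced backbone atom (CA by default), with parallel residue
#' labels and the chain identifier of its source.
#'
#' @param coords numeric matrix, n x 3, bead coordinates in Angstrom.
#' @param chain_id short text label (e.g. "A").
#' @param residue_ids integer vector parallel to the beads, strictly
#'   increasing.  Defaults to `1:n`.
#' @param source_atom atom name used for the trace (default `"CA"`).
#' @return an object of class `bead_chain`.
#' @export
#' @examples
#' bead_chain(cbind(c(0, 3.8, 7.6), 0, 0))
bead_chain <- function(coords, chain_id = "A", residue_ids = NULL,
                       source_atom = "CA") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n) {
    stop("residue_ids must be parallel to the beads")
  }
  dimnames(coords) <- NULL
  x <- structure(
    list(chain_id = as.character(chain_id), beads = coords,
         residue_ids = residue_ids, source_atom = as.character(source_atom)),
    class = "bead_chain"
  )
  x
}

#' Validate a bead chain for smoothing
#'
#' Checks the invariants required of chains admitted to smoothing: at least
#' two beads, consecutive beads distinct beyond the positional tolerance,
#' strictly increasing residue labels.
#'
#' @param chain a [bead_chain].
#' @param tol positional tolerance in Angstrom.
#' @return `chain`, invisibly; errors if invalid.
#' @export
validate_chain <- function(chain, tol = .kp_point_tol()) {
  stopifnot(inherits(chain, "bead_chain"))
  n <- nrow(chain$beads)
  if (n < 2L) stop("chain '", chain$chain_id, "' has fewer than 2 beads")
  if (length(chain$residue_ids) != n) stop("residue_ids not parallel to beads")
  if (any(diff(chain$residue_ids) <= 0L)) {
    stop("residue_ids must strictly increase along chain '", chain$chain_id, "'")
  }
  d <- sqrt(rowSums((chain$beads[-1, , drop = FALSE] -
                       chain$beads[-n, , drop = FALSE])^2))
  if (any(d <= tol)) {
    stop("consecutive coincident beads in chain '", chain$chain_id, "'")
  }
  invisible(chain)
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain %s: %d beads, atom %s, residues %d..%d>\n",
              x$chain_id, nrow(x$beads), x$source_atom,
              x$residue_ids[1], x$residue_ids[length(x$residue_ids)]))
  invisible(x)
}

#' Reverse the traversal direction of a chain
#'
#' Beads are reversed; residue labels keep increasing order by negating and
#' reversing, preserving relative spacing.
#'
#' @param chain a [bead_chain].
#' @return the reversed [bead_chain].
#' @export
reverse_chain <- function(chain) {
  n <- nrow(chain$beads)
  bead_chain(chain$beads[n:1, , drop = FALSE], chain$chain_id,
             rev(-chain$residue_ids), chain$source_atom)
}

# coerce single chain to a system (list of chains)
as_system <- function(x) {
  if (inherits(x, "bead_chain")) list(x) else x
}

#' Smoothing trajectory
#'
#' Ordered sequence of whole-system snapshots, one per accepted smoothing
#' pass; frame 1 is the input system, the last frame the reduced system.
#'
#' @param frames list of systems (each a list of [bead_chain]s).
#' @param step_labels character vector parallel to frames.
#' @param converged logical; `FALSE` when the iteration cap was hit.
#' @return an object of class `knot_trajectory`.
#' @export
knot_trajectory <- function(frames, step_labels, converged = TRUE) {
  stopifnot(length(frames) == length(step_labels))
  structure(list(frames = frames, step_labels = step_labels,
                 converged = converged),
            class = "knot_trajectory")
}

#' @export
print.knot_trajectory <- function(x, ...) {
  nb <- function(sys) sum(vapply(sys, function(ch) nrow(ch$beads), 1L))
  cat(sprintf("<knot_trajectory: %d frames, %d -> %d beads%s>\n",
              length(x$frames), nb(x$frames[[1]]),
              nb(x$frames[[length(x$frames)]]),
              if (x$converged) "" else ", UNCONVERGED"))
  invisible(x)
}
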