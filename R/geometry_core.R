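#' Does a 3D segment pierce a triangle?
#'
#' Conservative predicate used as the topology guard of the smoother: any
#' transversal crossing of the triangle interior, and any approach within
#' `eps` of the closed triangle (boundary included), counts as piercing.
#' Refusing a doubtful move can only under-smooth; it can never change the
#' chain topology.
#'
#' @param p,q segment endpoints (numeric length-3, Angstrom).
#' @param a,b,c triangle vertices.
#' @param eps length tolerance in Angstrom.
#' @return `TRUE` if the segment pierces the triangle.  A degenerate
#'   (near-zero-area) triangle is handled as its edge hull: piercing then
#'   means eps-proximity to the hull.
#' @export
#' @examples
#' segment_pierces_triangle(c(.5, .5, -1), c(.5, .5, 1),
#'                          c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
segment_pierces_triangle <- function(p, q, a, b, c, eps = .kp_eps()) {
  if (sqrt(sum((p - q)^2)) <= .kp_point_tol()) {
    stop("degenerate segment")
  }
  cpp_seg_tri_pierce(as.double(p), as.double(q), as.double(a),
                     as.double(b), as.double(c), eps)
}

#' Is a triangle degenerate (vertices collinear beyond area tolerance)?
#' @param a,b,c triangle vertices.
#' @param area_tol area tolerance (Angstrom^2).
#' @return logical.
#' @export
triangle_degenerate <- function(a, b, c, area_tol = 1e-12) {
  cpp_tri_degenerate(as.double(a), as.double(b), as.double(c), area_tol)
}

# Flatten a system into the NaN-separated "segment soup" used by the kernel.
# Returns the soup matrix plus, for each chain, the soup row of its first bead.
system_soup <- function(system) {
  system <- as_system(system)
  mats <- lapply(system, function(ch) ch$beads)
  offs <- integer(length(mats))
  sep <- matrix(NA_real_, 1L, 3L)
  pieces <- list()
  row <- 0L
  for (i in seq_along(mats)) {
    offs[i] <- row + 1L
    pieces[[length(pieces) + 1L]] <- mats[[i]]
    row <- row + nrow(mats[[i]])
    if (i < length(mats)) {
      pieces[[length(pieces) + 1L]] <- sep
      row <- row + 1L
    }
  }
  list(soup = do.call(rbind, pieces), offsets = offs)
}

#' Is a triangle pierced by any segment of a system?
#'
#' Scans every segment of every chain in the system against the triangle.
#' Segments listed in `excluded` (the triangle's own side segments) are
#' skipped outright.  Segments that share a vertex with the triangle are
#' tested with the shared-vertex neighbourhood trimmed away, so a touch
#' exactly at a common chain vertex does not count, while a genuine pass
#' through the triangle interior does.
#'
#' @param tri 3 x 3 matrix, one vertex per row.
#' @param system a [bead_chain] or list of them.
#' @param excluded integer matrix or data frame with columns `chain` (index
#'   into the system) and `seg` (1-based index of the segment's first bead):
#'   segments excluded from the scan.  `NULL` for none.
#' @param eps length tolerance in Angstrom.
#' @return logical.
#' @export
triangle_is_pierced <- function(tri, system, excluded = NULL, eps = .kp_eps()) {
  tri <- as.matrix(tri)
  storage.mode(tri) <- "double"
  sp <- system_soup(system)
  skip <- integer(0)
  if (!is.null(excluded)) {
    excluded <- as.matrix(excluded)
    skip <- sp$offsets[excluded[, 1L]] + excluded[, 2L] - 1L
  }
  cpp_tri_pierced_soup(tri, sp$soup, eps, as.integer(skip))
}

#' Proper crossing of two 2D segments with projection depth
#'
#' Used to enumerate the crossings of a planar projection.  Only proper
#' transversal interior intersections are returned; endpoint touches,
#' (near-)parallel overlaps and depth ties within `eps` are degeneracies
#' that make the caller re-project.
#'
#' @param p1,q1 endpoints of the first 2D segment.
#' @param d1 depths (projection distances) at `p1` and `q1` (length 2).
#' @param p2,q2,d2 likewise for the second segment.
#' @param eps tolerance.
#' @return `NULL` if the segments do not cross; the string `"degenerate"`
#'   for a degenerate configuration; otherwise a list with `point`, `u1`,
#'   `u2` (interior parameters in (0,1)), `depth1`, `depth2` and
#'   `over_segment` (1 or 2: which segment passes nearer the viewer, i.e.
#'   has *greater* depth, depth being the coordinate along the viewing
#'   axis).
#' @export
segments_cross_2d <- function(p1, q1, d1, p2, q2, d2, eps = 1e-9) {
  r <- q1 - p1
  s <- q2 - p2
  lr <- sqrt(sum(r^2)); ls <- sqrt(sum(s^2))
  if (lr <= eps || ls <= eps) return("degenerate")
  denom <- r[1] * s[2] - r[2] * s[1]
  # near-parallel: no crossing unless collinear with overlapping extents
  if (abs(denom) <= eps * lr * ls) {
    w <- p2 - p1
    cr <- abs(w[1] * r[2] - w[2] * r[1]) / lr
    if (cr <= eps) {
      s1 <- sum(w * r) / lr^2
      s2 <- s1 + sum(s * r) / lr^2
      marg <- eps * 1e3
      if (max(s1, s2) > marg && min(s1, s2) < 1 - marg) return("degenerate")
    }
    return(NULL)
  }
  w <- p2 - p1
  u1 <- (w[1] * s[2] - w[2] * s[1]) / denom
  u2 <- (w[1] * r[2] - w[2] * r[1]) / denom
  margin <- eps * 1e3  # parameter-space guard band near endpoints
  if (u1 <= margin || u1 >= 1 - margin || u2 <= margin || u2 >= 1 - margin) {
    if (u1 < -margin || u1 > 1 + margin || u2 < -margin || u2 > 1 + margin) {
      return(NULL)
    }
    return("degenerate")
  }
  depth1 <- d1[1] + u1 * (d1[2] - d1[1])
  depth2 <- d2[1] + u2 * (d2[2] - d2[1])
  if (abs(depth1 - depth2) <= eps) return("degenerate")
  list(point = p1 + u1 * r, u1 = u1, u2 = u2,
       depth1 = depth1, depth2 = depth2,
       over_segment = if (depth1 > depth2) 1L else 2L)
}
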