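#' Choose a deterministic generic projection for an open chain
#'
#' Tries the identity rotation first, then a fixed golden-angle spiral of
#' viewing directions, and returns the first rotation whose z-projection of
#' the chain is generic: no degenerate segment crossings, no two crossings
#' (or crossing/bead) closer than the tolerance, every crossing pairing one
#' odd and one even passage, and both termini able to reach the outside of
#' the projected drawing along their outward rays, so the implicit closure
#' between last and first passage can be drawn without any new crossing.
#'
#' @param chain a [bead_chain] (or a list of chains for a joint projection).
#' @param max_candidates number of viewing directions tried (default 10000).
#' @param closed treat the chain as a closed polygon (used by the
#'   determinant oracle); skips the termini-escape and parity checks.
#' @return a 3 x 3 rotation matrix (apply as `beads %*% t(R)`; rows 1-2
#'   span the projection plane, row 3 is the viewing depth).
#' @export
choose_projection <- function(chain, max_candidates = 10000L, closed = FALSE) {
  system <- as_system(chain)
  for (R in .projection_candidates(max_candidates)) {
    d <- try(.project_diagram(system, R, closed = closed), silent = TRUE)
    if (inherits(d, "try-error")) next
    if (!closed) {
      if (!.parity_ok(d)) next
      if (!.termini_escape(system, R)) next
    }
    return(R)
  }
  stop("no generic projection found among ", max_candidates, " candidates")
}

# deterministic candidate rotations: identity, then golden-angle spiral
.projection_candidates <- function(n) {
  out <- vector("list", n)
  out[[1]] <- diag(3)
  ga <- pi * (3 - sqrt(5))
  for (k in 2:n) {
    z <- 1 - 2 * (k - 1.5) / (n - 1)
    r <- sqrt(max(0, 1 - z^2))
    th <- ga * (k - 1)
    v <- c(r * cos(th), r * sin(th), z)
    out[[k]] <- .rotation_to_z(v, th)
  }
  out
}

# orthonormal rotation taking unit vector v to the z axis, with an in-plane
# twist so repeated near-degenerate views differ
.rotation_to_z <- function(v, twist = 0) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  ct <- cos(twist); st <- sin(twist)
  rbind(ct * e1 + st * e2, -st * e1 + ct * e2, v)
}

# enumerate crossings of the z-projection; stop("degenerate...") on any
# degeneracy.  system: list of chains; closed: last->first segment added
# (single chain only).  Returns the raw crossing table.  Fully vectorized
# over segment pairs (the semantics match segments_cross_2d).
.project_diagram <- function(system, R, closed = FALSE, eps = 1e-7) {
  chains2d <- lapply(system, function(ch) ch$beads %*% t(R))
  px <- py <- qx <- qy <- dp <- dq <- chn <- pos <- numeric(0)
  for (ci in seq_along(chains2d)) {
    m <- chains2d[[ci]]
    n <- nrow(m)
    i <- seq_len(n - 1L); j <- seq(2L, n)
    if (closed) { i <- c(i, n); j <- c(j, 1L) }
    px <- c(px, m[i, 1]); py <- c(py, m[i, 2])
    qx <- c(qx, m[j, 1]); qy <- c(qy, m[j, 2])
    dp <- c(dp, m[i, 3]); dq <- c(dq, m[j, 3])
    chn <- c(chn, rep(ci, length(i))); pos <- c(pos, seq_along(i))
  }
  ns <- length(px)
  rx <- qx - px; ry <- qy - py
  len <- sqrt(rx^2 + ry^2)
  if (any(len <= 1e3 * eps)) stop("degenerate: short segment")
  if (ns < 2L) return(list())

  nseg_chain <- vapply(chains2d, function(m) nrow(m) - 1L + as.integer(closed), 1L)
  # all unordered pairs, a-major order
  ia <- rep.int(seq_len(ns - 1L), times = (ns - 1L):1L)
  ib <- unlist(lapply(seq_len(ns - 1L), function(a) seq(a + 1L, ns)),
               use.names = FALSE)
  dd <- abs(pos[ia] - pos[ib])
  same <- chn[ia] == chn[ib]
  adj <- same & (dd == 1L | (closed & dd == nseg_chain[chn[ia]] - 1L))
  keep <- which(!adj)
  ia <- ia[keep]; ib <- ib[keep]

  denom <- rx[ia] * ry[ib] - ry[ia] * rx[ib]
  wx <- px[ib] - px[ia]; wy <- py[ib] - py[ia]
  par <- abs(denom) <= eps * len[ia] * len[ib]
  if (any(par)) {
    pa <- ia[par]; pb <- ib[par]
    crd <- abs(wx[par] * ry[pa] - wy[par] * rx[pa]) / len[pa]
    col <- crd <= eps
    if (any(col)) {
      # collinear: degenerate only when the extents overlap along the line
      ca <- pa[col]; cb <- pb[col]
      s1 <- (wx[par][col] * rx[ca] + wy[par][col] * ry[ca]) / len[ca]^2
      s2 <- s1 + (rx[cb] * rx[ca] + ry[cb] * ry[ca]) / len[ca]^2
      lo <- pmin(s1, s2); hi <- pmax(s1, s2)
      marg <- eps * 1e3
      if (any(hi > marg & lo < 1 - marg)) stop("degenerate: crossing")
    }
  }
  ok <- !par
  u1 <- u2 <- rep(NA_real_, length(ia))
  u1[ok] <- (wx[ok] * ry[ib[ok]] - wy[ok] * rx[ib[ok]]) / denom[ok]
  u2[ok] <- (wx[ok] * ry[ia[ok]] - wy[ok] * rx[ia[ok]]) / denom[ok]
  margin <- eps * 1e3
  inner <- ok & u1 > margin & u1 < 1 - margin & u2 > margin & u2 < 1 - margin
  outer <- ok & (u1 < -margin | u1 > 1 + margin | u2 < -margin | u2 > 1 + margin)
  if (any(ok & !inner & !outer)) stop("degenerate: crossing")
  hit <- which(inner)
  if (length(hit) == 0L) return(list())
  a <- ia[hit]; b <- ib[hit]
  h1 <- u1[hit]; h2 <- u2[hit]
  # crossing too close to a bead projection
  if (any(pmin(h1, 1 - h1) * len[a] <= eps * 1e2) ||
      any(pmin(h2, 1 - h2) * len[b] <= eps * 1e2)) {
    stop("degenerate: crossing at bead")
  }
  depth1 <- dp[a] + h1 * (dq[a] - dp[a])
  depth2 <- dp[b] + h2 * (dq[b] - dp[b])
  if (any(abs(depth1 - depth2) <= eps)) stop("degenerate: crossing")
  cx <- px[a] + h1 * rx[a]; cy <- py[a] + h1 * ry[a]
  if (length(hit) >= 2L) {
    pd <- stats::dist(cbind(cx, cy))
    if (min(pd) <= eps * 1e2) stop("degenerate: crossing pair")
  }
  chir <- sign(rx[a] * ry[b] - ry[a] * rx[b])
  lapply(seq_along(hit), function(k) list(
    chain1 = chn[a[k]], t1 = pos[a[k]] + h1[k],
    chain2 = chn[b[k]], t2 = pos[b[k]] + h2[k],
    over1 = depth1[k] > depth2[k],
    point = c(cx[k], cy[k]),
    chir = chir[k]))
}

# each crossing must pair an odd and an even passage (single chain)
.parity_ok <- function(cross) {
  if (length(cross) == 0L) return(TRUE)
  t_all <- c(vapply(cross, function(x) x$t1, 1),
             vapply(cross, function(x) x$t2, 1))
  r <- rank(t_all)
  nc <- length(cross)
  all((r[seq_len(nc)] + r[seq_len(nc) + nc]) %% 2 == 1)
}

# can each terminus walk to infinity along its outward ray without hitting
# any projected segment?
.termini_escape <- function(system, R) {
  pts <- do.call(rbind, lapply(system, function(ch) ch$beads %*% t(R)))[, 1:2,
                                                                        drop = FALSE]
  centroid <- colMeans(pts)
  far <- 10 * (max(pts) - min(pts) + 1)
  for (ch in system) {
    m <- (ch$beads %*% t(R))[, 1:2, drop = FALSE]
    n <- nrow(m)
    for (tip in c(1L, n)) {
      dir <- m[tip, ] - centroid
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) return(FALSE)
      ray_end <- m[tip, ] + dir / nd * far
      inner <- if (tip == 1L) 2L else n - 1L
      for (ch2 in system) {
        m2 <- (ch2$beads %*% t(R))[, 1:2, drop = FALSE]
        for (s in seq_len(nrow(m2) - 1L)) {
          if (identical(ch2$chain_id, ch$chain_id)) {
            # segments at the terminus share its vertex; skip them
            if (tip == 1L && s == 1L) next
            if (tip == n && s == n - 1L) next
          }
          r <- segments_cross_2d(m[tip, ], ray_end, c(0, 0),
                                 m2[s, ], m2[s + 1L, ], c(0, 0), 1e-9)
          if (identical(r, "degenerate") || is.list(r)) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Build the planar diagram of a chain under a rotation
#'
#' Records every transversal crossing between non-adjacent projected
#' segments, in traversal order, with over/under decided by projection
#' depth and the local handedness of each crossing (needed to trace the
#' faces of the diagram).
#'
#' @param chain a [bead_chain].
#' @param rotation a rotation from [choose_projection].
#' @param closed treat the chain as a closed polygon.
#' @return an object of class `planar_diagram`: passages in traversal
#'   order (`crossing`, `over`), per-crossing handedness `chir`, crossing
#'   positions, and the source metadata.
#' @export
build_diagram <- function(chain, rotation = choose_projection(chain),
                          closed = FALSE) {
  system <- as_system(chain)
  stopifnot(length(system) == 1L)
  cross <- .project_diagram(system, rotation, closed = closed)
  .diagram_from_crossings(cross, n_chains = 1L, rotation = rotation)
}

# shared: crossing list -> planar_diagram (passages sorted by position)
.diagram_from_crossings <- function(cross, n_chains, rotation) {
  nc <- length(cross)
  if (nc == 0L) {
    return(structure(list(n = 0L, seq = integer(0), over = logical(0),
                          chir = integer(0), chain_of = integer(0),
                          t = numeric(0), points = matrix(0, 0, 2),
                          rotation = rotation),
                     class = "planar_diagram"))
  }
  pass <- data.frame(
    crossing = rep(seq_len(nc), 2L),
    chain = c(vapply(cross, function(x) x$chain1, 1),
              vapply(cross, function(x) x$chain2, 1)),
    t = c(vapply(cross, function(x) x$t1, 1),
          vapply(cross, function(x) x$t2, 1)),
    over = c(vapply(cross, function(x) x$over1, TRUE),
             vapply(cross, function(x) !x$over1, TRUE))
  )
  pass <- pass[order(pass$chain, pass$t), , drop = FALSE]
  structure(list(
    n = nc,
    seq = pass$crossing,
    over = pass$over,
    chir = vapply(cross, function(x) as.integer(x$chir), 1L),
    chain_of = pass$chain,
    t = pass$t,
    points = do.call(rbind, lapply(cross, function(x) x$point)),
    rotation = rotation
  ), class = "planar_diagram")
}

#' @export
print.planar_diagram <- function(x, ...) {
  cat(sprintf("<planar_diagram: %d crossings>\n", x$n))
  invisible(x)
}

#' Dowker-Thistlethwaite code of a planar diagram
#'
#' Passages are numbered 1..2n along the chain from the N terminus; each
#' crossing pairs an odd and an even label (the implicit closure wraps the
#' numbering, no closure segment is constructed).  The output lists, for
#' odd labels 1, 3, 5, ..., the paired even label, negated when the
#' even-labelled passage is the over-strand.
#'
#' @param d a [build_diagram] result.
#' @return an object of class `dt_code` (integer vector of signed even
#'   values; empty for the unknot).
#' @export
dt_code <- function(d) {
  stopifnot(inherits(d, "planar_diagram"))
  n <- d$n
  if (n == 0L) return(new_dt_code(integer(0)))
  if (length(d$seq) != 2L * n) stop("invalid diagram: passage count mismatch")
  lab_of <- matrix(0L, n, 2L)  # crossing -> its two labels
  for (k in seq_along(d$seq)) {
    cr <- d$seq[k]
    lab_of[cr, if (lab_of[cr, 1] == 0L) 1L else 2L] <- k
  }
  over_at <- d$over
  vals <- integer(n)
  for (cr in seq_len(n)) {
    l1 <- lab_of[cr, 1]; l2 <- lab_of[cr, 2]
    odd <- if (l1 %% 2L == 1L) l1 else l2
    even <- if (l1 %% 2L == 1L) l2 else l1
    if (odd %% 2L != 1L || even %% 2L != 0L) {
      stop("invalid diagram: crossing pairs two labels of equal parity ",
           "(implicit closure would add crossings; re-project)")
    }
    vals[(odd + 1L) / 2L] <- if (over_at[even]) -even else even
  }
  new_dt_code(vals)
}

#' Construct a DT code object
#' @param values signed even integers (the code), in odd-label order.
#' @return an object of class `dt_code`.
#' @export
new_dt_code <- function(values) {
  structure(list(values = as.integer(values), n = length(values)),
            class = "dt_code")
}

#' @export
print.dt_code <- function(x, ...) {
  cat("DT:", if (x$n == 0L) "(empty - unknot)" else
    paste(x$values, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.dt_code <- function(x, ...) {
  if (x$n == 0L) "" else paste(x$values, collapse = " ")
}

#' Syntactic and realizability validation of a DT code
#'
#' Checks that the values are even, that their magnitudes are a permutation
#' of 2, 4, ..., 2n, and (for n <= 12) that the implied pairing is
#' realizable as a closed curve in the plane, by searching for a crossing
#' handedness assignment whose traced faces satisfy Euler's formula.
#'
#' @param code a [new_dt_code] (or plain integer vector).
#' @return logical.
#' @export
validate_dt <- function(code) {
  if (!inherits(code, "dt_code")) code <- new_dt_code(code)
  v <- code$values
  n <- length(v)
  if (n == 0L) return(TRUE)
  if (any(v %% 2L != 0L) || any(v == 0L)) return(FALSE)
  if (!setequal(abs(v), seq(2L, 2L * n, by = 2L))) return(FALSE)
  st <- .state_from_code(code)
  if (n > 12L) return(TRUE)  # syntactic only beyond brute-force reach
  !is.null(.realize_chirality(st$seq))
}

# dt_code -> rewrite-engine state (seq, over); chirality not implied
.state_from_code <- function(code) {
  v <- code$values
  n <- length(v)
  seqv <- integer(2L * n)
  over <- logical(2L * n)
  for (cr in seq_len(n)) {
    odd <- 2L * cr - 1L
    even <- abs(v[cr])
    seqv[odd] <- cr
    seqv[even] <- cr
    over[even] <- v[cr] < 0L
    over[odd] <- v[cr] > 0L
  }
  list(seq = seqv, over = over)
}

# state -> dt_code (labels = current positions)
.code_from_state <- function(st) {
  n <- length(st$seq) / 2L
  if (n == 0L) return(new_dt_code(integer(0)))
  first <- integer(max(st$seq))
  vals <- integer(n)
  k <- 0L
  for (pos in seq_along(st$seq)) {
    cr <- st$seq[pos]
    if (first[cr] == 0L) first[cr] <- pos
    else {
      a <- first[cr]; b <- pos
      odd <- if (a %% 2L == 1L) a else b
      even <- if (a %% 2L == 1L) b else a
      if (odd %% 2L == 0L) stop("state violates odd/even pairing")
      vals[(odd + 1L) / 2L] <- if (st$over[even]) -even else even
    }
  }
  new_dt_code(vals)
}
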