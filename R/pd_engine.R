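# Combinatorial planar-diagram engine.
#
# A diagram state is a list:
#   seq  - integer vector, length 2n: crossing id at each passage position
#          (traversal order, implicitly closed into a cycle)
#   over - logical, length 2n: is this passage the over-strand
#   chir - integer vector indexed by crossing id, +1/-1: local handedness,
#          defined relative to the traversal-earlier passage: +1 when the
#          second strand crosses left-to-right under the first's direction
#          (counter-clockwise dart order in1, in2, out1, out2)
#
# Edges are the 2n curve arcs between consecutive passages (edge k runs
# from position k to position k+1, cyclically).  Faces are traced from the
# rotation system; Euler's formula F = n + 2 certifies planarity.

# dart ids: tail of edge k = 2k-1 (at position k), head of edge k = 2k
# (at position wrap(k+1))
.pd_wrap <- function(k, m) ((k - 1L) %% m) + 1L

# face orbits of the rotation system; NULL if some vertex is inconsistent
.pd_faces <- function(seqv, chir) {
  m <- length(seqv)
  n <- m / 2L
  if (n == 0L) return(list())
  # positions of each crossing
  pos1 <- integer(n); pos2 <- integer(n)
  for (p in seq_len(m)) {
    cr <- seqv[p]
    if (pos1[cr] == 0L) pos1[cr] <- p else pos2[cr] <- p
  }
  # sigma: next dart counter-clockwise at the vertex
  sigma <- integer(2L * m)
  for (cr in seq_len(n)) {
    a <- pos1[cr]; b <- pos2[cr]
    in1 <- 2L * .pd_wrap(a - 1L, m); out1 <- 2L * a - 1L
    in2 <- 2L * .pd_wrap(b - 1L, m); out2 <- 2L * b - 1L
    cyc <- if (chir[cr] >= 0L) c(in1, in2, out1, out2) else c(in1, out2, out1, in2)
    for (i in 1:4) sigma[cyc[i]] <- cyc[.pd_wrap(i + 1L, 4L)]
  }
  # alpha: other dart of the same edge
  alpha <- function(d) if (d %% 2L == 1L) d + 1L else d - 1L
  phi_seen <- logical(2L * m)
  faces <- list()
  for (d0 in seq_len(2L * m)) {
    if (phi_seen[d0]) next
    d <- d0
    orbit <- integer(0)
    repeat {
      phi_seen[d] <- TRUE
      orbit <- c(orbit, d)
      d <- sigma[alpha(d)]
      if (d == d0) break
      if (phi_seen[d]) return(NULL)  # inconsistent map
    }
    faces[[length(faces) + 1L]] <- orbit
  }
  faces
}

# brute-force handedness realization: first chir assignment (deterministic
# enumeration) whose rotation system is planar (F = n + 2); NULL if none
.realize_chirality <- function(seqv) {
  n <- length(seqv) / 2L
  if (n == 0L) return(integer(0))
  if (n > 14L) stop("realization search limited to 14 crossings")
  for (mask in 0:(2^n - 1)) {
    chir <- ifelse(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L, -1L, 1L)
    f <- .pd_faces(seqv, chir)
    if (!is.null(f) && length(f) == n + 2L) return(chir)
  }
  NULL
}

# edges of a face orbit: dart d belongs to edge ceiling(d / 2)
.face_edges <- function(orbit) sort(unique((orbit + 1L) %/% 2L))

# positions bounding edge k: k and wrap(k+1)
.edge_pos <- function(k, m) c(k, .pd_wrap(k + 1L, m))

# ---- Reidemeister moves ----------------------------------------------------

# drop the listed passage positions, renumbering crossings compactly
.pd_drop_positions <- function(st, drop_pos) {
  keep <- setdiff(seq_along(st$seq), drop_pos)
  seqv <- st$seq[keep]
  over <- st$over[keep]
  old_ids <- sort(unique(seqv))
  map <- integer(max(c(old_ids, 0L)))
  map[old_ids] <- seq_along(old_ids)
  list(seq = map[seqv], over = over, chir = st$chir[old_ids])
}

# R1: remove the curl crossing whose two passages bound a monogon face
.pd_apply_r1 <- function(st, face) {
  m <- length(st$seq)
  k <- .face_edges(face)[1]
  pp <- .edge_pos(k, m)
  stopifnot(st$seq[pp[1]] == st$seq[pp[2]])
  .pd_drop_positions(st, pp)
}

# R2: remove the two crossings of a bigon face where one strand is over at
# both and the other under at both
.pd_apply_r2 <- function(st, face) {
  m <- length(st$seq)
  ee <- .face_edges(face)
  pp <- unique(c(.edge_pos(ee[1], m), .edge_pos(ee[2], m)))
  stopifnot(length(pp) == 4L)
  .pd_drop_positions(st, pp)
}

# is a bigon face R2-removable?
.pd_r2_ok <- function(st, face) {
  m <- length(st$seq)
  ee <- .face_edges(face)
  if (length(ee) != 2L) return(FALSE)
  p1 <- .edge_pos(ee[1], m); p2 <- .edge_pos(ee[2], m)
  if (length(unique(c(p1, p2))) != 4L) return(FALSE)
  crs <- unique(st$seq[c(p1, p2)])
  if (length(crs) != 2L) return(FALSE)
  (st$over[p1[1]] == st$over[p1[2]]) &&
    (st$over[p2[1]] == st$over[p2[2]]) &&
    (st$over[p1[1]] != st$over[p2[1]])
}

# R3 candidates on a trigon face: each edge whose two passages are both
# over or both under can slide across the opposite crossing
.pd_r3_edges <- function(st, face) {
  m <- length(st$seq)
  ee <- .face_edges(face)
  if (length(ee) != 3L) return(integer(0))
  pp <- c(.edge_pos(ee[1], m), .edge_pos(ee[2], m), .edge_pos(ee[3], m))
  if (length(unique(pp)) != 6L) return(integer(0))
  if (length(unique(st$seq[pp])) != 3L) return(integer(0))
  ok <- vapply(ee, function(k) {
    p <- .edge_pos(k, m)
    st$over[p[1]] == st$over[p[2]]
  }, TRUE)
  ee[ok]
}

# R3 slide: swap the passage contents across each of the three face edges.
# Crossing handedness is tied to the traversal order of a crossing's two
# passages; a swap across the wrap-around edge (positions 2n, 1) inverts
# that order for both crossings involved, so their chir flips.
.pd_apply_r3 <- function(st, face) {
  m <- length(st$seq)
  ee <- .face_edges(face)
  seqv <- st$seq; over <- st$over; chir <- st$chir
  for (k in ee) {
    p <- .edge_pos(k, m)
    a <- p[1]; b <- p[2]
    tmp_s <- seqv[a]; seqv[a] <- seqv[b]; seqv[b] <- tmp_s
    tmp_o <- over[a]; over[a] <- over[b]; over[b] <- tmp_o
    if (b < a) {  # wrap edge: traversal order of both crossings' passages flips
      chir[seqv[a]] <- -chir[seqv[a]]
      chir[seqv[b]] <- -chir[seqv[b]]
    }
  }
  list(seq = seqv, over = over, chir = chir)
}

# serialize a state for visited-set bookkeeping
.pd_key <- function(st) {
  paste(c(st$seq, as.integer(st$over), st$chir), collapse = ",")
}

# one deterministic greedy step: R1 first, then R2, each choosing the face
# whose lowest bounding position is smallest; NULL if no reduction applies
.pd_reduce_step <- function(st) {
  faces <- .pd_faces(st$seq, st$chir)
  if (is.null(faces)) stop("internal: inconsistent rotation system")
  m <- length(st$seq)
  best <- NULL; best_pos <- Inf; best_kind <- ""
  for (f in faces) {
    ee <- .face_edges(f)
    if (length(ee) == 1L) {
      pp <- .edge_pos(ee[1], m)
      if (st$seq[pp[1]] == st$seq[pp[2]] && min(pp) < best_pos) {
        best <- f; best_pos <- min(pp); best_kind <- "r1"
      }
    }
  }
  if (!is.null(best)) return(.pd_apply_r1(st, best))
  for (f in faces) {
    if (.pd_r2_ok(st, f)) {
      pp <- unlist(lapply(.face_edges(f), .edge_pos, m))
      if (min(pp) < best_pos) { best <- f; best_pos <- min(pp); best_kind <- "r2" }
    }
  }
  if (!is.null(best)) return(.pd_apply_r2(st, best))
  NULL
}

# all R3 successor states, deterministically ordered
.pd_r3_successors <- function(st) {
  faces <- .pd_faces(st$seq, st$chir)
  m <- length(st$seq)
  out <- list()
  ord <- order(vapply(faces, function(f) min(unlist(lapply(.face_edges(f),
                                                           .edge_pos, m))), 1))
  for (f in faces[ord]) {
    for (k in .pd_r3_edges(st, f)) {
      st2 <- st
      # slide exactly this edge's strand: the move swaps all three edge
      # pairs at once (one slide = one trigon flip)
      out[[length(out) + 1L]] <- .pd_apply_r3(st2, f)
      break  # one successor per trigon face: the flip is the same state
    }
  }
  out
}

# full deterministic simplification: greedy R1/R2 to a fixed point, then a
# bounded breadth-first search through R3 slides for a state where R1/R2
# unlock again; repeats until no reduction is reachable
.pd_simplify <- function(st, max_states = 3000L) {
  repeat {
    repeat {
      nxt <- .pd_reduce_step(st)
      if (is.null(nxt)) break
      st <- nxt
    }
    if (length(st$seq) == 0L) return(st)
    # BFS through R3 space
    seen <- .pd_key(st)
    queue <- list(st)
    found <- NULL
    while (length(queue) > 0L && length(seen) < max_states) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nb in .pd_r3_successors(cur)) {
        key <- .pd_key(nb)
        if (key %in% seen) next
        seen <- c(seen, key)
        red <- .pd_reduce_step(nb)
        if (!is.null(red)) { found <- red; break }
        queue[[length(queue) + 1L]] <- nb
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) return(st)
    st <- found
  }
}

# canonical signed DT values over all starts, directions and mirror:
# smallest magnitude sequence, ties broken toward positive signs
.pd_canonical_values <- function(st) {
  m <- length(st$seq)
  n <- m / 2L
  if (n == 0L) return(integer(0))
  best <- NULL
  for (mirror in c(FALSE, TRUE)) {
    over <- if (mirror) !st$over else st$over
    for (s in seq_len(m)) {
      for (dir in c(1L, -1L)) {
        relab <- if (dir == 1L) .pd_wrap(seq_len(m) - s + 1L, m)
        else .pd_wrap(s - seq_len(m) + 1L, m)
        # relab[p] = new label of old position p
        first <- integer(n); vals <- integer(n); ok <- TRUE
        lab_of <- cbind(integer(n), integer(n))
        for (p in seq_len(m)) {
          cr <- st$seq[p]
          if (lab_of[cr, 1] == 0L) lab_of[cr, 1] <- p else lab_of[cr, 2] <- p
        }
        for (cr in seq_len(n)) {
          l1 <- relab[lab_of[cr, 1]]; l2 <- relab[lab_of[cr, 2]]
          o1 <- over[lab_of[cr, 1]]; o2 <- over[lab_of[cr, 2]]
          if (l1 %% 2L == 1L) { odd <- l1; even <- l2; oe <- o2 }
          else { odd <- l2; even <- l1; oe <- o1 }
          if (odd %% 2L != 1L) { ok <- FALSE; break }
          vals[(odd + 1L) / 2L] <- if (oe) -even else even
        }
        if (!ok) next
        if (is.null(best) || .pd_code_less(vals, best)) best <- vals
      }
    }
  }
  best
}

# magnitude-lexicographic order, positive signs preferred on ties
.pd_code_less <- function(a, b) {
  aa <- abs(a); ab <- abs(b)
  for (i in seq_along(aa)) {
    if (aa[i] != ab[i]) return(aa[i] < ab[i])
  }
  sa <- as.integer(a < 0); sb <- as.integer(b < 0)
  for (i in seq_along(sa)) {
    if (sa[i] != sb[i]) return(sa[i] < sb[i])
  }
  FALSE
}
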