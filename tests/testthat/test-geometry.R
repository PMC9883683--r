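test_that("segment-triangle piercing matches the obvious cases", {
  tri <- list(a = c(0, 0, 0), b = c(2, 0, 0), c = c(0, 2, 0))
  expect_true(segment_pierces_triangle(c(0.5, 0.5, -1), c(0.5, 0.5, 1),
                                       tri$a, tri$b, tri$c))
  expect_false(segment_pierces_triangle(c(3, 3, -1), c(3, 3, 1),
                                        tri$a, tri$b, tri$c))
  # boundary graze within eps counts as piercing (conservative)
  expect_true(segment_pierces_triangle(c(1, 1e-12, -1), c(1, 1e-12, 1),
                                       tri$a, tri$b, tri$c))
})

test_that("piercing is invariant under triangle permutation and reversal", {
  rng <- chainknot:::.lcg(7)
  ri <- function() round(rng() * 20 - 10)
  for (k in 1:60) {
    p <- c(ri(), ri(), ri()); q <- c(ri(), ri(), ri())
    a <- c(ri(), ri(), ri()); b <- c(ri(), ri(), ri()); cc <- c(ri(), ri(), ri())
    if (sqrt(sum((p - q)^2)) < 1 || triangle_degenerate(a, b, cc, 1e-6)) next
    base <- segment_pierces_triangle(p, q, a, b, cc)
    expect_identical(segment_pierces_triangle(q, p, a, b, cc), base)
    expect_identical(segment_pierces_triangle(p, q, b, cc, a), base)
    expect_identical(segment_pierces_triangle(p, q, cc, b, a), base)
  }
})

test_that("piercing agrees with an exact-arithmetic oracle off boundaries", {
  # integer coordinates keep every orientation determinant exact in doubles
  exact_cross <- function(p, q, a, b, cc) {
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    d1 <- sum(n * (p - a)); d2 <- sum(n * (q - a))
    if (!(d1 * d2 < 0)) return(FALSE)
    # crossing point scaled by (d1 - d2): stays integral
    x <- p * (d1 - d2) + (q - p) * d1
    aa <- a * (d1 - d2); bb <- b * (d1 - d2); cs <- cc * (d1 - d2)
    s <- function(u, v) {
      w <- c((v[2] - u[2]) * (x[3] - u[3]) - (v[3] - u[3]) * (x[2] - u[2]),
             (v[3] - u[3]) * (x[1] - u[1]) - (v[1] - u[1]) * (x[3] - u[3]),
             (v[1] - u[1]) * (x[2] - u[2]) - (v[2] - u[2]) * (x[1] - u[1]))
      sum(n * w) * sign(d1 - d2)
    }
    s1 <- s(aa, bb); s2 <- s(bb, cs); s3 <- s(cs, aa)
    (s1 > 0 && s2 > 0 && s3 > 0) || (s1 < 0 && s2 < 0 && s3 < 0)
  }
  rng <- chainknot:::.lcg(11)
  ri <- function() round(rng() * 12 - 6)
  checked <- 0L
  for (k in 1:400) {
    p <- c(ri(), ri(), ri()); q <- c(ri(), ri(), ri())
    a <- c(ri(), ri(), ri()); b <- c(ri(), ri(), ri()); cc <- c(ri(), ri(), ri())
    if (sqrt(sum((p - q)^2)) < 1 || triangle_degenerate(a, b, cc, 1e-6)) next
    oracle <- exact_cross(p, q, a, b, cc)
    pred <- segment_pierces_triangle(p, q, a, b, cc)
    if (oracle) {
      expect_true(pred)       # proper crossings always detected
      checked <- checked + 1L
    } else if (!pred) {
      checked <- checked + 1L # agreement on clear misses
    }
    # remaining disagreements can only be eps-boundary touches, which the
    # predicate is allowed (required) to report conservatively
  }
  expect_gt(checked, 200L)
})

test_that("a collinear chain never pierces its own triangles", {
  ch <- bead_chain(cbind(0:9 * 3.8, 0, 0))
  tri <- ch$beads[3:5, ]
  expect_false(triangle_is_pierced(tri, ch,
                                   excluded = cbind(chain = c(1, 1),
                                                    seg = c(3, 4))))
})

test_that("an obstacle chain threading a triangle is detected", {
  a <- bead_chain(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4), 0), chain_id = "A")
  thread <- bead_chain(cbind(2, 1.5, c(-3, 3)), chain_id = "B")
  tri <- a$beads[c(1, 2, 3), ]
  expect_true(triangle_is_pierced(tri, list(a, thread),
                                  excluded = cbind(chain = c(1, 1),
                                                   seg = c(1, 2))))
  far <- bead_chain(cbind(20, 20, c(-3, 3)), chain_id = "B")
  expect_false(triangle_is_pierced(tri, list(a, far),
                                   excluded = cbind(chain = c(1, 1),
                                                    seg = c(1, 2))))
})

test_that("2D crossing reports point, parameters and depth order", {
  r <- segments_cross_2d(c(0, 0), c(2, 2), c(0, 0), c(0, 2), c(2, 0), c(1, 1))
  expect_equal(r$point, c(1, 1))
  expect_equal(r$over_segment, 2L)   # greater depth = nearer the viewer
  expect_true(r$u1 > 0 && r$u1 < 1 && r$u2 > 0 && r$u2 < 1)
  # parallel offset: no crossing
  expect_null(segments_cross_2d(c(0, 0), c(1, 0), c(0, 0),
                                c(0, 1), c(1, 1), c(0, 0)))
  # collinear overlap: degeneracy
  expect_identical(segments_cross_2d(c(0, 0), c(2, 0), c(0, 0),
                                     c(1, 0), c(3, 0), c(0, 0)), "degenerate")
  # collinear but disjoint: no crossing
  expect_null(segments_cross_2d(c(0, 0), c(1, 0), c(0, 0),
                                c(2, 0), c(3, 0), c(0, 0)))
  # endpoint touch: degeneracy
  expect_identical(segments_cross_2d(c(0, 0), c(2, 2), c(0, 0),
                                     c(2, 2), c(3, 0), c(1, 1)), "degenerate")
  # depth tie at the crossing: degeneracy
  expect_identical(segments_cross_2d(c(0, 0), c(2, 2), c(0, 0),
                                     c(0, 2), c(2, 0), c(0, 0)), "degenerate")
})
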