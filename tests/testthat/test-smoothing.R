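test_that("a straight chain loses all interior beads in one pass", {
  ch <- bead_chain(cbind(0:4 * 3.8, 0, 0))
  res <- smoothing_pass(ch)
  expect_true(res$changed)
  expect_equal(nrow(res$system[[1]]$beads), 2L)
  # fully blocked pass reports no change
  res2 <- smoothing_pass(res$system)
  expect_false(res2$changed)
})

test_that("unknotted chains reduce to exactly their two end points", {
  for (ch in list(make_chain("unknot_helix", n_beads = 100),
                  make_chain("unknot_zigzag", n_beads = 20))) {
    out <- smooth_chains(ch)
    fin <- out$system[[1]]
    expect_equal(nrow(fin$beads), 2L)
    expect_identical(fin$beads[1, ], ch$beads[1, ])
    expect_identical(fin$beads[2, ], ch$beads[nrow(ch$beads), ])
    expect_true(out$converged)
  }
})

test_that("termini stay fixed in every trajectory frame", {
  ch <- make_chain("torus_knot", p = 2, q = 3)
  out <- smooth_chains(ch)
  for (fr in out$trajectory$frames) {
    b <- fr[[1]]$beads
    expect_identical(b[1, ], ch$beads[1, ])
    expect_identical(b[nrow(b), ], ch$beads[nrow(ch$beads), ])
  }
})

test_that("smoothing a trefoil conserves its determinant in every frame", {
  ch <- make_chain("torus_knot", p = 2, q = 3)
  out <- smooth_chains(ch)
  expect_true(all(frame_dets(out$trajectory) == 3))
  expect_gte(nrow(out$system[[1]]$beads), 6L)  # minimal stick trefoil: 6 edges
})

test_that("bead count is non-increasing along the trajectory", {
  for (ch in list(make_chain("torus_knot", p = 2, q = 5),
                  make_chain("unknot_helix", n_beads = 80))) {
    out <- smooth_chains(ch)
    nb <- vapply(out$trajectory$frames, function(s) nrow(s[[1]]$beads), 1L)
    expect_true(all(diff(nb) <= 0))
    expect_lt(nb[length(nb)], nb[1])
  }
})

test_that("an obstacle chain blocks deletions that would pass through it", {
  pair <- make_chain("linked_pair")
  out <- smooth_chains(pair)
  # threaded rings cannot shrink to bare segments without a strand passage
  expect_gt(nrow(out$system[[1]]$beads), 2L)
  expect_gt(nrow(out$system[[2]]$beads), 2L)
  # and they stay threaded (oracle)
  expect_gt(abs(gauss_linking(out$system[[1]], out$system[[2]])), 0.5)
})

test_that("reduce_beads strips superfluous beads and nothing else", {
  two <- bead_chain(cbind(c(0, 3.8), 0, 0))
  expect_identical(reduce_beads(two)$beads, two$beads)
  zz <- make_chain("unknot_zigzag", n_beads = 20)
  expect_equal(nrow(reduce_beads(zz)$beads), 2L)
  tref <- smooth_chains(make_chain("torus_knot", p = 2, q = 3))$system[[1]]
  expect_identical(reduce_beads(tref)$beads, tref$beads)  # already minimal
})

test_that("two runs on identical input are byte-identical", {
  w <- chainknot:::.saw(120, 3.8, 1.0, 77)
  o1 <- smooth_chains(w)
  o2 <- smooth_chains(w)
  expect_identical(o1$trajectory$frames, o2$trajectory$frames)
  expect_identical(o1$system, o2$system)
})

test_that("rerunning smoothing on its own output preserves the result", {
  # a trivial chain's two end points are a true fixed point
  triv <- smooth_chains(make_chain("unknot_helix", n_beads = 60))$system[[1]]
  expect_identical(smooth_chains(triv)$system[[1]]$beads, triv$beads)
  # a reduced knot may still wiggle under the exploration endgame, but its
  # bead-count scale, invariant and name are stable
  for (ch in list(make_chain("torus_knot", p = 2, q = 3),
                  make_chain("figure_eight"))) {
    fin <- smooth_chains(ch)$system[[1]]
    again <- smooth_chains(fin)$system[[1]]
    expect_equal(knot_determinant(again), knot_determinant(fin))
    expect_identical(chainknot:::.classify_chain(again),
                     chainknot:::.classify_chain(fin))
  }
})

test_that("reversing a single chain mirrors the trajectory frame by frame", {
  for (ch in list(make_chain("torus_knot", p = 2, q = 3),
                  make_chain("unknot_helix", n_beads = 60),
                  chainknot:::.saw(90, 3.8, 1.0, 5))) {
    fwd <- smooth_chains(ch)
    rev <- smooth_chains(reverse_chain(ch))
    expect_reversed_trajectory(fwd, rev)
  }
})

test_that("the iteration cap flags an unconverged result", {
  ch <- make_chain("torus_knot", p = 2, q = 3)
  out <- smooth_chains(ch, smooth_config(max_iterations = 1L))
  expect_false(out$converged)
})

test_that("subchain smoothing moves only interior beads of the range", {
  ch <- bead_chain(cbind(0:9 * 3.8, c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1), 0))
  out <- smooth_subchain(ch, 3, 8)
  fin <- out$system[[1]]
  # flanks untouched
  expect_identical(fin$beads[1:2, ], ch$beads[1:2, ])
  nfin <- nrow(fin$beads)
  expect_identical(fin$beads[(nfin - 1):nfin, ], ch$beads[9:10, ])
  # subchain of a (nearly) straight stretch collapses to its two bounds
  expect_equal(out$subchain_range[2] - out$subchain_range[1], 1L)
  expect_error(smooth_subchain(ch, 3, 4), "at least 3")
  expect_error(smooth_subchain(ch, 3, 99), "not found")
})

test_that("full-range subchain smoothing equals plain smoothing", {
  ch <- make_chain("torus_knot", p = 2, q = 3, n_beads = 80)
  a <- smooth_chains(ch)
  b <- smooth_subchain(ch, ch$residue_ids[1],
                       ch$residue_ids[length(ch$residue_ids)])
  expect_identical(a$system[[1]]$beads, b$system[[1]]$beads)
})
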