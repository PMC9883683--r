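test_that("fixture generators are pure and byte-stable", {
  a <- make_chain("torus_knot", p = 2, q = 3)
  b <- make_chain("torus_knot", p = 2, q = 3)
  expect_identical(a, b)
  w1 <- make_chain("unknot_random", n_beads = 80, seed = 3)
  w2 <- make_chain("unknot_random", n_beads = 80, seed = 3)
  expect_identical(w1, w2)
})

test_that("torus knot parameters must be coprime", {
  expect_error(make_chain("torus_knot", p = 2, q = 4), "coprime")
  expect_error(make_chain("nonsense"), "unknown fixture kind")
})

test_that("ground truth states the forced topology of each kind", {
  expect_equal(ground_truth("torus_knot", p = 2, q = 5)$label, "5_1")
  expect_equal(ground_truth("torus_knot", p = 2, q = 5)$determinant, 5)
  expect_equal(ground_truth("figure_eight")$label, "4_1")
  expect_equal(ground_truth("twist_knot", twists = 4)$label, "6_1")
  expect_equal(ground_truth("unknot_helix")$label, "0_1")
  expect_equal(ground_truth("linked_pair")$label, "linked")
  gt <- ground_truth("composite",
                     factors = list(list(kind = "torus_knot", p = 2, q = 3),
                                    list(kind = "torus_knot", p = 2, q = 3)))
  expect_equal(gt$label, "3_1#3_1")
  expect_equal(gt$determinant, 9)
})

test_that("random unknots are certified trivial before being emitted", {
  for (sd in 1:3) {
    w <- make_chain("unknot_random", n_beads = 80, seed = sd)
    expect_equal(knot_determinant(w), 1)
  }
})

test_that("fixture determinants match their ground truth", {
  cases <- list(
    list(kind = "torus_knot", p = 2, q = 3),
    list(kind = "figure_eight"),
    list(kind = "twist_knot", twists = 4),
    list(kind = "stick_trefoil"))
  for (cs in cases) {
    gt <- do.call(ground_truth, cs[names(cs) != "n_beads"])
    ch <- do.call(make_chain, cs)
    expect_equal(knot_determinant(ch), gt$determinant, label = cs$kind)
  }
})

test_that("fixtures export cleanly through the IO layer", {
  ch <- make_chain("stick_trefoil")
  back <- suppressWarnings(parse_pdb(write_pdb(ch)))[[1]]
  expect_equal(back$beads, ch$beads, tolerance = 1e-3)
  pair <- make_chain("linked_pair")
  xyz <- paste(c(apply(pair[[1]]$beads, 1, paste, collapse = " "), "END",
                 apply(pair[[2]]$beads, 1, paste, collapse = " ")),
               collapse = "\n")
  back2 <- parse_xyz(xyz)
  expect_length(back2, 2L)
  expect_equal(back2[[2]]$beads, pair[[2]]$beads, tolerance = 1e-6)
})
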