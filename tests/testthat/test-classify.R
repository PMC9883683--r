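test_that("Reidemeister simplification removes curls and is idempotent", {
  expect_equal(simplify_dt(new_dt_code(2))$n, 0L)        # single curl
  tref <- new_dt_code(c(4, 6, 2))
  s1 <- simplify_dt(tref)
  expect_equal(abs(s1$values), c(4, 6, 2))               # already minimal
  expect_identical(simplify_dt(s1)$values, s1$values)    # idempotent
})

test_that("simplification never increases length and preserves the determinant", {
  for (ch in list(smooth_chains(make_chain("torus_knot", p = 2, q = 5))$system[[1]],
                  smooth_chains(make_chain("figure_eight"))$system[[1]],
                  smooth_chains(make_chain("twist_knot", twists = 4))$system[[1]])) {
    raw <- dt_code(build_diagram(ch, choose_projection(ch)))
    min_code <- simplify_diagram(build_diagram(ch, choose_projection(ch)))
    expect_lte(min_code$n, raw$n)
    expect_equal(knot_determinant(min_code), knot_determinant(raw))
  }
})

test_that("classification names the tabulated knots and fails honestly", {
  expect_equal(classify_knot(new_dt_code(integer(0))), "0_1")
  expect_equal(classify_knot(new_dt_code(c(4, 6, 2))), "3_1")
  expect_equal(classify_knot(new_dt_code(c(4, 6, 8, 2))), "4_1")
  expect_equal(classify_knot(new_dt_code(c(4, 8, 12, 10, 2, 6))), "6_1")
  # a granny-knot minimal code is composite: not in the prime table
  g <- make_chain("composite",
                  factors = list(list(kind = "torus_knot", p = 2, q = 3),
                                 list(kind = "torus_knot", p = 2, q = 3)))
  fin <- smooth_chains(g)$system[[1]]
  code <- simplify_diagram(build_diagram(fin, choose_projection(fin)))
  expect_match(classify_knot(code), "^unknown_")
})

test_that("the knot determinant distinguishes the packaged fixtures", {
  expect_equal(knot_determinant(make_chain("stick_trefoil")), 3)
  expect_equal(knot_determinant(make_chain("figure_eight")), 5)
  expect_equal(knot_determinant(make_chain("torus_knot", p = 2, q = 5)), 5)
  expect_equal(knot_determinant(make_chain("twist_knot", twists = 4)), 9)
  expect_equal(knot_determinant(make_chain("unknot_helix", n_beads = 60)), 1)
})

test_that("composite determinants multiply over factors", {
  g <- make_chain("composite",
                  factors = list(list(kind = "torus_knot", p = 2, q = 3),
                                 list(kind = "torus_knot", p = 2, q = 3)))
  expect_equal(knot_determinant(g), 9)
})

test_that("subentanglement scan factors a granny knot", {
  g <- make_chain("composite",
                  factors = list(list(kind = "torus_knot", p = 2, q = 3),
                                 list(kind = "torus_knot", p = 2, q = 3)))
  fin <- smooth_chains(g)$system[[1]]
  sub <- find_subentanglements(fin)
  expect_length(sub$ranges, 2L)
  expect_equal(sub$labels, c("3_1", "3_1"))
  expect_equal(sub$label, "3_1#3_1")
  # a reduced unknot has none
  triv <- smooth_chains(make_chain("unknot_helix", n_beads = 50))$system[[1]]
  expect_equal(find_subentanglements(triv)$label, "0_1")
})

test_that("link detection matches the Gauss linking oracle", {
  hopf <- make_chain("linked_pair")
  expect_gt(abs(gauss_linking(hopf[[1]], hopf[[2]])), 0.5)
  rep_h <- detect_links(smooth_chains(hopf)$system)
  expect_true(rep_h$linked)
  expect_gte(rep_h$crossings, 2L)

  stacked <- make_chain("unlinked_pair")
  expect_lt(abs(gauss_linking(stacked[[1]], stacked[[2]])), 0.1)
  rep_s <- detect_links(smooth_chains(stacked)$system)
  expect_false(rep_s$linked)

  far <- list(bead_chain(cbind(0:5 * 3.8, 0, 0), chain_id = "A"),
              bead_chain(cbind(0:5 * 3.8, 50, 0), chain_id = "B"))
  rep_f <- detect_links(far)
  expect_false(rep_f$linked)
  expect_equal(rep_f$crossings, 0L)
})

test_that("link detection is symmetric in chain order", {
  hopf <- smooth_chains(make_chain("linked_pair"))$system
  a <- detect_links(hopf)
  b <- detect_links(rev(hopf))
  expect_equal(a$linked, b$linked)
  expect_equal(a$crossings, b$crossings)
})

test_that("analyze_topology assembles labels, codes and links", {
  res <- analyze_topology(make_chain("stick_trefoil"))
  expect_equal(res$chains[[1]]$label, "3_1")
  expect_true(length(res$chains[[1]]$dt) == 3L)
  out <- capture.output(print(res))
  expect_match(out[1], "chain A: 3_1 ; DT: ")
})
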