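test_that("straight and planar chains project with zero crossings", {
  straight <- bead_chain(cbind(0:5 * 3.8, 0.1 * (0:5)^1.5, 0))
  rot <- choose_projection(straight)
  expect_identical(rot, diag(3))          # identity accepted first
  expect_equal(build_diagram(straight, rot)$n, 0L)
  expect_equal(dt_code(build_diagram(straight, rot))$n, 0L)
})

test_that("projection choice is deterministic", {
  ch <- make_chain("stick_trefoil")
  r1 <- choose_projection(ch)
  r2 <- choose_projection(ch)
  expect_identical(r1, r2)
})

test_that("the minimal stick trefoil projects to exactly three crossings", {
  ch <- make_chain("stick_trefoil")
  d <- build_diagram(ch, choose_projection(ch))
  expect_equal(d$n, 3L)
  code <- dt_code(d)
  expect_true(validate_dt(code))
  expect_setequal(abs(code$values), c(2, 4, 6))
  expect_equal(abs(simplify_dt(code)$values), c(4, 6, 2))
})

test_that("DT codes satisfy the permutation and pairing invariants", {
  for (ch in list(make_chain("stick_trefoil"),
                  smooth_chains(make_chain("figure_eight"))$system[[1]],
                  smooth_chains(make_chain("twist_knot",
                                           twists = 4))$system[[1]])) {
    code <- dt_code(build_diagram(ch, choose_projection(ch)))
    expect_true(all(abs(code$values) %% 2 == 0))
    expect_setequal(abs(code$values), seq(2L, 2L * code$n, by = 2L))
    expect_true(validate_dt(code))
  }
})

test_that("DT validation rejects syntactic and unrealizable codes", {
  expect_true(validate_dt(new_dt_code(integer(0))))
  expect_true(validate_dt(new_dt_code(c(4, 6, 2))))
  expect_false(validate_dt(new_dt_code(c(2, 4, 5))))   # odd value
  expect_false(validate_dt(new_dt_code(c(4, 4, 2))))   # not a permutation
  expect_true(validate_dt(new_dt_code(2)))             # reducible curl
})

test_that("any two generic projections simplify to the same minimal code", {
  ch <- smooth_chains(make_chain("torus_knot", p = 2, q = 3))$system[[1]]
  codes <- list()
  for (R in chainknot:::.projection_candidates(4000)) {
    d <- try(build_diagram(ch, R), silent = TRUE)
    if (inherits(d, "try-error")) next
    if (!chainknot:::.parity_ok(
      chainknot:::.project_diagram(list(ch), R))) next
    if (!chainknot:::.termini_escape(list(ch), R)) next
    codes[[length(codes) + 1L]] <- simplify_diagram(d)$values
    if (length(codes) >= 3L) break
  }
  expect_gte(length(codes), 2L)
  for (k in seq_along(codes)[-1]) expect_identical(codes[[k]], codes[[1]])
})

test_that("a reduced two-bead chain always yields the empty code", {
  fin <- smooth_chains(make_chain("unknot_helix", n_beads = 60))$system[[1]]
  code <- dt_code(build_diagram(fin, choose_projection(fin)))
  expect_equal(code$n, 0L)
})
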