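test_that("PDB parsing extracts the CA trace in residue order", {
  ch <- parse_pdb(pdb_3res())
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$chain_id, "A")
  expect_equal(ch[[1]]$beads,
               cbind(c(0, 3.8, 7.6), 0, 0), ignore_attr = TRUE)
  expect_equal(ch[[1]]$residue_ids, 1:3)
})

test_that("an empty selection is an error naming the filter", {
  expect_error(parse_pdb(pdb_3res(), chain_filter = "B"), "empty selection")
  expect_error(parse_pdb(pdb_3res(), atom_name = "CB"), "empty selection")
})

test_that("PDB and mmCIF renderings give identical bead chains", {
  a <- parse_pdb(pdb_3res())
  b <- parse_cif(cif_3res())
  expect_equal(a[[1]]$beads, b[[1]]$beads)
  expect_equal(a[[1]]$residue_ids, b[[1]]$residue_ids)
  expect_equal(a[[1]]$chain_id, b[[1]]$chain_id)
})

test_that("mmCIF without an _atom_site loop is a format error", {
  expect_error(parse_cif("data_x\n_cell.length_a 10\n"), "_atom_site")
})

test_that("multi-model mmCIF uses model 1 only, with a notice", {
  expect_message(ch <- parse_cif(cif_two_models()), "model")
  ref <- parse_cif(cif_3res())
  expect_equal(ch[[1]]$beads, ref[[1]]$beads)
})

test_that("altloc duplicates keep the highest occupancy, ties by id", {
  txt <- paste(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(3, "CA", "GLY", "A", 2, 2, 0, 0, occ = 0.6, alt = "B"),
    pdb_line(4, "CA", "GLY", "A", 3, 5, 0, 0, occ = 0.5, alt = "B"),
    pdb_line(5, "CA", "GLY", "A", 3, 6, 0, 0, occ = 0.5, alt = "A"),
    "TER", "END", ""), collapse = "\n")
  ch <- parse_pdb(txt)
  expect_equal(ch[[1]]$beads[2, 1], 2)  # occupancy 0.6 wins
  expect_equal(ch[[1]]$beads[3, 1], 6)  # tie: altloc A wins
})

test_that("a large consecutive-bead distance warns about a chain gap", {
  txt <- paste(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 5, 40, 0, 0),
    "TER", "END", ""), collapse = "\n")
  expect_warning(parse_pdb(txt), "gap")
})

test_that("XYZ chains split on END; blanks ignored; empty input empty", {
  ch <- parse_xyz("0 0 0\n1 0 0\nEND\n\n0 0 5\n1 0 5\n")
  expect_length(ch, 2L)
  expect_equal(nrow(ch[[1]]$beads), 2L)
  expect_equal(ch[[2]]$beads[2, ], c(1, 0, 5))
  expect_length(parse_xyz(""), 0L)
  one <- parse_xyz(paste(sprintf("%d 0 0", 1:100), collapse = "\n"))
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$beads), 100L)
  expect_error(parse_xyz("0 0 zero\n"), "line 1")
})

test_that("write_pdb emits ATOM/TER/END and MODEL records for trajectories", {
  ch <- parse_pdb(pdb_3res())[[1]]
  txt <- write_pdb(ch)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(sum(grepl("^ATOM", lines)), 3L)
  expect_equal(sum(grepl("^TER", lines)), 1L)
  expect_equal(tail(lines, 1), "END")
  traj <- knot_trajectory(list(list(ch), list(ch)), c("a", "b"))
  mt <- write_pdb(traj)
  expect_match(mt, "MODEL     1")
  expect_match(mt, "MODEL     2")
})

test_that("write/parse round trip preserves beads to PDB precision", {
  rng <- chainknot:::.lcg(42)
  for (k in 1:5) {
    n <- 5L + k
    xyz <- matrix(vapply(seq_len(3 * n), function(i) rng(), 1), n, 3) * 14 - 7
    ch <- bead_chain(xyz, chain_id = "Q", residue_ids = seq(2, by = 3,
                                                           length.out = n))
    back <- suppressWarnings(parse_pdb(write_pdb(ch)))
    expect_equal(back[[1]]$beads, ch$beads, tolerance = 1e-3)
    expect_equal(back[[1]]$residue_ids, ch$residue_ids)
    expect_equal(back[[1]]$chain_id, "Q")
  }
  # two-chain round trip
  two <- parse_pdb(two_chain_pdb())
  back <- parse_pdb(write_pdb(two))
  expect_length(back, 2L)
  expect_equal(back[[2]]$beads, two[[2]]$beads, tolerance = 1e-3)
})

test_that("out-of-range coordinates are a formatting error", {
  ch <- bead_chain(cbind(c(0, 1e5), 0, 0))
  expect_error(write_pdb(ch), "column width")
})

test_that("malformed PDB ids are rejected before any network use", {
  expect_error(fetch_structure("xx"), "malformed")
  expect_error(fetch_structure("abcd"), "malformed")  # must start with digit
})
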