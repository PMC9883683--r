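# shared test helpers: text fixtures built in code, trajectory utilities

pdb_line <- function(serial, atom, res, chain, resno, x, y, z, occ = 1,
                     alt = " ", type = "ATOM  ") {
  an <- if (nchar(atom) <= 3L) sprintf(" %-3s", atom) else sprintf("%-4s", atom)
  sprintf("%s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00",
          type, serial, an, alt, res, chain, resno, x, y, z, occ)
}

# minimal 3-residue single-chain PDB with CA at (0,0,0),(3.8,0,0),(7.6,0,0)
pdb_3res <- function() {
  paste(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0),
    "TER", "END", ""), collapse = "\n")
}

# the same structure rendered as mmCIF
cif_3res <- function() {
  paste(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "ATOM 1 CA . GLY A 1 0.000 0.000 0.000 1.00",
    "ATOM 2 CA . GLY A 2 3.800 0.000 0.000 1.00",
    "ATOM 3 CA . GLY A 3 7.600 0.000 0.000 1.00",
    "#", ""), collapse = "\n")
}

# two-model mmCIF; model 2 has shifted coordinates
cif_two_models <- function() {
  hdr <- c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num")
  rows <- c(
    "ATOM 1 CA . GLY A 1 0.000 0.000 0.000 1.00 1",
    "ATOM 2 CA . GLY A 2 3.800 0.000 0.000 1.00 1",
    "ATOM 3 CA . GLY A 3 7.600 0.000 0.000 1.00 1",
    "ATOM 4 CA . GLY A 1 9.000 9.000 9.000 1.00 2",
    "ATOM 5 CA . GLY A 2 9.000 9.000 12.800 1.00 2",
    "ATOM 6 CA . GLY A 3 9.000 9.000 16.600 1.00 2")
  paste(c(hdr, rows, "#", ""), collapse = "\n")
}

two_chain_pdb <- function() {
  paste(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "TER",
    pdb_line(3, "CA", "GLY", "B", 1, 0, 10, 0),
    pdb_line(4, "CA", "GLY", "B", 2, 3.8, 10, 0),
    pdb_line(5, "CA", "GLY", "B", 3, 7.6, 10, 0),
    "TER", "END", ""), collapse = "\n")
}

# trajectory helpers -------------------------------------------------------

frame_dets <- function(traj) {
  vapply(traj$frames, function(sys) {
    sum(vapply(sys, knot_determinant, 1))  # single-chain frames in practice
  }, 1)
}

expect_reversed_trajectory <- function(fwd, rev) {
  expect_equal(length(fwd$frames), length(rev$frames))
  for (k in seq_along(fwd$frames)) {
    a <- fwd$frames[[k]][[1]]$beads
    b <- rev$frames[[k]][[1]]$beads
    expect_identical(a, b[nrow(b):1, , drop = FALSE])
  }
}

# random knotted/unknotted walk whose termini are routed far above the
# coil, so the chord closure (and hence the determinant) is unambiguous
protruding_walk <- function(n, seed) {
  w <- chainknot:::.saw(n, step = 3.8, min_sep = 1.0, seed = seed)
  if (is.null(w)) return(NULL)
  b <- w$beads
  top <- max(b[, 3]) + 10
  m <- nrow(b)
  # slight lateral lean: exactly vertical tails are collinear with the
  # closure chord's endpoints and degenerate every projection
  up1 <- cbind(b[1, 1] + 0.13, b[1, 2] - 0.07,
               seq(b[1, 3] + 3.8, top + 3.8, by = 3.8))
  up2 <- cbind(b[m, 1] - 0.11, b[m, 2] + 0.09,
               seq(b[m, 3] + 3.8, top, by = 3.8))
  bead_chain(rbind(up1[rev(seq_len(nrow(up1))), , drop = FALSE], b, up2))
}
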