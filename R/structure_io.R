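#' Parse PDB-format text into bead chains
#'
#' Extracts one backbone trace per chain from the named atom (CA by
#' default).  Altloc duplicates keep the highest-occupancy location (ties:
#' lexicographically smallest altloc id).  Multi-model files use model 1
#' only (a notice is logged).  HETATM records matching the trace atom are
#' kept only when their residue number links into the chain's polymer
#' numbering, so modified residues do not break the trace.  Chains with
#' fewer than two matching atoms are dropped with a warning.  A warning is
#' also emitted when a consecutive-bead distance exceeds twice the typical
#' virtual bond (7.6 A for CA): a chain gap can silently untie a knot, so
#' the tool warns rather than guesses.
#'
#' @param text PDB-format text (single string or character vector of lines).
#' @param atom_name atom name selecting the trace (default `"CA"`).
#' @param chain_filter optional character vector of chain ids to keep.
#' @return list of [bead_chain]s, in file order.
#' @export
parse_pdb <- function(text, atom_name = "CA", chain_filter = NULL) {
  stopifnot(nzchar(atom_name))
  lines <- .split_lines(text)
  lines <- .first_model_only(lines, "PDB")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)))
  .chains_from_atoms(pdb$atom, atom_name, chain_filter)
}

#' Parse mmCIF text into bead chains
#'
#' Identical contract to [parse_pdb]: PDB and mmCIF renderings of the same
#' structure yield identical bead chains.
#'
#' @inheritParams parse_pdb
#' @param text mmCIF text containing an `_atom_site` loop.
#' @return list of [bead_chain]s.
#' @export
parse_cif <- function(text, atom_name = "CA", chain_filter = NULL) {
  stopifnot(nzchar(atom_name))
  lines <- .split_lines(text)
  if (!any(grepl("^_atom_site\\.", lines))) {
    stop("mmCIF format error: no _atom_site loop found")
  }
  atoms <- .parse_cif_atom_site(lines)
  .chains_from_atoms(atoms, atom_name, chain_filter)
}

#' Parse END-separated XYZ text into bead chains
#'
#' Lines are whitespace-separated `x y z` triples; the keyword `END`
#' separates chains (a trailing `END` is optional); blank lines are
#' ignored.  Residue labels are assigned `1..n` per chain.
#'
#' @param text XYZ-dialect text.
#' @return list of [bead_chain]s; chain ids `"A"`, `"B"`, ...
#' @export
parse_xyz <- function(text) {
  lines <- .split_lines(text)
  ids <- c(LETTERS, paste0(rep(LETTERS, each = 26), rep(LETTERS, 26)))
  chains <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) == 0L) return(invisible())
    coords <- do.call(rbind, cur)
    chains[[length(chains) + 1L]] <<- bead_chain(
      coords, chain_id = ids[length(chains) + 1L], source_atom = "CA")
    cur <<- list()
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (toupper(ln) == "END") { flush(); next }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) < 3L || anyNA(val[1:3])) {
      stop("XYZ parse error at line ", k, ": ", lines[k])
    }
    cur[[length(cur) + 1L]] <- val[1:3]
  }
  flush()
  chains
}

#' Fetch a structure from RCSB by PDB id
#'
#' Downloads the mmCIF (preferred) or PDB rendering of the entry and caches
#' it on disk keyed by id, so repeated calls are byte-identical and
#' offline-safe once cached.
#'
#' @param pdb_id 4-character PDB id (digit + 3 alphanumerics).
#' @param format `"cif"` (default) or `"pdb"`.
#' @param cache_dir cache directory; defaults to the package user cache.
#' @return the structure text (single string), with attribute `format`.
#' @export
fetch_structure <- function(pdb_id, format = c("cif", "pdb"),
                            cache_dir = NULL) {
  format <- match.arg(format)
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id)) {
    stop("malformed PDB id: '", pdb_id, "'")
  }
  pdb_id <- tolower(pdb_id)
  if (is.null(cache_dir)) {
    cache_dir <- tools::R_user_dir("chainknot", which = "cache")
  }
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, paste0(pdb_id, ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s", pdb_id, format)
    ok <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0L) {
      unlink(dest)
      stop("fetch error: could not retrieve '", pdb_id, "' from RCSB")
    }
  }
  txt <- paste(readLines(dest, warn = FALSE), collapse = "\n")
  attr(txt, "format") <- format
  txt
}

#' Write bead chains or a trajectory as PDB text
#'
#' A single system becomes a MODEL-less PDB with one ATOM record per bead
#' (atom name = the chain's `source_atom`, residue numbers preserved,
#' residue name `GLY`), `TER` after each chain and a final `END`.  A
#' [knot_trajectory] becomes a multi-MODEL PDB, one MODEL per frame.
#' Coordinates re-parse to within 1e-3 A (PDB fixed-width precision).
#'
#' @param x a [bead_chain], list of them, or a [knot_trajectory].
#' @return PDB text as a single string.
#' @export
write_pdb <- function(x) {
  if (inherits(x, "knot_trajectory")) {
    out <- character(0)
    for (f in seq_along(x$frames)) {
      out <- c(out, sprintf("MODEL     %d", f),
               .pdb_body(x$frames[[f]]), "ENDMDL")
    }
    return(paste(c(out, "END", ""), collapse = "\n"))
  }
  paste(c(.pdb_body(as_system(x)), "END", ""), collapse = "\n")
}

# ---- internal helpers ------------------------------------------------------

.split_lines <- function(text) {
  if (length(text) == 1L) unlist(strsplit(text, "\n", fixed = TRUE))
  else as.character(text)
}

.first_model_only <- function(lines, label) {
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1L) {
    message(label, " input has ", length(mstart), " models; using model 1")
    mend <- grep("^ENDMDL", lines)
    keep <- c(seq_len(mstart[1] - 1L),
              seq(mstart[1] + 1L, mend[1] - 1L))
    lines <- lines[keep]
  }
  lines
}

# minimal mmCIF _atom_site loop reader returning a bio3d-like atom frame.
# bio3d's read.cif round-trips through its own pdb container; parsing the
# one loop we need keeps the multi-model and column contracts explicit.
.parse_cif_atom_site <- function(lines) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  need <- c("group_PDB", "label_atom_id", "Cartn_x", "Cartn_y", "Cartn_z")
  for (nm in need) {
    if (!(nm %in% cols)) stop("mmCIF format error: missing _atom_site.", nm)
  }
  first <- max(hdr_idx) + 1L
  rows <- list()
  for (k in first:length(lines)) {
    if (k > length(lines)) break
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    tok <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(tok) != length(cols)) {
      stop("mmCIF format error: _atom_site row with ", length(tok),
           " fields, expected ", length(cols))
    }
    rows[[length(rows) + 1L]] <- tok
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  d <- as.data.frame(m, stringsAsFactors = FALSE)
  if ("pdbx_PDB_model_num" %in% cols) {
    first_model <- d$pdbx_PDB_model_num[1]
    if (any(d$pdbx_PDB_model_num != first_model)) {
      message("mmCIF input has multiple models; using model ", first_model)
      d <- d[d$pdbx_PDB_model_num == first_model, , drop = FALSE]
    }
  }
  pick <- function(a, b) if (a %in% cols) d[[a]] else d[[b]]
  chain <- if ("auth_asym_id" %in% cols) d$auth_asym_id else d$label_asym_id
  resno <- if ("auth_seq_id" %in% cols) d$auth_seq_id else d$label_seq_id
  alt <- if ("label_alt_id" %in% cols) d$label_alt_id else "."
  occ <- if ("occupancy" %in% cols) suppressWarnings(as.numeric(d$occupancy)) else 1
  ins <- if ("pdbx_PDB_ins_code" %in% cols) d$pdbx_PDB_ins_code else "?"
  alt[alt %in% c(".", "?")] <- NA_character_
  ins[ins %in% c(".", "?")] <- NA_character_
  data.frame(
    type = d$group_PDB,
    elety = gsub('"', "", d$label_atom_id, fixed = TRUE),
    alt = alt,
    chain = chain,
    resno = suppressWarnings(as.integer(resno)),
    insert = ins,
    x = as.numeric(d$Cartn_x), y = as.numeric(d$Cartn_y),
    z = as.numeric(d$Cartn_z),
    o = ifelse(is.na(occ), 1, occ),
    stringsAsFactors = FALSE
  )
}

# shared selection logic: atom data frame -> list of bead chains
.chains_from_atoms <- function(atoms, atom_name, chain_filter) {
  atoms$alt[atoms$alt %in% c("", " ")] <- NA_character_
  atoms$insert[atoms$insert %in% c("", " ")] <- NA_character_
  sel <- atoms[atoms$elety == atom_name, , drop = FALSE]
  if (!is.null(chain_filter)) {
    sel <- sel[sel$chain %in% chain_filter, , drop = FALSE]
  }
  if (nrow(sel) == 0L) {
    stop("empty selection: no '", atom_name, "' atoms",
         if (!is.null(chain_filter)) {
           paste0(" in chains {", paste(chain_filter, collapse = ","), "}")
         } else "")
  }
  chains <- list()
  for (cid in unique(sel$chain)) {
    a <- sel[sel$chain == cid, , drop = FALSE]
    # HETATM: keep only residues linking into the ATOM polymer numbering
    atm <- a[a$type == "ATOM", , drop = FALSE]
    het <- a[a$type != "ATOM", , drop = FALSE]
    if (nrow(atm) > 0L && nrow(het) > 0L) {
      rng <- range(atm$resno)
      keep <- het$resno >= rng[1] - 1L & het$resno <= rng[2] + 1L &
        !(het$resno %in% atm$resno)
      a <- rbind(atm, het[keep, , drop = FALSE])
    }
    # altloc: highest occupancy wins, ties to smallest altloc id
    key <- paste(a$resno, ifelse(is.na(a$insert), "", a$insert))
    if (anyDuplicated(key)) {
      ord <- order(key, -a$o, ifelse(is.na(a$alt), "", a$alt))
      a <- a[ord, , drop = FALSE]
      a <- a[!duplicated(paste(a$resno, ifelse(is.na(a$insert), "", a$insert))), ,
             drop = FALSE]
    }
    a <- a[order(a$resno, ifelse(is.na(a$insert), "", a$insert)), , drop = FALSE]
    if (nrow(a) < 2L) {
      warning("chain '", cid, "' has fewer than 2 '", atom_name,
              "' atoms; omitted")
      next
    }
    rid <- a$resno
    if (any(diff(rid) <= 0L)) {
      warning("chain '", cid, "' residue numbering not strictly increasing ",
              "(insertion codes?); beads renumbered 1..n")
      rid <- seq_len(nrow(a))
    }
    ch <- bead_chain(cbind(a$x, a$y, a$z), chain_id = cid,
                     residue_ids = rid, source_atom = atom_name)
    d <- sqrt(rowSums((ch$beads[-1, , drop = FALSE] -
                         ch$beads[-nrow(ch$beads), , drop = FALSE])^2))
    gap_tol <- if (atom_name == "CA") 15.2 else 2 * stats::median(d)
    if (any(d > gap_tol)) {
      warning("chain '", cid, "' has ", sum(d > gap_tol),
              " consecutive-bead distance(s) above ", round(gap_tol, 1),
              " A: possible structure gap, topology may be unreliable")
    }
    chains[[length(chains) + 1L]] <- ch
  }
  if (length(chains) == 0L) {
    stop("empty selection: no chain with >= 2 '", atom_name, "' atoms")
  }
  chains
}

.pdb_body <- function(system) {
  out <- character(0)
  serial <- 0L
  for (ch in system) {
    nm <- ch$source_atom
    an <- if (nchar(nm) <= 3L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    n <- nrow(ch$beads)
    if (any(abs(ch$beads) >= 1e4)) {
      stop("coordinate magnitude exceeds PDB column width")
    }
    if (any(ch$residue_ids > 9999L | ch$residue_ids < -999L)) {
      stop("residue number exceeds PDB column width")
    }
    for (i in seq_len(n)) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %s GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial %% 100000L, an, substr(ch$chain_id, 1, 1),
        ch$residue_ids[i], ch$beads[i, 1], ch$beads[i, 2], ch$beads[i, 3]))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      GLY %1s%4d",
                          serial %% 100000L, substr(ch$chain_id, 1, 1),
                          ch$residue_ids[n]))
  }
  out
}
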