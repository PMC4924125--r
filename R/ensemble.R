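# Multi-model PDB ensembles: reading, validation, node definition,
# continuous renumbering, and writing (score tables, B-factor heat-map PDBs).

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
NUCLEOTIDES <- c("A", "G", "C", "U", "DA", "DG", "DC", "DT")
WATER_NAMES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "TIP4", "SPC", "SOL")

#' Read a multi-model PDB file into an ensemble
#'
#' Parses a PDB file in the MODEL/ENDMDL multi-model dialect (an NMR ensemble
#' or molecular-dynamics frames dumped as models) into an `sdri_ensemble`.
#' Every standard amino-acid or nucleotide residue becomes one network node;
#' nodes are renumbered continuously 1..N across chains in file order, with
#' the author residue number retained as `original_number`. All models are
#' verified to share the same atom topology.
#'
#' Waters are always excluded. Other HETATM entities (e.g. structural metal
#' ions) are excluded unless `include_hetero = TRUE`, in which case each
#' becomes an extra node of kind `"hetero"` (note that scoring then requires
#' radius/mass entries for them). Alternate locations are reduced to a single
#' conformer per atom: the highest occupancy wins, ties broken by altloc
#' letter (so 'A' before 'B').
#'
#' @param path Path to a PDB file with one or more MODEL blocks (a plain
#'   single-structure file is read as a 1-frame ensemble).
#' @param include_hetero Keep non-water HETATM residues as extra nodes.
#' @param altloc_policy `"occupancy"` (default, described above) or
#'   `"first"` (first conformer encountered).
#' @return An object of class `sdri_ensemble`: a list with `atoms` (tibble of
#'   per-atom records), `nodes` (tibble with columns `node`, `chain`, `kind`,
#'   `name`, `original_number`, `n_atoms`), `xyz` (frames x 3*atoms
#'   coordinate matrix) and `frame_count`.
#' @seealso [make_ensemble()] to generate synthetic ensembles,
#'   [write_ensemble_pdb()], [node_adjacency()], [node_rmsf()]
#' @export
read_ensemble <- function(path, include_hetero = FALSE,
                          altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  check_model_topology(path)

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- tibble::as_tibble(pdb$atom)
  xyz <- unclass(pdb$xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)

  atoms$element <- resolve_element(atoms$elesy, atoms$elety)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  keep <- !(atoms$resid %in% WATER_NAMES)
  if (!include_hetero) keep <- keep & atoms$type == "ATOM"
  if (!any(keep)) abort(sprintf("no residue atoms found in '%s'", path))

  # altloc reduction: one conformer per (chain, residue, atom name)
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
    ord <- if (altloc_policy == "occupancy") {
      order(key, -atoms$o, atoms$alt)
    } else {
      order(key, seq_len(nrow(atoms)))
    }
    first_of_key <- !duplicated(key[ord])
    sel <- sort(ord[first_of_key])
    keep <- keep & seq_len(nrow(atoms)) %in% sel
  }

  idx <- which(keep)
  atoms <- atoms[idx, ]
  xyz <- xyz[, bio3d::atom2xyz(idx), drop = FALSE]
  new_ensemble(atoms, xyz, source = path)
}

# Verify that every MODEL block carries the same atoms in the same order.
# bio3d keeps only the first model's atom table, so the check runs on the
# raw fixed-column records (atom name, altloc, residue, chain, number).
check_model_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort(sprintf("'%s' contains no ATOM/HETATM records", path))
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) return(invisible(1L))

  model_id <- cumsum(model_starts)
  sig <- substr(lines[is_atom], 13, 27)
  grp <- model_id[is_atom]
  if (any(grp == 0L)) abort(sprintf("'%s': atom records found outside MODEL blocks", path))
  sigs <- split(sig, grp)
  ref <- sigs[[1L]]
  for (m in seq_along(sigs)[-1L]) {
    cur <- sigs[[m]]
    if (length(cur) != length(ref) || any(cur != ref)) {
      bad <- if (length(cur) != length(ref)) {
        min(length(cur), length(ref)) + 1L
      } else {
        which(cur != ref)[1L]
      }
      where <- if (bad <= length(cur)) cur[bad] else ref[bad]
      abort(sprintf(
        "model %d does not match model 1 topology near atom record '%s' (atom %d)",
        as.integer(names(sigs)[m]), trimws(where), bad
      ))
    }
  }
  invisible(length(sigs))
}

resolve_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fill <- el == ""
  if (any(fill)) {
    # fall back on the atom name: strip digits/primes, leading digit means H
    nm <- toupper(trimws(elety[fill]))
    guess <- ifelse(grepl("^[0-9]", nm) | grepl("^H", nm), "H",
                    substr(gsub("[0-9']", "", nm), 1, 1))
    two <- nm %in% c("FE", "ZN", "MG", "NA", "CL", "CA", "MN", "CU", "BR",
                     "SE", "CO", "NI")
    guess[two] <- nm[two]
    el[fill] <- guess
  }
  el
}

# Assemble the ensemble object: classify residues, renumber nodes 1..N in
# chain-then-file order, index atoms by node.
new_ensemble <- function(atoms, xyz, source = "memory") {
  stopifnot(nrow(atoms) * 3L == ncol(xyz))
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  node_of_atom <- match(res_key, unique(res_key))
  first_atom <- match(seq_along(unique(res_key)), node_of_atom)

  kind <- dplyr::case_when(
    atoms$resid[first_atom] %in% AMINO3 ~ "amino-acid",
    atoms$resid[first_atom] %in% NUCLEOTIDES ~ "nucleotide",
    .default = "hetero"
  )
  nodes <- tibble::tibble(
    node = seq_along(first_atom),
    chain = atoms$chain[first_atom],
    kind = kind,
    name = atoms$resid[first_atom],
    original_number = atoms$resno[first_atom],
    n_atoms = tabulate(node_of_atom, nbins = length(first_atom))
  )
  if (any(nodes$n_atoms == 0L)) abort("internal error: node with no atoms")
  atoms$node <- node_of_atom

  structure(
    list(atoms = atoms, nodes = nodes, xyz = xyz,
         frame_count = nrow(xyz), source = source),
    class = "sdri_ensemble"
  )
}

#' Renumber ensemble nodes continuously from 1
#'
#' Node indices are already assigned continuously when an ensemble is read or
#' generated; this re-derives them (chain-then-sequence file order, 1..N with
#' no gaps or repeats) and returns the ensemble together with the old-to-new
#' mapping. Author residue numbering (which may start anywhere, e.g. at 19)
#' is preserved in the `original_number` column for reporting.
#'
#' @param ensemble An `sdri_ensemble`.
#' @return The ensemble, with a `renumbering` attribute: a tibble mapping
#'   `chain` and `original_number` to the continuous `node` index.
#' @export
renumber_nodes <- function(ensemble) {
  stopifnot(inherits(ensemble, "sdri_ensemble"))
  mapping <- ensemble$nodes[, c("chain", "original_number", "node")]
  attr(ensemble, "renumbering") <- mapping
  ensemble
}

#' @export
print.sdri_ensemble <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf(
    "<sdri_ensemble> %d nodes (%s), %d atoms, %d frame%s\n",
    nrow(x$nodes),
    paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
    nrow(x$atoms), x$frame_count, if (x$frame_count == 1L) "" else "s"
  ))
  cat(sprintf("  chains: %s\n", paste(unique(x$nodes$chain), collapse = ", ")))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' @method as_tibble sdri_ensemble
#' @export
as_tibble.sdri_ensemble <- function(x, ...) x$nodes

n_nodes <- function(ensemble) nrow(ensemble$nodes)

#' Extract one frame's coordinates
#'
#' @param ensemble An `sdri_ensemble`.
#' @param frame Frame index (1-based).
#' @return A numeric atoms x 3 matrix of coordinates (Angstrom).
#' @export
frame_coords <- function(ensemble, frame = 1L) {
  if (frame < 1L || frame > ensemble$frame_count) {
    abort(sprintf("frame %d out of range (ensemble has %d frame(s))",
                  frame, ensemble$frame_count))
  }
  matrix(ensemble$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Restrict an ensemble to selected chains
#'
#' Keeps only the nodes of the given chains and renumbers the remainder
#' continuously. Scoring a sub-assembly this way differs from scoring the
#' full assembly and filtering afterwards: the network itself changes.
#'
#' @param ensemble An `sdri_ensemble`.
#' @param chains Character vector of chain identifiers to keep.
#' @export
filter_chains <- function(ensemble, chains) {
  keep_atoms <- which(ensemble$atoms$chain %in% chains)
  if (length(keep_atoms) == 0L) {
    abort(sprintf("no atoms on chain(s) %s", paste(chains, collapse = ", ")))
  }
  new_ensemble(ensemble$atoms[keep_atoms, ],
               ensemble$xyz[, bio3d::atom2xyz(keep_atoms), drop = FALSE],
               source = ensemble$source)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with fixed-width PDB columns
#' (coordinates to 3 decimals). Reading the file back with [read_ensemble()]
#' reproduces the topology exactly and coordinates to column precision.
#'
#' @param ensemble An `sdri_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  bio3d::write.pdb(
    file = path, xyz = ensemble$xyz, type = a$type,
    resno = a$resno, resid = a$resid, eleno = a$eleno, elety = a$elety,
    chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
    o = a$o, b = if (is.null(a$b)) 0 else a$b, elesy = a$element
  )
  invisible(path)
}

#' Write a single frame with per-node scores in the B-factor column
#'
#' Produces a heat-map PDB: every atom's temperature-factor column is set to
#' its node's normalized score scaled to 0-100, so molecular-graphics
#' spectrum coloring paints the ranking onto the structure.
#'
#' @param ensemble An `sdri_ensemble`.
#' @param scores Per-node normalized scores in `[0, 1]`, one per node.
#' @param frame Which frame's coordinates to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(ensemble, scores, frame = 1L, path) {
  if (length(scores) != n_nodes(ensemble)) {
    abort(sprintf("scores length %d does not match node count %d",
                  length(scores), n_nodes(ensemble)))
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    abort("scores must be finite normalized values in [0, 1]")
  }
  if (frame < 1L || frame > ensemble$frame_count) {
    abort(sprintf("frame %d out of range (ensemble has %d frame(s))",
                  frame, ensemble$frame_count))
  }
  a <- ensemble$atoms
  bio3d::write.pdb(
    file = path, xyz = ensemble$xyz[frame, ], type = a$type,
    resno = a$resno, resid = a$resid, eleno = a$eleno, elety = a$elety,
    chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
    o = a$o, b = round(scores[a$node] * 100, 2), elesy = a$element
  )
  invisible(path)
}

#' Write and read per-node score tables
#'
#' `write_score_table()` writes an SDRI profile as tab-separated text with
#' `#`-prefixed metadata header lines (recording the run configuration when
#' present); `read_score_table()` reads it back.
#'
#' @param profile A per-node score tibble, as returned by [sdri_score()]
#'   (any tibble with a `node` column is accepted).
#' @param path Output file path.
#' @param meta Optional named character vector written as `# key: value`
#'   header lines; defaults to the profile's `meta` attribute.
#' @return `path` (write) or a tibble (read).
#' @export
write_score_table <- function(profile, path, meta = attr(profile, "meta")) {
  if (!is.data.frame(profile) || nrow(profile) == 0L) {
    abort("profile is empty: refusing to write an empty score table")
  }
  if (!"node" %in% names(profile)) abort("profile must have a 'node' column")
  header <- character(0)
  if (!is.null(meta) && length(meta)) {
    header <- sprintf("# %s: %s", names(meta), unname(meta))
  }
  writeLines(header, path)
  readr::write_tsv(profile, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
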