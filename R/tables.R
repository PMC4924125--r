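#' Built-in whole-residue van der Waals radii
#'
#' Effective van der Waals radius of each standard amino-acid residue and
#' nucleotide, treating the whole residue (all of its atoms) as a single
#' sphere. Radii are derived from published mean residue partial volumes
#' (amino acids: Zamyatnin, Prog. Biophys. Mol. Biol. 24, 1972; nucleotides:
#' standard-state nucleotide volumes in the Voss & Gerstein volume library)
#' via the sphere-equivalent radius r = (3V / 4 pi)^(1/3).
#'
#' The normalized inter-node distance divides the center-of-mass separation
#' of two nodes by the sum of their radii, so every downstream score is
#' radius-table dependent. Supply your own table with [read_radius_table()]
#' to use a different parameterization; rankings are typically robust to the
#' choice because the radii enter as a smooth pairwise scale factor.
#'
#' @return A tibble with columns `name` (3-letter residue code or 1/2-letter
#'   nucleotide code) and `radius` (Angstrom).
#' @seealso [read_radius_table()], [node_adjacency()]
#' @export
#' @examples
#' vdw_radii()
vdw_radii <- function() {
  tibble::tibble(
    name = c(
      "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
      "A", "G", "C", "U", "DA", "DG", "DC", "DT"
    ),
    radius = c(
      2.766, 3.459, 3.009, 2.982, 2.959, 3.250, 3.209, 2.430, 3.319, 3.414,
      3.414, 3.427, 3.388, 3.566, 2.996, 2.770, 3.026, 3.789, 3.589, 3.221,
      4.221, 4.256, 4.097, 4.078, 4.207, 4.243, 4.082, 4.176
    )
  )
}

#' Built-in atomic masses
#'
#' Standard atomic weights (unified atomic mass units) for the elements that
#' occur in protein and nucleic-acid structures, plus common structural ions.
#'
#' @return A tibble with columns `element` and `mass`.
#' @export
atomic_masses <- function() {
  tibble::tibble(
    element = c(
      "H", "D", "C", "N", "O", "S", "P", "SE",
      "NA", "MG", "K", "CA", "ZN", "CL", "FE", "MN", "CU", "CO", "NI", "I", "BR", "F"
    ),
    mass = c(
      1.008, 2.014, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971,
      22.990, 24.305, 39.098, 40.078, 65.38, 35.45, 55.845, 54.938,
      63.546, 58.933, 58.693, 126.904, 79.904, 18.998
    )
  )
}

#' Read a user radius or mass override table
#'
#' Reads a two-column delimited text file (whitespace-, comma- or
#' tab-separated; `#` comments allowed) mapping a name to a positive value,
#' for use in place of [vdw_radii()] or [atomic_masses()].
#'
#' @param path Path to the table file.
#' @param value_name Name for the value column of the returned tibble.
#' @param key_name Name for the key column.
#' @return A two-column tibble.
#' @export
read_radius_table <- function(path, value_name = "radius", key_name = "name") {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE,
                           col.names = c(key_name, value_name))
  if (nrow(tab) == 0L) {
    abort(sprintf("no rows found in table file '%s'", path))
  }
  tab[[value_name]] <- as.numeric(tab[[value_name]])
  if (anyNA(tab[[value_name]]) || any(tab[[value_name]] <= 0)) {
    abort(sprintf("all values in '%s' must be positive numbers", path))
  }
  tibble::as_tibble(tab)
}

#' @rdname read_radius_table
#' @export
read_mass_table <- function(path) {
  read_radius_table(path, value_name = "mass", key_name = "element")
}

# name -> value lookup with a helpful error; `what` names the table in the
# error message, `who` optionally names the offending entity class.
lookup_table <- function(keys, table, key_col, value_col, what) {
  idx <- match(keys, table[[key_col]])
  if (anyNA(idx)) {
    missing <- sort(unique(keys[is.na(idx)]))
    abort(sprintf(
      "%s not found in %s table: %s",
      if (length(missing) > 1L) "entries" else "entry",
      what, paste(missing, collapse = ", ")
    ))
  }
  table[[value_col]][idx]
}
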