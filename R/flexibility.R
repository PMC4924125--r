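# Per-node flexibility: rigid-body superposition of frames and root mean
# square fluctuation of node centers of mass, or ingestion of an external
# per-residue flexibility table (e.g. chemical-shift-derived RMSF).

#' Superpose ensemble frames by rigid-body least squares
#'
#' Removes global translation/rotation by fitting every frame onto a
#' reference over a selection of guide atoms. The default selection uses
#' C-alpha atoms for amino acids and C1' atoms for nucleotides; the default
#' reference is the ensemble mean, refined iteratively (fit, recompute mean,
#' refit). Fluctuations measured after superposition reflect internal motion
#' rather than rigid drift.
#'
#' @param ensemble An `sdri_ensemble` with >= 2 frames.
#' @param selection `"guide"` (Calpha / C1', default), `"backbone"`
#'   (N, CA, C protein backbone plus nucleic P, C1'), or `"all-heavy"`.
#' @param reference `"mean"` (iterated mean structure, default) or
#'   `"first"` frame.
#' @param iterations Mean-structure refinement passes (ignored for
#'   `reference = "first"`).
#' @return The ensemble with transformed coordinates; superposition settings
#'   are recorded in the `superposition` attribute.
#' @export
superpose_frames <- function(ensemble,
                             selection = c("guide", "backbone", "all-heavy"),
                             reference = c("mean", "first"),
                             iterations = 2L) {
  selection <- match.arg(selection)
  reference <- match.arg(reference)
  if (ensemble$frame_count < 2L) abort("superposition needs at least 2 frames")

  a <- ensemble$atoms
  sel_atoms <- switch(
    selection,
    "guide" = which((a$elety == "CA" & !a$is_hydrogen) | a$elety == "C1'"),
    "backbone" = which(a$elety %in% c("N", "CA", "C", "P", "C1'") & !a$is_hydrogen),
    "all-heavy" = which(!a$is_hydrogen)
  )
  if (length(sel_atoms) == 0L && selection == "guide") {
    # e.g. coarse models without canonical atom names
    sel_atoms <- which(!a$is_hydrogen)
  }
  if (length(sel_atoms) < 3L) {
    abort("fewer than 3 selection atoms: rigid-body fit is under-determined")
  }
  inds <- bio3d::atom2xyz(sel_atoms)

  xyz <- ensemble$xyz
  ref <- xyz[1L, ]
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  if (reference == "mean") {
    for (k in seq_len(iterations)) {
      ref <- colMeans(fitted)
      fitted <- bio3d::fit.xyz(fixed = ref, mobile = fitted,
                               fixed.inds = inds, mobile.inds = inds)
    }
  }
  ensemble$xyz <- fitted
  attr(ensemble, "superposition") <- list(selection = selection,
                                          reference = reference,
                                          n_fit_atoms = length(sel_atoms))
  ensemble
}

#' Root mean square fluctuation of node centers of mass
#'
#' For each node, `RMSF_i = sqrt(mean_t |com_i(t) - <com_i>|^2)` over the
#' (superposed) frames. The node's center of mass is computed as in
#' [node_com()], so all atoms of the node contribute, mass-weighted.
#'
#' Any node with zero fluctuation makes the SDRI score `H / RMSF` undefined,
#' so a static ensemble is an error rather than a silently-masked value;
#' supply an external flexibility table or more frames instead.
#'
#' @param ensemble A superposed `sdri_ensemble` with >= 2 frames (set
#'   `superposed = FALSE` to skip the in-place superposition).
#' @param masses Element mass table.
#' @param superposed Set `TRUE` if the ensemble is already superposed.
#' @return A tibble with columns `node`, `rmsf` (Angstrom); attribute
#'   `source = "ensemble"`.
#' @export
node_rmsf <- function(ensemble, masses = atomic_masses(), superposed = FALSE) {
  if (ensemble$frame_count < 2L) {
    abort("RMSF needs at least 2 frames; a single structure carries no fluctuation")
  }
  if (!superposed && is.null(attr(ensemble, "superposition"))) {
    ensemble <- superpose_frames(ensemble)
  }
  n <- n_nodes(ensemble)
  m <- lookup_table(ensemble$atoms$element, masses, "element", "mass", "mass")
  coms <- array(0, dim = c(ensemble$frame_count, n, 3L))
  for (f in seq_len(ensemble$frame_count)) {
    coms[f, , ] <- com_from_coords(frame_coords(ensemble, f), m,
                                   ensemble$atoms$node, n)
  }
  mean_com <- apply(coms, c(2L, 3L), mean)
  sq <- sweep(coms, c(2L, 3L), mean_com)^2
  rmsf <- sqrt(rowMeans(apply(sq, 1L, function(fr) rowSums(fr))))
  # apply() above returns n x frames; rowMeans gives per-node mean square
  out <- tibble::tibble(node = seq_len(n), rmsf = rmsf)
  attr(out, "source") <- "ensemble"
  attr(out, "superposition") <- attr(ensemble, "superposition")
  out
}

#' Load an external per-residue flexibility table
#'
#' Reads a two-column delimited file (node index or author residue number,
#' RMSF in Angstrom), e.g. random-coil-index derived RMSF for an NMR
#' ensemble. Rows are matched to the ensemble's nodes first by continuous
#' node index and, if that fails, by author residue number; the file must
#' cover every node exactly once.
#'
#' @param path Path to the table.
#' @param nodes Node tibble of the target ensemble (`ensemble$nodes`).
#' @return A tibble with columns `node`, `rmsf`; attribute
#'   `source = "external"`.
#' @export
read_rmsf_table <- function(path, nodes) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE,
                           col.names = c("id", "rmsf"))
  tab$id <- as.integer(tab$id)
  tab$rmsf <- as.numeric(tab$rmsf)
  if (anyNA(tab$rmsf) || any(tab$rmsf < 0)) {
    abort(sprintf("'%s': RMSF values must be non-negative numbers", path))
  }
  n <- nrow(nodes)

  match_by <- function(keys) {
    idx <- match(keys, tab$id)
    if (anyNA(idx) || nrow(tab) != n || anyDuplicated(idx)) NULL else tab$rmsf[idx]
  }
  vals <- match_by(nodes$node)
  if (is.null(vals)) vals <- match_by(nodes$original_number)
  if (is.null(vals)) {
    unmatched_n <- setdiff(nodes$node, tab$id)
    unmatched_o <- setdiff(nodes$original_number, tab$id)
    abort(sprintf(
      paste0("'%s' does not align with the ensemble: %d rows for %d nodes; ",
             "unmatched node indices: %s; unmatched author numbers: %s"),
      path, nrow(tab), n,
      paste(utils::head(unmatched_n, 5L), collapse = ", "),
      paste(utils::head(unmatched_o, 5L), collapse = ", ")
    ))
  }
  out <- tibble::tibble(node = nodes$node, rmsf = vals)
  attr(out, "source") <- "external"
  out
}
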