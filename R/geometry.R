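# Residue interaction network geometry: centers of mass, van der Waals
# normalized distances, the frame-averaged weighted adjacency matrix, and
# the contact-grade (degree) metric.

#' Mass-weighted centers of mass for every node
#'
#' Computes each node's center of mass in one frame, over all of the node's
#' atoms. Hydrogens contribute when present (MD frames); crystal structures
#' without hydrogens give heavy-atom centers.
#'
#' @param ensemble An `sdri_ensemble`.
#' @param frame Frame index.
#' @param masses Element mass table, see [atomic_masses()].
#' @return A nodes x 3 numeric matrix (Angstrom).
#' @export
node_com <- function(ensemble, frame = 1L, masses = atomic_masses()) {
  coords <- frame_coords(ensemble, frame)
  m <- lookup_table(ensemble$atoms$element, masses, "element", "mass", "mass")
  com_from_coords(coords, m, ensemble$atoms$node, n_nodes(ensemble))
}

com_from_coords <- function(coords, m, node, n) {
  wsum <- rowsum(coords * m, node, reorder = TRUE)
  mtot <- rowsum(m, node, reorder = TRUE)[, 1L]
  if (any(mtot <= 0)) abort("node with non-positive total mass")
  wsum / mtot
}

#' Normalized inter-node distance
#'
#' The center-of-mass distance between two nodes divided by the sum of their
#' whole-residue van der Waals radii. Values below 1 mark strongly
#' interacting (interpenetrating-sphere) pairs.
#'
#' @param com_i,com_j Centers of mass, 3-vectors (Angstrom).
#' @param r_i,r_j Whole-residue van der Waals radii (Angstrom).
#' @return Dimensionless scalar.
#' @export
#' @examples
#' normalized_distance(c(0, 0, 0), c(7, 0, 0), 3, 4) # = 1
normalized_distance <- function(com_i, com_j, r_i, r_j) {
  stopifnot(r_i + r_j > 0)
  sqrt(sum((com_i - com_j)^2)) / (r_i + r_j)
}

#' Frame-averaged weighted adjacency matrix of the residue network
#'
#' For every node pair and frame, the center-of-mass distance is normalized
#' by the summed van der Waals radii; the per-pair normalized distances are
#' then reduced over frames and inverted so that close pairs carry large
#' weights. The default `weight_mode = "inverse-of-mean"` sets
#' `a_ij = 1 / mean_t(dbar_ij(t))`; the alternative `"mean-of-inverse"` uses
#' `a_ij = mean_t(1 / dbar_ij(t))`. Weights are rounded to
#' `round_decimals` places (default 4), the diagonal is zero, and the matrix
#' is symmetric. No distance cutoff is applied: every pair is connected with
#' a weight that decays with separation.
#'
#' @param ensemble An `sdri_ensemble` with at least 2 frames.
#' @param radii Whole-residue radius table, see [vdw_radii()].
#' @param masses Element mass table.
#' @param weight_mode `"inverse-of-mean"` (default) or `"mean-of-inverse"`.
#' @param round_decimals Integer number of decimals to round weights to, or
#'   `NULL` to disable rounding.
#' @return An N x N symmetric non-negative matrix with zero diagonal, with
#'   attributes `weight_mode` and `round_decimals`.
#' @export
node_adjacency <- function(ensemble, radii = vdw_radii(),
                           masses = atomic_masses(),
                           weight_mode = c("inverse-of-mean", "mean-of-inverse"),
                           round_decimals = 4L) {
  weight_mode <- match.arg(weight_mode)
  if (ensemble$frame_count < 2L) {
    abort("adjacency needs an ensemble with at least 2 frames")
  }
  n <- n_nodes(ensemble)
  r <- lookup_table(ensemble$nodes$name, radii, "name", "radius", "van der Waals radius")
  rsum <- outer(r, r, "+")
  m <- lookup_table(ensemble$atoms$element, masses, "element", "mass", "mass")

  acc <- matrix(0, n, n)
  for (f in seq_len(ensemble$frame_count)) {
    com <- com_from_coords(frame_coords(ensemble, f), m, ensemble$atoms$node, n)
    d <- as.matrix(stats::dist(com))
    if (any(d[upper.tri(d)] == 0)) {
      bad <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1L, ]
      abort(sprintf("coincident centers of mass for nodes %d and %d in frame %d",
                    bad[2L], bad[1L], f))
    }
    dbar <- d / rsum
    acc <- acc + if (weight_mode == "mean-of-inverse") {
      ifelse(dbar > 0, 1 / dbar, 0)
    } else {
      dbar
    }
  }
  mean_mat <- acc / ensemble$frame_count
  a <- if (weight_mode == "mean-of-inverse") {
    mean_mat
  } else {
    ifelse(mean_mat > 0, 1 / mean_mat, 0)
  }
  diag(a) <- 0
  dimnames(a) <- NULL
  if (!is.null(round_decimals)) a <- round(a, round_decimals)
  structure(a, weight_mode = weight_mode, round_decimals = round_decimals)
}

#' Contact grade (degree) of every node
#'
#' The grade K_i of a node is the number of other nodes with at least one
#' heavy-atom pair within the cutoff distance. Hydrogens are ignored; the
#' whole assembly is considered, so inter-chain contacts count.
#'
#' @param ensemble An `sdri_ensemble`.
#' @param frame Frame on which contacts are evaluated (default the first
#'   model, i.e. the experimental structure for NMR/crystal input).
#' @param cutoff Contact distance threshold in Angstrom (edge when the
#'   closest heavy-atom pair is at distance <= cutoff).
#' @return A tibble with columns `node`, `chain`, `name`, `original_number`,
#'   `grade`.
#' @export
node_grade <- function(ensemble, frame = 1L, cutoff = 5.0) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be a positive distance")
  heavy <- which(!ensemble$atoms$is_hydrogen)
  if (length(heavy) == 0L) abort("no heavy atoms in ensemble")
  coords <- frame_coords(ensemble, frame)[heavy, , drop = FALSE]
  node <- ensemble$atoms$node[heavy]
  n <- n_nodes(ensemble)

  d <- as.matrix(stats::dist(coords))
  contact <- d <= cutoff
  # collapse the atom-level contact map to node level: any contacting
  # heavy-atom pair connects the two nodes
  node_contact <- rowsum(contact + 0, node) > 0
  node_contact <- t(rowsum(t(node_contact) + 0, node) > 0)
  diag(node_contact) <- FALSE
  grade <- as.integer(rowSums(node_contact))

  out <- ensemble$nodes[, c("node", "chain", "name", "original_number")]
  out$grade <- grade
  attr(out, "cutoff") <- cutoff
  attr(out, "frame") <- frame
  out
}
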