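# Shared fixtures and independent brute-force oracles for the test suite.

# Fixed-column PDB ATOM line (short atom names, single-character chain).
pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                          record = "ATOM  ", elesy = substr(elety, 1, 1)) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, elety, resid, chain, resno, x, y, z, 1.00, 0.00, elesy)
}

# Write a multi-model PDB given a list of per-model coordinate matrices and
# a shared atom table (data.frame: elety, resid, chain, resno, record).
write_toy_pdb <- function(path, atom_table, model_coords) {
  lines <- character(0)
  for (m in seq_along(model_coords)) {
    xyz <- model_coords[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(atom_table))) {
      a <- atom_table[i, ]
      rec <- if (is.null(a$record)) "ATOM  " else a$record
      lines <- c(lines, pdb_atom_line(i, a$elety, a$resid, a$chain, a$resno,
                                      xyz[i, 1], xyz[i, 2], xyz[i, 3],
                                      record = rec))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Three-residue, single-chain atom table (one atom per residue keeps the
# geometry transparent).
toy_atoms_3res <- function(resno = c(19L, 20L, 21L)) {
  data.frame(
    elety = c("CA", "CA", "CA"),
    resid = c("GLY", "ALA", "SER"),
    chain = "A",
    resno = resno,
    stringsAsFactors = FALSE
  )
}

# --- independent oracles ----------------------------------------------------

# Frame-averaged adjacency by naive per-frame loops (no vectorization).
adjacency_oracle <- function(ensemble, radii = vdw_radii(),
                             masses = atomic_masses(),
                             weight_mode = "inverse-of-mean",
                             round_decimals = NULL) {
  n <- nrow(ensemble$nodes)
  r <- radii$radius[match(ensemble$nodes$name, radii$name)]
  m <- masses$mass[match(ensemble$atoms$element, masses$element)]
  acc <- matrix(0, n, n)
  for (f in seq_len(ensemble$frame_count)) {
    coords <- frame_coords(ensemble, f)
    com <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      rows <- which(ensemble$atoms$node == i)
      w <- m[rows]
      com[i, ] <- colSums(coords[rows, , drop = FALSE] * w) / sum(w)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dbar <- sqrt(sum((com[i, ] - com[j, ])^2)) / (r[i] + r[j])
        acc[i, j] <- acc[i, j] +
          if (weight_mode == "mean-of-inverse") 1 / dbar else dbar
      }
    }
  }
  mean_mat <- acc / ensemble$frame_count
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      a[i, j] <- if (weight_mode == "mean-of-inverse") mean_mat[i, j] else 1 / mean_mat[i, j]
    }
  }
  if (!is.null(round_decimals)) a <- round(a, round_decimals)
  a
}

# Contact grade by all-pairs all-atoms loops.
grade_oracle <- function(ensemble, frame = 1, cutoff = 5) {
  coords <- frame_coords(ensemble, frame)
  heavy <- !ensemble$atoms$is_hydrogen
  n <- nrow(ensemble$nodes)
  K <- integer(n)
  for (i in seq_len(n)) {
    ai <- which(ensemble$atoms$node == i & heavy)
    for (j in seq_len(n)) {
      if (i == j) next
      aj <- which(ensemble$atoms$node == j & heavy)
      hit <- FALSE
      for (p in ai) {
        for (q in aj) {
          if (sqrt(sum((coords[p, ] - coords[q, ])^2)) <= cutoff) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      if (hit) K[i] <- K[i] + 1L
    }
  }
  K
}

# Textbook bias-corrected sample skewness and excess kurtosis.
skewness_oracle <- function(x) {
  n <- length(x)
  s <- sd(x)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

kurtosis_oracle <- function(x) {
  n <- length(x)
  s <- sd(x)
  (n * (n + 1)) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}
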