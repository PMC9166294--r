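# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's own solver paths.

# Dense Moore-Penrose pseudoinverse solution of the resistor network:
# potentials, throughflow and effective resistance computed from ginv(L),
# independent of the grounded sparse solve in the package.
oracle_flow <- function(W, sources, sinks) {
  labs <- rownames(W)
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  b <- numeric(n)
  b[match(sources, labs)] <- 1 / length(sources)
  b[match(sinks, labs)] <- b[match(sinks, labs)] - 1 / length(sinks)
  v <- as.numeric(MASS::ginv(L) %*% b)
  curr <- W * outer(v, v, "-")
  thr <- 0.5 * rowSums(abs(curr))
  st <- match(c(sources, sinks), labs)
  thr[st] <- abs(rowSums(curr)[st])
  names(thr) <- labs
  names(v) <- labs
  list(potentials = v, throughflow = thr,
       effective_resistance = mean(v[sources]) - mean(v[sinks]))
}

# Brute-force contact graph: plain loops over frames, node pairs and atom
# pairs, no vectorization.
oracle_contact_graph <- function(traj, node_map, params) {
  labs <- node_map$nodes$label
  n <- length(labs)
  acc <- matrix(0, n, n, dimnames = list(labs, labs))
  for (k in seq_len(traj$n_frames)) {
    fr <- matrix(traj$coords[k, , ], ncol = 3)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmin <- Inf
      for (a in node_map$members[[labs[i]]])
        for (b in node_map$members[[labs[j]]]) {
          d <- sqrt(sum((fr[a, ] - fr[b, ])^2))
          if (d < dmin) dmin <- d
        }
      s <- stats::pnorm(dmin, params$c, params$sigma, lower.tail = FALSE)
      acc[i, j] <- acc[i, j] + s
      acc[j, i] <- acc[j, i] + s
    }
  }
  w <- acc / traj$n_frames
  w[w < params$prune_below] <- 0
  w
}

# minimal in-memory structure/trajectory builders (single-atom residues)
point_structure <- function(coords, resname = "ALA", chain = "A") {
  df <- data.frame(atom_name = "CA", element = "C",
                   resnum = seq_len(nrow(coords)), resname = resname,
                   chain = chain, x = coords[, 1], y = coords[, 2],
                   z = coords[, 3], stringsAsFactors = FALSE)
  pathflow:::make_point_structure(df)
}

traj_from_frames <- function(structure, frames) {
  pathflow:::new_trajectory_ensemble(structure, frames)
}

# a contact graph built directly from a conductance matrix
graph_from_weights <- function(W, labels = rownames(W),
                               kinds = rep("residue", nrow(W))) {
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(nrow(W)))
  pathflow:::new_contact_graph(W, labels, kinds, 1L,
                               contact_params(), validate_range = FALSE)
}

# small peptide + ligand PDB text (fixed-column), with hydrogens
peptide_pdb_lines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  H   GLY A   1      -0.500  -0.850   0.000  1.00  0.00           H",
    "ATOM      6  N   ALA A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       4.000   2.750   0.000  1.00  0.00           C",
    "ATOM      8  CB  ALA A   2       5.500   2.600   0.200  1.00  0.00           C",
    "ATOM      9  C   ALA A   2       3.500   3.800   1.000  1.00  0.00           C",
    "ATOM     10  O   ALA A   2       3.600   5.000   0.800  1.00  0.00           O",
    "ATOM     11  N   SER A   3       3.000   3.300   2.150  1.00  0.00           N",
    "ATOM     12  CA  SER A   3       2.450   4.200   3.150  1.00  0.00           C",
    "ATOM     13  OG  SER A   3       1.100   3.900   3.400  1.00  0.00           O",
    "HETATM   14  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O")
}

write_peptide_pdb <- function(path, lines = peptide_pdb_lines()) {
  writeLines(c(lines, "END"), path)
  path
}

# full synthetic cholesterol molecule appended to the peptide
peptide_with_clr_pdb <- function(path, n_clr = 1) {
  tmpl <- clr_template()
  lines <- peptide_pdb_lines()
  serial <- 14
  for (m in seq_len(n_clr)) {
    off <- c(15 + 10 * m, 0, 0)
    for (i in seq_len(nrow(tmpl))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "HETATM%5d  %-3s CLR L%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, tmpl$atom_name[i], 200 + m,
        tmpl$x[i] + off[1], tmpl$y[i] + off[2], tmpl$z[i] + off[3],
        tmpl$element[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
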