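# Trajectory observables: Kabsch superposition, per-residue RMSF, pairwise
# Calpha distance series/histograms, hydrogen-bond occupancy, and bound-ligand
# stability.

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, Se = 78.971, F = 18.998,
                    Cl = 35.45, Br = 79.904)

atom_masses <- function(elements) {
  m <- .atomic_masses[elements]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD of `mobile %*% R + t` to `reference`.
#' Reflections are excluded by the determinant correction.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, not all
#'   collinear.
#' @param weights Optional nonnegative weights, length `n`.
#' @return An `alignment` list: `rotation` (3x3, `det = +1`), `translation`
#'   (length-3), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    pf_error("usage_error", "point sets must be equal-size n x 3 matrices")
  n <- nrow(P)
  if (n < 3) pf_error("geometry_error", "need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2)
    pf_error("geometry_error", "degenerate (collinear) point configuration")
  C <- t(Pc * w) %*% Qc
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- Pc %*% R
  rmsd <- sqrt(sum(w * rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = qc - as.numeric(pc %*% R),
                 rmsd = rmsd),
            class = "alignment")
}

apply_alignment <- function(coords, alignment) {
  sweep(coords %*% alignment$rotation, 2, alignment$translation, "+")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: rmsd %.4f A (det R = %+.3f)\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

# Superpose all frames on a reference using the given atom subset; returns
# the aligned coordinate array.
align_frames <- function(coords, ref, align_idx) {
  for (k in seq_len(dim(coords)[1])) {
    fr <- matrix(coords[k, , ], ncol = 3)
    al <- kabsch_superpose(fr[align_idx, , drop = FALSE],
                           ref[align_idx, , drop = FALSE])
    coords[k, , ] <- apply_alignment(fr, al)
  }
  coords
}

default_ca_selection <- function(topology) {
  at <- topology$atoms
  which(at$atom_name == "CA" & at$residue_name %in% .standard_aa)
}

#' Per-residue root mean square fluctuation
#'
#' When `align = TRUE`, frames are superposed on the iterated mean structure
#' (two passes) using all protein Calpha atoms, then
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)`.
#'
#' @param traj A `trajectory_ensemble` with at least 2 frames.
#' @param selection Atom indices to report; defaults to all protein Calpha
#'   atoms.
#' @param align Superpose frames before computing fluctuations.
#' @param align_selection Atom indices used for the superposition; defaults
#'   to all protein Calpha atoms.
#' @return Data frame (node_label, rmsf) in Angstrom, one row per selected
#'   atom, labelled by residue.
#' @export
compute_rmsf <- function(traj, selection = NULL, align = TRUE,
                         align_selection = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (traj$n_frames < 2L)
    pf_error("degenerate_input_error", "RMSF needs at least 2 frames")
  at <- traj$topology$atoms
  if (is.null(selection)) selection <- default_ca_selection(traj$topology)
  if (length(selection) == 0L)
    pf_error("usage_error", "empty atom selection")
  coords <- traj$coords
  if (align) {
    if (is.null(align_selection))
      align_selection <- default_ca_selection(traj$topology)
    if (length(align_selection) < 3L) align_selection <- selection
    ref <- matrix(coords[1, , ], ncol = 3)
    for (pass in 1:2) {
      coords <- align_frames(coords, ref, align_selection)
      ref <- apply(coords, c(2, 3), mean)
    }
  }
  mean_pos <- apply(coords[, selection, , drop = FALSE], c(2, 3), mean)
  dev2 <- 0
  for (k in seq_len(traj$n_frames)) {
    d <- matrix(coords[k, selection, ], ncol = 3) - mean_pos
    dev2 <- dev2 + rowSums(d^2)
  }
  rmsf <- sqrt(dev2 / traj$n_frames)
  data.frame(
    node_label = node_label(at$chain_id[selection],
                            at$residue_name[selection],
                            at$residue_number[selection]),
    rmsf = rmsf, stringsAsFactors = FALSE)
}

#' Per-frame distance between two atoms, with a density histogram
#'
#' @param traj A `trajectory_ensemble`.
#' @param atom_a,atom_b Distinct atom indices.
#' @param bin_width Histogram bin width in Angstrom, bins anchored at 0.
#' @return A `distance_series`: per-frame distances (Angstrom), histogram
#'   breaks and densities (densities sum to 1 over bins after multiplying by
#'   the bin width).
#' @export
pair_distance_series <- function(traj, atom_a, atom_b, bin_width = 0.5) {
  if (identical(atom_a, atom_b))
    pf_error("usage_error", "atoms must be distinct")
  n_at <- dim(traj$coords)[2]
  if (any(c(atom_a, atom_b) < 1) || any(c(atom_a, atom_b) > n_at))
    pf_error("lookup_error", "atom index out of range")
  d <- sqrt(rowSums((traj$coords[, atom_a, , drop = TRUE] -
                     traj$coords[, atom_b, , drop = TRUE])^2))
  if (traj$n_frames == 1L) d <- sqrt(sum((traj$coords[1, atom_a, ] -
                                          traj$coords[1, atom_b, ])^2))
  breaks <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(atom_a = atom_a, atom_b = atom_b, values = d,
                 breaks = h$breaks, density = h$counts /
                   (length(d) * bin_width)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series: atoms %d-%d, %d frames, mean %.2f A (range %.2f-%.2f)\n",
              x$atom_a, x$atom_b, length(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Hydrogen-bond criteria
#'
#' @param da_cutoff Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param dha_angle_min Minimum D-H...A angle in degrees, applied only when
#'   hydrogens are present in the topology.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(da_cutoff = 3.0, dha_angle_min = 150) {
  da_cutoff <- parse_length(da_cutoff, "da_cutoff")
  if (da_cutoff <= 0) pf_error("config_error", "da_cutoff must be > 0")
  if (dha_angle_min <= 0 || dha_angle_min > 180)
    pf_error("config_error", "dha_angle_min must lie in (0, 180]")
  structure(list(da_cutoff = da_cutoff, dha_angle_min = dha_angle_min),
            class = "hbond_criteria")
}

# hydrogens covalently attached to a donor: same residue, within 1.25 A in
# the first frame
attached_hydrogens <- function(traj, donor) {
  at <- traj$topology$atoms
  h_idx <- which(at$element == "H" &
                 at$chain_id == at$chain_id[donor] &
                 at$residue_number == at$residue_number[donor])
  if (length(h_idx) == 0L) return(integer(0))
  d0 <- matrix(traj$coords[1, , ], ncol = 3)
  dd <- sqrt(rowSums((d0[h_idx, , drop = FALSE] -
                      matrix(d0[donor, ], length(h_idx), 3,
                             byrow = TRUE))^2))
  h_idx[dd <= 1.25]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A frame counts for a donor-acceptor pair when the heavy-atom
#' donor-acceptor distance is at most `da_cutoff` and, when the donor has an
#' attached hydrogen in the topology, the D-H...A angle of some attached
#' hydrogen is at least `dha_angle_min`.  Occupancy is the counted fraction
#' of frames.
#'
#' @param traj A `trajectory_ensemble`.
#' @param donors,acceptors Nonempty atom index vectors (heavy atoms).
#' @param criteria An [hbond_criteria()] object.
#' @return Data frame (donor, acceptor, occupancy).
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria()) {
  if (length(donors) == 0L || length(acceptors) == 0L)
    pf_error("usage_error", "donor and acceptor selections must be nonempty")
  out <- expand.grid(donor = donors, acceptor = acceptors)
  out <- out[out$donor != out$acceptor, , drop = FALSE]
  occ <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    don <- out$donor[r]; acc <- out$acceptor[r]
    hs <- attached_hydrogens(traj, don)
    hits <- 0L
    for (k in seq_len(traj$n_frames)) {
      fr <- matrix(traj$coords[k, , ], ncol = 3)
      dda <- sqrt(sum((fr[don, ] - fr[acc, ])^2))
      if (dda > criteria$da_cutoff) next
      if (length(hs) > 0L) {
        ok <- FALSE
        for (h in hs) {
          v1 <- fr[don, ] - fr[h, ]; v2 <- fr[acc, ] - fr[h, ]
          ang <- acos(pmin(pmax(sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
            180 / pi
          if (ang >= criteria$dha_angle_min) { ok <- TRUE; break }
        }
        if (!ok) next
      }
      hits <- hits + 1L
    }
    occ[r] <- hits / traj$n_frames
  }
  data.frame(donor = out$donor, acceptor = out$acceptor, occupancy = occ)
}

#' Bound-ligand stability: COM displacement and RMSD per frame
#'
#' Each frame is superposed on the first frame using the protein selection;
#' the ligand's mass-weighted center-of-mass displacement and heavy-atom RMSD
#' relative to the first frame are then reported.
#'
#' @param traj A `trajectory_ensemble`.
#' @param node_map A `node_map` containing the interactor.
#' @param interactor_label Interactor node label.
#' @param protein_selection Atom indices used for the superposition; defaults
#'   to all protein Calpha atoms.
#' @return Data frame (frame, com_displacement, rmsd) in Angstrom.
#' @export
ligand_displacement <- function(traj, node_map, interactor_label,
                                protein_selection = NULL) {
  if (traj$n_frames < 2L)
    pf_error("degenerate_input_error", "need at least 2 frames")
  lig <- node_map$members[[interactor_label]]
  if (is.null(lig) || length(lig) == 0L)
    pf_error("lookup_error", sprintf("unknown or empty interactor '%s'",
                                     interactor_label))
  if (is.null(protein_selection))
    protein_selection <- default_ca_selection(traj$topology)
  if (length(protein_selection) < 3L)
    pf_error("geometry_error", "protein selection too small to superpose")
  masses <- atom_masses(traj$topology$atoms$element[lig])
  ref <- matrix(traj$coords[1, , ], ncol = 3)
  lig_ref <- ref[lig, , drop = FALSE]
  com_ref <- colSums(lig_ref * masses) / sum(masses)
  com_disp <- numeric(traj$n_frames); rmsd <- numeric(traj$n_frames)
  for (k in seq_len(traj$n_frames)) {
    fr <- matrix(traj$coords[k, , ], ncol = 3)
    al <- kabsch_superpose(fr[protein_selection, , drop = FALSE],
                           ref[protein_selection, , drop = FALSE])
    fr <- apply_alignment(fr, al)
    lk <- fr[lig, , drop = FALSE]
    com <- colSums(lk * masses) / sum(masses)
    com_disp[k] <- sqrt(sum((com - com_ref)^2))
    rmsd[k] <- sqrt(mean(rowSums((lk - lig_ref)^2)))
  }
  data.frame(frame = seq_len(traj$n_frames), com_displacement = com_disp,
             rmsd = rmsd)
}
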