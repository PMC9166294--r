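# Superposition, RMSF, distance histograms, hydrogen bonds, ligand stability

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  al0 <- kabsch_superpose(P, P)
  expect_equal(al0$rmsd, 0, tolerance = 1e-9)
  expect_equal(al0$rotation, diag(3), tolerance = 1e-9)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Q <- P %*% R + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  al <- kabsch_superpose(P, Q)
  expect_equal(al$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)
  expect_equal(pathflow:::apply_alignment(P, al), Q, tolerance = 1e-9)
})

test_that("mirror images get a proper rotation, verified by rotation sampling", {
  Tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.8))
  M <- Tri %*% diag(c(-1, 1, 1))
  al <- kabsch_superpose(M, Tri)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)
  expect_gt(al$rmsd, 0)
  # brute-force oracle: no sampled proper rotation beats the returned rmsd
  cen <- function(X) sweep(X, 2, colMeans(X))
  Mc <- cen(M); Tc <- cen(Tri)
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf
  for (a in angles) for (b in angles) for (cc in angles) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(cc), -sin(cc), 0, sin(cc), cos(cc), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    Rg <- Rz %*% Ry %*% Rz2
    best <- min(best, sqrt(mean(rowSums((Mc %*% Rg - Tc)^2))))
  }
  expect_lte(al$rmsd, best + 1e-9)
  expect_error(kabsch_superpose(Tri[1:2, ], Tri[1:2, ]),
               class = "pathflow_geometry_error")
  collinear <- cbind(0:3, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear),
               class = "pathflow_geometry_error")
})

test_that("RMSF matches its definition on constructed displacements", {
  s <- point_structure(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                             c(10, 10, 0)))
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  # static trajectory: all zero
  tr <- traj_from_frames(s, list(base, base, base))
  expect_equal(compute_rmsf(tr, align = FALSE)$rmsf, rep(0, 4))
  expect_error(compute_rmsf(traj_from_frames(s, list(base))),
               class = "pathflow_degenerate_input_error")
  # one atom displaced +/- delta about its mean: RMSF = delta
  delta <- 0.7
  f1 <- base; f1[2, 1] <- f1[2, 1] + delta
  f2 <- base; f2[2, 1] <- f2[2, 1] - delta
  r <- compute_rmsf(traj_from_frames(s, list(f1, f2)), align = FALSE)
  expect_equal(r$rmsf[2], delta, tolerance = 1e-12)
  expect_equal(r$rmsf[-2], rep(0, 3))
})

test_that("isotropic Gaussian noise gives RMSF = sqrt(3) sigma", {
  s <- point_structure(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  sigma <- 0.5
  set.seed(99)
  frames <- lapply(1:10000, function(k)
    base + matrix(rnorm(9, sd = sigma), 3, 3))
  r <- compute_rmsf(traj_from_frames(s, frames), align = FALSE)
  expect_equal(r$rmsf, rep(sqrt(3) * sigma, 3), tolerance = 0.03)
})

test_that("aligned RMSF is invariant to global rigid motion of all frames", {
  enm <- sample_enm_trajectory(helix_coords <- pathflow:::helix_coords(12),
                               n_frames = 60, seed = 17)
  r0 <- compute_rmsf(enm$traj, align = TRUE)
  moved <- enm$traj
  set.seed(5)
  for (k in seq_len(moved$n_frames)) {
    th <- runif(1, 0, 2 * pi); ph <- runif(1, 0, pi)
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(ph), 0, sin(ph), 0, 1, 0, -sin(ph), 0, cos(ph)),
                 3, 3, byrow = TRUE)
    moved$coords[k, , ] <- matrix(moved$coords[k, , ], ncol = 3) %*%
      (Rz %*% Ry) + matrix(runif(3, -20, 20), nrow(helix_coords), 3,
                           byrow = TRUE)
  }
  r1 <- compute_rmsf(moved, align = TRUE)
  expect_equal(r1$rmsf, r0$rmsf, tolerance = 1e-6)
})

test_that("distance histograms are density-normalized and order-invariant", {
  s <- point_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  f10 <- rbind(c(0, 0, 0), c(10, 0, 0))
  f12 <- rbind(c(0, 0, 0), c(12, 0, 0))
  tr <- traj_from_frames(s, list(f10, f12))
  ds <- pair_distance_series(tr, 1, 2, bin_width = 1)
  expect_equal(sort(ds$values), c(10, 12))
  expect_equal(sum(ds$density) * 1, 1)
  expect_equal(sort(ds$density[ds$density > 0]), c(0.5, 0.5))
  # constant geometry: a single occupied bin
  trc <- traj_from_frames(s, list(f10, f10, f10))
  dsc <- pair_distance_series(trc, 1, 2, bin_width = 0.5)
  expect_equal(sum(dsc$density > 0), 1)
  expect_equal(sum(dsc$density) * 0.5, 1)
  # frame order irrelevant
  ds2 <- pair_distance_series(traj_from_frames(s, list(f12, f10)), 1, 2,
                              bin_width = 1)
  expect_identical(ds2$density, ds$density)
  expect_error(pair_distance_series(tr, 1, 1),
               class = "pathflow_usage_error")
})

test_that("hydrogen-bond occupancy counts distance (and angle) criteria", {
  # donor with explicit hydrogen, acceptor across
  df <- data.frame(atom_name = c("OG", "HG", "OD1"),
                   element = c("O", "H", "O"),
                   resnum = c(1, 1, 2), resname = c("SER", "SER", "ASP"),
                   chain = "A", x = c(0, 0.95, 2.8), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  s <- pathflow:::make_point_structure(df)
  lin <- as.matrix(df[, c("x", "y", "z")])     # D-H...A angle 180
  far <- lin; far[3, 1] <- 3.2                 # beyond the 3-A cutoff
  bent <- lin; bent[3, ] <- c(0.95, 1.9, 0)    # angle ~90, distance ok
  tr_all <- traj_from_frames(s, list(lin, lin, lin))
  expect_equal(hbond_occupancy(tr_all, 1, 3)$occupancy, 1.0)
  tr_far <- traj_from_frames(s, list(far, far))
  expect_equal(hbond_occupancy(tr_far, 1, 3)$occupancy, 0.0)
  tr_half <- traj_from_frames(s, list(lin, far, lin, far))
  expect_equal(hbond_occupancy(tr_half, 1, 3)$occupancy, 0.5)
  # geometry passing the distance but failing the angle criterion
  tr_bent <- traj_from_frames(s, list(bent, bent))
  expect_equal(hbond_occupancy(tr_bent, 1, 3)$occupancy, 0.0)
  # without hydrogens in the topology the distance criterion alone applies
  df_noh <- df[-2, ]
  s2 <- pathflow:::make_point_structure(df_noh)
  tr2 <- traj_from_frames(s2, list(lin[-2, ], far[-2, ]))
  expect_equal(hbond_occupancy(tr2, 1, 2)$occupancy, 0.5)
  expect_error(hbond_occupancy(tr2, integer(0), 2),
               class = "pathflow_usage_error")
})

test_that("ligand stability separates translation from in-place rotation", {
  ser <- generate_state_series(n_frames = 3, jitter_sd = 0, seed = 1,
                               replicates = 1)
  st <- ser$states$A_only
  tr <- st$trajs[[1]]
  lig <- st$node_map$members[["L:CLR201"]]
  # rigid whole-system motion only: removed by superposition
  moved <- tr
  th <- 0.8
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  for (k in 2:3) moved$coords[k, , ] <-
    matrix(moved$coords[k, , ], ncol = 3) %*% Rz +
    matrix(c(3, -2, 7), dim(tr$coords)[2], 3, byrow = TRUE)
  ld0 <- ligand_displacement(moved, st$node_map, "L:CLR201")
  expect_equal(max(ld0$com_displacement), 0, tolerance = 1e-9)
  expect_equal(max(ld0$rmsd), 0, tolerance = 1e-9)
  # ligand translated +5 A after protein alignment
  shifted <- tr
  shifted$coords[2, lig, 1] <- shifted$coords[2, lig, 1] + 5
  ld1 <- ligand_displacement(shifted, st$node_map, "L:CLR201")
  expect_equal(ld1$com_displacement[2], 5, tolerance = 1e-9)
  # in-place rotation about the ligand COM: zero COM motion, nonzero RMSD
  # matching the analytic value from the rotated coordinates
  rot <- tr
  fr <- matrix(rot$coords[2, , ], ncol = 3)
  masses <- pathflow:::atom_masses(st$structure$atoms$element[lig])
  com <- colSums(fr[lig, , drop = FALSE] * masses) / sum(masses)
  th2 <- 0.5
  Rz2 <- matrix(c(cos(th2), -sin(th2), 0, sin(th2), cos(th2), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  lig_rot <- sweep(sweep(fr[lig, , drop = FALSE], 2, com) %*% Rz2, 2, com,
                   "+")
  rot$coords[2, lig, ] <- lig_rot
  ld2 <- ligand_displacement(rot, st$node_map, "L:CLR201")
  expect_equal(ld2$com_displacement[2], 0, tolerance = 1e-9)
  analytic <- sqrt(mean(rowSums((lig_rot - fr[lig, , drop = FALSE])^2)))
  expect_equal(ld2$rmsd[2], analytic, tolerance = 1e-9)
  expect_gt(ld2$rmsd[2], 0.1)
})
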