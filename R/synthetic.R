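# Synthetic trajectory and graph generators with known ground truth.
#
# Synthetic "residues" are single-heavy-atom (Calpha-only) nodes; interactors
# are 3-atom rigid beads, so the minimum-distance node convention is
# exercised against multi-atom nodes.  Contact persistence is realized by
# jittering coordinates across frames around base geometries with
# inter-node distances far below (persistent) or far above (absent) the
# contact cutoff.  Every generator is a pure function of its spec and seed.

make_point_structure <- function(df, source = "<synthetic>") {
  atoms <- data.frame(
    atom_index = seq_len(nrow(df)),
    atom_name = df$atom_name,
    element = df$element,
    residue_number = df$resnum,
    residue_name = df$resname,
    chain_id = df$chain,
    is_heavy = df$element != "H",
    x = df$x, y = df$y, z = df$z,
    bfactor = 0,
    altloc = " ",
    record = ifelse(df$resname %in% .standard_aa, "ATOM", "HETATM"),
    stringsAsFactors = FALSE
  )
  new_structure_model(atoms, source = source)
}

ca_residue_df <- function(coords, resnum, chain = "A", resname = "ALA") {
  data.frame(atom_name = "CA", element = "C", resnum = resnum,
             resname = resname, chain = chain,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

#' Idealized cholesterol heavy-atom template
#'
#' 28 heavy atoms (27 carbons, 1 hydroxyl oxygen) of an energy-minimized
#' cholesterol conformer, centered at its centroid.  Used to build synthetic
#' ligand molecules.
#'
#' @return Data frame (atom_name, element, x, y, z), coordinates in Angstrom.
#' @export
clr_template <- function() {
  txt <- "C1 C 2.726 -0.211 2.140
C2 C 2.753 -0.945 0.795
C3 C 4.155 -0.798 0.145
C4 C 4.534 0.629 -0.273
C5 C 5.968 0.726 -0.813
C6 C 7.004 1.240 0.206
C7 C 8.366 1.395 -0.476
C8 C 7.142 0.340 1.432
C9 C 1.597 -0.516 -0.149
C10 C 1.638 -1.277 -1.506
C11 C 0.192 -1.393 -2.004
C12 C -0.598 -0.518 -1.043
C13 C -2.117 -0.713 -0.972
C14 C -2.764 -0.564 -2.359
C15 C -4.203 -0.147 -2.342
C16 C -4.900 0.185 -1.238
C17 C -6.275 0.804 -1.397
C18 C -7.159 0.806 -0.146
O1 O -7.766 -0.473 0.051
C19 C -6.426 1.215 1.134
C20 C -4.897 1.262 1.009
C21 C -4.287 0.115 0.164
C22 C -4.631 -1.248 0.813
C23 C -2.723 0.301 0.044
C24 C -1.969 0.285 1.398
C25 C -0.438 0.368 1.260
C26 C 0.120 -0.712 0.316
C27 C -0.085 -2.116 0.935"
  df <- utils::read.table(text = txt, col.names = c("atom_name", "element",
                                                    "x", "y", "z"),
                          stringsAsFactors = FALSE)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

# Calpha-like helix: radius 2.3 A, 100 deg turn, 1.5 A rise per residue
helix_coords <- function(n, radius = 2.3, turn_deg = 100, rise = 1.5) {
  th <- (seq_len(n) - 1) * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

# Kirchhoff (connectivity) matrix of an elastic network
kirchhoff_matrix <- function(reference_coords, enm_cutoff = 10) {
  d <- as.matrix(stats::dist(reference_coords))
  A <- (d > 0 & d <= enm_cutoff) * 1
  diag(A) <- 0
  G <- diag(rowSums(A)) - A
  G
}

#' Sample an elastic-network (Gaussian network model) trajectory
#'
#' Frames are the reference structure plus isotropic Gaussian displacements
#' whose per-coordinate covariance is `kT_gamma * pinv(Gamma)`, where `Gamma`
#' is the Kirchhoff matrix of the contact network at `enm_cutoff`.  The
#' theoretical per-node RMSF is `sqrt(3 * kT_gamma * diag(pinv(Gamma)))`.
#'
#' @param reference_coords `n x 3` reference coordinates (Angstrom); defaults
#'   to a 20-residue Calpha helix.
#' @param enm_cutoff Contact cutoff of the elastic network, Angstrom.
#' @param kT_gamma Spring-scale `kT/gamma` in Angstrom^2 (sets fluctuation
#'   amplitude).
#' @param n_frames Number of frames to sample (`>= 2`).
#' @param seed Integer seed; the sampler is bit-reproducible.
#' @return List: `traj` (`trajectory_ensemble`), `structure`, `node_map`,
#'   `theoretical_rmsf` (named by node label), `kirchhoff`.
#' @export
sample_enm_trajectory <- function(reference_coords = helix_coords(20),
                                  enm_cutoff = 10, kT_gamma = 1.0,
                                  n_frames = 100, seed = 1) {
  reference_coords <- as.matrix(reference_coords)
  n <- nrow(reference_coords)
  if (n_frames < 2L) pf_error("spec_error", "n_frames must be >= 2")
  if (enm_cutoff <= 0) pf_error("spec_error", "enm_cutoff must be > 0")
  G <- kirchhoff_matrix(reference_coords, enm_cutoff)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-9 * max(e$values)
  n_zero <- sum(abs(e$values) < tol)
  if (n_zero != 1L)
    pf_error("spec_error",
             "elastic network is disconnected (Kirchhoff matrix has more than one zero eigenvalue)")
  modes <- seq_len(n - 1)
  V <- e$vectors[, modes, drop = FALSE]
  lam <- e$values[modes]
  B <- V %*% diag(sqrt(kT_gamma / lam), n - 1)
  gplus_diag <- rowSums(sweep(V^2, 2, lam, "/"))
  structure_df <- ca_residue_df(reference_coords, seq_len(n))
  struct <- make_point_structure(structure_df, "<synthetic ENM>")
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    Z <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
    frames[[k]] <- reference_coords + B %*% Z
  }
  traj <- new_trajectory_ensemble(struct, frames)
  nmap <- build_node_map(struct)
  th <- sqrt(3 * kT_gamma * gplus_diag)
  names(th) <- nmap$nodes$label
  list(traj = traj, structure = struct, node_map = nmap,
       theoretical_rmsf = th, kirchhoff = G)
}

# ring of k points of given radius around a center, in the y-z plane
cluster_ring <- function(center, k, radius = 1.2) {
  th <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
  cbind(center[1] + 0 * th, center[2] + radius * cos(th),
        center[3] + radius * sin(th))
}

#' Generate a single-bottleneck contact system with known flow ground truth
#'
#' Source and sink patches are connected only through a serial bridge chain;
#' background nodes dangle off the bridge and carry no current.  By
#' construction every bridge node's throughflow equals 1 (all injected
#' current passes through it).
#'
#' @param n_source,n_sink,n_bridge Patch and bridge sizes (`>= 1`).
#' @param background_nodes Number of dangling off-path nodes.
#' @param n_frames Frames to emit.
#' @param jitter_sd Per-coordinate Gaussian jitter SD across frames
#'   (Angstrom).
#' @param seed Integer seed.
#' @return List: `traj`, `structure`, `node_map`, `ground_truth` (bridge,
#'   source, sink and background labels; `expected_bridge_flow = 1`).
#' @export
generate_bottleneck_system <- function(n_source = 3, n_sink = 3,
                                       n_bridge = 3, background_nodes = 4,
                                       n_frames = 20, jitter_sd = 0.2,
                                       seed = 1) {
  if (n_bridge < 1L) pf_error("spec_error", "bridge must be nonempty")
  u <- 6.0  # contact spacing, Angstrom
  src <- cluster_ring(c(0, 0, 0), n_source)
  bridge <- cbind(u * seq_len(n_bridge), 0, 0)
  snk <- cluster_ring(c(u * (n_bridge + 1), 0, 0), n_sink)
  bg <- NULL
  bg_attach <- integer(0)
  if (background_nodes > 0) {
    # each background node dangles off one bridge node; directions cycle
    # fastest so same-direction nodes land on bridge nodes >= 2 apart
    dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    bg <- t(vapply(seq_len(background_nodes), function(m) {
      k <- ((m - 1L) %/% 4L * 2L) %% n_bridge + 1L
      bg_attach[m] <<- k
      dir <- dirs[(m - 1L) %% 4L + 1L, ]
      bridge[k, ] + 8.5 * dir
    }, numeric(3)))
  }
  base <- rbind(src, bridge, snk, bg)
  n <- nrow(base)
  n_bg <- if (is.null(bg)) 0L else nrow(bg)
  roles <- c(rep("source", n_source), rep("bridge", n_bridge),
             rep("sink", n_sink), rep("background", n_bg))
  # internal consistency: no direct source-sink or patch-to-far-bridge
  # contact may exist in the base geometry
  dmat <- as.matrix(stats::dist(base))
  far_ok <- function(i, j) all(dmat[i, j] > 9.8)
  src_i <- which(roles == "source"); snk_i <- which(roles == "sink")
  brd_i <- which(roles == "bridge")
  if (!far_ok(src_i, snk_i) ||
      (n_bridge > 1 && !far_ok(src_i, brd_i[-1])) ||
      (n_bridge > 1 && !far_ok(snk_i, brd_i[-n_bridge])))
    pf_error("spec_error",
             "bottleneck spec creates a bypass around the bridge")
  # strict-series invariant: in the base-geometry contact graph, removing
  # any single bridge node must disconnect every source from every sink.
  # Edges below 1e-3 (three orders under the path weights) are negligible
  # by construction and ignored here.
  w0 <- smoothed_contact_weight(dmat, contact_params())
  diag(w0) <- 0
  w0[w0 < 1e-3] <- 0
  for (bk in brd_i) {
    keep <- setdiff(seq_len(n), bk)
    comp <- graph_components(w0[keep, keep, drop = FALSE])
    if (any(comp[match(src_i, keep)] %in% comp[match(snk_i, keep)]))
      pf_error("spec_error",
               "bottleneck spec creates a bypass around the bridge")
  }
  struct <- make_point_structure(ca_residue_df(base, seq_len(n)),
                                 "<synthetic bottleneck>")
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k)
    base + matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3))
  traj <- new_trajectory_ensemble(struct, frames)
  nmap <- build_node_map(struct)
  labs <- nmap$nodes$label
  list(traj = traj, structure = struct, node_map = nmap,
       ground_truth = list(
         source_labels = labs[src_i], sink_labels = labs[snk_i],
         bridge_labels = labs[brd_i],
         background_labels = labs[roles == "background"],
         expected_bridge_flow = 1))
}

#' Generate a two-route contact system with a tunable flow split
#'
#' Two disjoint source-to-sink routes (each a single midnode) whose contact
#' weights are `g` and `r * g`; by the current-divider rule the midnode
#' throughflows are `1/(1+r)` and `r/(1+r)`.
#'
#' @param r Conductance ratio of route 2 to route 1 (`> 0`).
#' @param w_max Contact weight of the stronger route; limited by the clean
#'   two-route geometry (see the methods vignette).
#' @param n_frames Frames to emit (identical unless `jitter_sd > 0`).
#' @param jitter_sd Per-coordinate jitter SD (Angstrom); default 0 so the
#'   emitted weights are exact.
#' @param seed Integer seed (used only when jittering).
#' @param params Contact parameters used to invert weights into distances.
#' @return List: `traj`, `structure`, `node_map`, `ground_truth` with the
#'   expected split.
#' @export
generate_two_path_system <- function(r, w_max = 0.025, n_frames = 5,
                                     jitter_sd = 0, seed = 1,
                                     params = contact_params()) {
  if (!is.numeric(r) || r <= 0)
    pf_error("spec_error", "ratio r must be > 0")
  g1 <- w_max / max(1, r)      # route 1 weight
  g2 <- r * g1                 # route 2 weight
  if (min(g1, g2) < 10 * params$prune_below)
    pf_error("spec_error",
             sprintf("ratio r = %g pushes the weak route below the pruning threshold", r))
  L <- 10.4
  d_for_w <- function(w) params$c + params$sigma * stats::qnorm(1 - w)
  d1 <- d_for_w(g1); d2 <- d_for_w(g2)
  if (min(d1, d2) <= L / 2)
    pf_error("spec_error", "w_max too large for a clean two-route geometry")
  h1 <- sqrt(d1^2 - (L / 2)^2); h2 <- sqrt(d2^2 - (L / 2)^2)
  base <- rbind(c(0, 0, 0),           # S
                c(L / 2, h1, 0),      # M1 (route 1)
                c(L / 2, -h2, 0),     # M2 (route 2)
                c(L, 0, 0))           # T
  struct <- make_point_structure(ca_residue_df(base, 1:4),
                                 "<synthetic two-path>")
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    if (jitter_sd > 0) base + matrix(stats::rnorm(12, sd = jitter_sd), 4, 3)
    else base
  })
  traj <- new_trajectory_ensemble(struct, frames)
  nmap <- build_node_map(struct)
  labs <- nmap$nodes$label
  list(traj = traj, structure = struct, node_map = nmap,
       ground_truth = list(
         ratio = r, source_label = labs[1], sink_label = labs[4],
         midnode_labels = c(route1 = labs[2], route2 = labs[3]),
         expected_split = c(route1 = 1 / (1 + r), route2 = r / (1 + r))))
}

# place a linear 3-atom bead (rigid interactor) along x at height y
bead_df <- function(xs, y, resnum, chain = "L", resname = "CLR") {
  data.frame(atom_name = c("C1", "C2", "O1"), element = c("C", "C", "O"),
             resnum = resnum, resname = resname, chain = chain,
             x = xs, y = y, z = 0, stringsAsFactors = FALSE)
}

#' Generate the four-condition ligand-occupancy series
#'
#' Emulates an apo / site-A-only / site-B-only / both design.  Site A is a
#' 3-atom interactor bead lying directly on the source-to-sink path (a strong
#' parallel shortcut across the central residues); site B bridges a side
#' region onto the path, adding a weaker parallel route.  By construction:
#' flow through A exceeds flow through B when both are present, and flow
#' through A decreases from the A-only state to the both state (B adds a
#' parallel route).
#'
#' @param n_frames Frames per replicate.
#' @param jitter_sd Per-coordinate jitter SD (Angstrom); interactor beads are
#'   jittered rigidly.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param replicates Replicate trajectories per condition.
#' @return List with `states` (named list `none`, `A_only`, `B_only`, `both`;
#'   each has `structure`, `node_map`, `trajs`) and `ground_truth`.
#' @export
generate_state_series <- function(n_frames = 20, jitter_sd = 0.2, seed = 1,
                                  replicates = 3) {
  # protein: S - R1 - R2 - R3 - T along x, spacing 6 A; side nodes X1, X2
  prot <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0), c(18, 0, 0),
                c(24, 0, 0), c(6, 6, 0), c(18, 6, 0))
  prot_df <- ca_residue_df(prot, 1:7)
  A_df <- bead_df(c(6, 12, 18), -6, resnum = 201)    # on-path shortcut
  B_df <- bead_df(c(7, 12, 17), 11, resnum = 202)    # side-region bridge
  states <- list(none = NULL, A_only = list(A_df), B_only = list(B_df),
                 both = list(A_df, B_df))
  out <- list()
  for (st in names(states)) {
    df <- do.call(rbind, c(list(prot_df), states[[st]]))
    struct <- make_point_structure(df, sprintf("<synthetic state %s>", st))
    nmap <- build_node_map(struct,
                           interactor_selectors = list(list(residue_name = "CLR")))
    base <- as.matrix(df[, c("x", "y", "z")])
    is_bead <- df$resname == "CLR"
    bead_ids <- unique(df$resnum[is_bead])
    trajs <- lapply(seq_len(replicates), function(i) {
      set.seed(seed + i)
      frames <- lapply(seq_len(n_frames), function(k) {
        jit <- matrix(stats::rnorm(3 * nrow(base), sd = jitter_sd),
                      nrow(base), 3)
        # rigid beads: one displacement per interactor molecule
        for (bid in bead_ids) {
          rows <- which(df$resnum == bid & is_bead)
          jit[rows, ] <- matrix(jit[rows[1], ], length(rows), 3,
                                byrow = TRUE)
        }
        base + jit
      })
      new_trajectory_ensemble(struct, frames, replicate_id = i)
    })
    out[[st]] <- list(structure = struct, node_map = nmap, trajs = trajs)
  }
  src <- out$none$node_map$nodes$label[1]
  snk <- out$none$node_map$nodes$label[5]
  list(states = out,
       ground_truth = list(
         source_label = src, sink_label = snk,
         site_A = "L:CLR201", site_B = "L:CLR202",
         orderings = c("flow(A|both) > flow(B|both)",
                       "flow(A|both) < flow(A|A_only)")))
}

#' Construct small named resistor-network fixtures
#'
#' @param kind `"series"` (chain of unit edges), `"parallel"` (two
#'   two-edge branches with branch conductances `conductances`),
#'   `"wheatstone"` (four arms plus a bridge edge), or `"random"`
#'   (connected Erdos-Renyi graph with uniform weights, 5-12 nodes).
#' @param n Number of nodes (series/random; random draws 5-12 when `NULL`).
#' @param conductances Branch conductances for `"parallel"`.
#' @param arm,bridge Arm and bridge conductances for `"wheatstone"`.
#' @param seed Seed for `"random"`.
#' @return A `contact_graph`.
#' @export
make_toy_graph <- function(kind = c("series", "parallel", "wheatstone",
                                    "random"),
                           n = 3, conductances = c(1, 3), arm = 1,
                           bridge = 1, seed = 1) {
  if (length(kind) == 1L && !kind %in% c("series", "parallel", "wheatstone",
                                         "random"))
    pf_error("usage_error", sprintf("unknown toy-graph kind '%s'", kind))
  kind <- match.arg(kind)
  # toy fixtures may carry conductances above 1 (resistor semantics), unlike
  # trajectory-derived contact weights
  toy <- function(w, labels)
    new_contact_graph(w, labels, rep("residue", length(labels)), 1L,
                      contact_params(), validate_range = FALSE)
  if (kind == "series") {
    labs <- sprintf("N%02d", seq_len(n))
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
    return(toy(w, labs))
  }
  if (kind == "parallel") {
    labs <- c("S", "M1", "M2", "T")
    w <- matrix(0, 4, 4, dimnames = list(labs, labs))
    g <- conductances
    w["S", "M1"] <- w["M1", "S"] <- g[1]; w["M1", "T"] <- w["T", "M1"] <- g[1]
    w["S", "M2"] <- w["M2", "S"] <- g[2]; w["M2", "T"] <- w["T", "M2"] <- g[2]
    return(toy(w, labs))
  }
  if (kind == "wheatstone") {
    labs <- c("S", "A", "B", "T")
    w <- matrix(0, 4, 4, dimnames = list(labs, labs))
    w["S", "A"] <- w["A", "S"] <- arm; w["S", "B"] <- w["B", "S"] <- arm
    w["A", "T"] <- w["T", "A"] <- arm; w["B", "T"] <- w["T", "B"] <- arm
    w["A", "B"] <- w["B", "A"] <- bridge
    return(toy(w, labs))
  }
  # random: connected Erdos-Renyi with uniform weights
  set.seed(seed)
  if (is.null(n) || n < 5) n <- sample(5:12, 1)
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- ut[stats::runif(length(ut)) < 0.4]
    w[on] <- stats::runif(length(on), 0.2, 1)
    w <- w + t(w)
    comp <- graph_components(w)
    if (length(unique(comp)) == 1L && length(on) > 0) break
  }
  toy(w, sprintf("N%02d", seq_len(n)))
}

#' Centroid separation between two bound sterol molecules
#'
#' Unweighted heavy-atom centroid distance between two interactor nodes,
#' e.g. the CRD-site and TMD-site cholesterol molecules of a receptor
#' structure.
#'
#' @param structure A `structure_model` containing exactly two molecules
#'   matched by `selector` (or give `labels`).
#' @param selector Interactor selector, default cholesterol (`CLR`).
#' @param labels Optional pair of interactor node labels.
#' @return Distance in Angstrom.
#' @export
sterol_site_separation <- function(structure,
                                   selector = list(residue_name = "CLR"),
                                   labels = NULL) {
  nmap <- build_node_map(structure, interactor_selectors = list(selector))
  inter <- nmap$nodes$label[nmap$nodes$kind == "interactor"]
  if (is.null(labels)) {
    if (length(inter) != 2L)
      pf_error("usage_error",
               sprintf("expected exactly 2 interactor molecules, found %d",
                       length(inter)))
    labels <- inter
  }
  cm <- coords_matrix(structure)
  cent <- function(lab) colMeans(cm[nmap$members[[lab]], , drop = FALSE])
  sqrt(sum((cent(labels[1]) - cent(labels[2]))^2))
}

#' Synthetic two-sterol receptor stand-in
#'
#' Builds a SYNTHETIC, coarse stand-in for a class F receptor with two bound
#' cholesterol molecules: a Calpha helix spanning the membrane region plus
#' two full 28-heavy-atom cholesterol templates whose centroids are placed
#' `separation` Angstrom apart, the extracellular (CRD-like) site above the
#' membrane-embedded (TMD-like) site.  This is a constructed geometry for
#' exercising the structure pipeline, not a deposited structure.
#'
#' @param separation Centroid separation of the two sterols, Angstrom.
#' @param path Optional output PDB path.
#' @return A `structure_model` (written to `path` when given).
#' @export
synthetic_two_sterol_receptor <- function(separation = 45, path = NULL) {
  hel <- helix_coords(40)
  hel <- sweep(hel, 2, c(8, 0, 0), "+")   # offset helix from the sterol axis
  prot <- ca_residue_df(hel, seq_len(nrow(hel)))
  tmpl <- clr_template()
  mk_clr <- function(center, resnum) {
    data.frame(atom_name = tmpl$atom_name, element = tmpl$element,
               resnum = resnum, resname = "CLR", chain = "L",
               x = tmpl$x + center[1], y = tmpl$y + center[2],
               z = tmpl$z + center[3], stringsAsFactors = FALSE)
  }
  clr_tmd <- mk_clr(c(0, 0, 10), 1202)              # in the helical bundle
  clr_crd <- mk_clr(c(0, 0, 10 + separation), 1201) # extracellular site
  struct <- make_point_structure(rbind(prot, clr_crd, clr_tmd),
                                 "<synthetic two-sterol receptor>")
  if (!is.null(path)) {
    nmap <- build_node_map(struct,
                           interactor_selectors = list(list(residue_name = "CLR")))
    vals <- stats::setNames(rep(0, nrow(nmap$nodes)), nmap$nodes$label)
    writeLines(c("REMARK   SYNTHETIC stand-in structure generated by pathflow",
                 "REMARK   two cholesterol molecules at a fixed centroid separation",
                 write_bfactor_pdb(struct, nmap, vals)), path)
  }
  struct
}

#' Write a ground-truth sidecar as YAML
#'
#' @param ground_truth List returned by a generator.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  yaml::write_yaml(ground_truth, path)
  invisible(path)
}
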