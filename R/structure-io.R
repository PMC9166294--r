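# Structure and trajectory input.  Coordinates are Angstrom everywhere.
#
# The PDB reader is a strict fixed-column ATOM/HETATM parser: the package
# needs line-accurate format errors and an element-inference fallback for
# legacy files, which generic readers do not expose.

# Two-letter elements that occur in biomolecular files; used to disambiguate
# atom names such as "FE" or "CL" from carbon-with-suffix names ("CA", "CB").
.two_letter_elements <- c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "SE",
                          "BR", "CL", "NA", "CA", "K")

# Monoatomic ion residue names never eligible to become nodes.
.ion_resnames <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU",
                   "NI", "CO", "BR", "IOD", "CS", "LI", "SO4", "PO4")

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL",
                  # common protonation/termination variants
                  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "CYM",
                  "ASH", "GLH", "LYN", "MSE")

.aa_three_to_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                      GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                      LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                      SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

infer_element <- function(atom_name, record = "ATOM", resname = "") {
  nm <- toupper(trimws(atom_name))
  # ions / metals: atom name equals residue name in HETATM records
  if (record == "HETATM" && nm == toupper(trimws(resname)) &&
      nm %in% .two_letter_elements)
    return(paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))))
  # first alphabetic character, skipping leading digits (e.g. "1HB" -> H)
  chars <- strsplit(nm, "")[[1]]
  alpha <- chars[grepl("[A-Z]", chars)]
  if (length(alpha) == 0L) return("X")
  alpha[1]
}

parse_pdb_atom_lines <- function(lines, line_numbers, path = "<text>") {
  n <- length(lines)
  if (n == 0L)
    pf_error("empty_input_error", sprintf("no ATOM/HETATM records in %s", path))
  field <- function(from, to) substr(lines, from, to)
  num_field <- function(from, to, what) {
    raw <- field(from, to)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !nzchar(trimws(raw)))
    if (length(bad) > 0L)
      pf_error("format_error",
               sprintf("unparseable %s field at line %d of %s: '%s'",
                       what, line_numbers[bad[1]], path, raw[bad[1]]))
    val
  }
  record    <- trimws(field(1, 6))
  atom_name <- trimws(field(13, 16))
  altloc    <- field(17, 17)
  resname   <- trimws(field(18, 20))
  chain     <- field(22, 22)
  resnum    <- suppressWarnings(as.integer(trimws(field(23, 26))))
  if (anyNA(resnum))
    pf_error("format_error",
             sprintf("unparseable residue number at line %d of %s",
                     line_numbers[which(is.na(resnum))[1]], path))
  x <- num_field(31, 38, "x-coordinate")
  y <- num_field(39, 46, "y-coordinate")
  z <- num_field(47, 54, "z-coordinate")
  bfac <- suppressWarnings(as.numeric(field(61, 66)))
  bfac[is.na(bfac)] <- 0
  elem_col <- toupper(trimws(field(77, 78)))
  element <- ifelse(nzchar(elem_col),
                    paste0(substr(elem_col, 1, 1),
                           tolower(substr(elem_col, 2, 2))),
                    NA_character_)
  miss <- which(is.na(element))
  if (length(miss) > 0L)
    element[miss] <- mapply(infer_element, atom_name[miss], record[miss],
                            resname[miss], USE.NAMES = FALSE)
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  atoms <- data.frame(
    atom_index = seq_len(n),
    atom_name = atom_name,
    element = element,
    residue_number = resnum,
    residue_name = resname,
    chain_id = chain,
    is_heavy = element != "H",
    x = x, y = y, z = z,
    bfactor = bfac,
    altloc = altloc,
    record = record,
    stringsAsFactors = FALSE
  )
  atoms
}

new_structure_model <- function(atoms, source = "<memory>") {
  if (nrow(atoms) == 0L)
    pf_error("empty_input_error", sprintf("structure %s has zero atoms", source))
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name,
               sep = "\r")
  residues <- atoms[!duplicated(key),
                    c("chain_id", "residue_number", "residue_name")]
  rownames(residues) <- NULL
  residues$residue_key <- unique(key)
  structure(
    list(atoms = atoms, residues = residues, residue_key = key,
         source = source),
    class = "structure_model"
  )
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records.  For multi-model files only the
#' first model is returned as the topology; pass the same file to
#' [read_trajectory()] to use all models as frames.  Elements are taken from
#' the element column when present, otherwise inferred from the atom name
#' (first alphabetic character, with a two-letter disambiguation table for
#' metals/halides).
#'
#' @param path Path to a PDB file.
#' @param dialect Only `"pdb"` is supported.
#' @return A `structure_model`: a list with an `atoms` data frame
#'   (atom_index, atom_name, element, residue_number, residue_name, chain_id,
#'   is_heavy, x, y, z) and a derived `residues` table.
#' @export
read_structure <- function(path, dialect = "pdb") {
  if (!identical(dialect, "pdb"))
    pf_error("config_error", sprintf("unsupported structure dialect '%s'",
                                     dialect))
  if (!file.exists(path))
    pf_error("input_error", sprintf("structure file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) {
    keep <- is_atom & (seq_along(lines) < endmdl[1])
  } else {
    keep <- is_atom
  }
  atoms <- parse_pdb_atom_lines(lines[keep], which(keep), path)
  model <- new_structure_model(atoms, source = path)
  validate_structure_model(model)
  model
}

validate_structure_model <- function(model) {
  at <- model$atoms
  if (!all(is.finite(c(at$x, at$y, at$z))))
    pf_error("format_error", "non-finite coordinates in structure")
  if (any(at$is_heavy == (at$element == "H")))
    pf_error("integrity_error", "is_heavy inconsistent with element")
  key <- paste(at$chain_id, at$residue_number, at$atom_name, at$altloc,
               sep = "\r")
  if (anyDuplicated(key))
    pf_error("integrity_error",
             "duplicate (chain, residue number, atom name) within model")
  invisible(model)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues (%d heavy atoms)\n",
              nrow(x$atoms), nrow(x$residues), sum(x$atoms$is_heavy)))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

coords_matrix <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# Split a (possibly multi-model) PDB file into a list of coordinate matrices.
read_pdb_frames <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  n_top <- nrow(topology$atoms)
  frames <- list()
  if (length(model_starts) == 0L) {
    atoms <- parse_pdb_atom_lines(lines[grepl("^(ATOM  |HETATM)", lines)],
                                  grep("^(ATOM  |HETATM)", lines), path)
    frames[[1]] <- as.matrix(atoms[, c("x", "y", "z")])
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    for (k in seq_along(model_starts)) {
      rng <- seq(model_starts[k], model_ends[k])
      sel <- rng[grepl("^(ATOM  |HETATM)", lines[rng])]
      atoms <- parse_pdb_atom_lines(lines[sel], sel, path)
      frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
    }
  }
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != n_top)
      pf_error("topology_mismatch_error",
               sprintf("frame %d of %s has %d atoms; topology has %d",
                       k, path, nrow(frames[[k]]), n_top))
  }
  frames
}

#' Read a trajectory against a topology
#'
#' Accepts multi-model PDB files or DCD files (read via \pkg{bio3d}).  Frames
#' are concatenated in the order the paths are given, then strided.
#'
#' @param topology A `structure_model`.
#' @param paths Character vector of trajectory file paths.
#' @param stride Keep every `stride`-th frame (>= 1) after concatenation.
#' @param replicate_id Integer replicate label carried through to outputs.
#' @param frame_times Optional numeric vector of frame times (ns), strictly
#'   increasing, one per retained frame.
#' @return A `trajectory_ensemble`: coordinates as an
#'   `n_frames x n_atoms x 3` array plus the topology reference.
#' @export
read_trajectory <- function(topology, paths, stride = 1L, replicate_id = 1L,
                            frame_times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(paths) == 0L)
    pf_error("empty_input_error", "no trajectory paths given")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    pf_error("usage_error", "stride must be an integer >= 1")
  frames <- list()
  for (p in paths) {
    if (!file.exists(p))
      pf_error("input_error", sprintf("trajectory file not found: %s", p))
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(p, verbose = FALSE)
      n_at <- ncol(xyz) / 3
      if (n_at != nrow(topology$atoms))
        pf_error("topology_mismatch_error",
                 sprintf("%s has %d atoms per frame; topology has %d",
                         p, n_at, nrow(topology$atoms)))
      for (k in seq_len(nrow(xyz)))
        frames[[length(frames) + 1L]] <-
          matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    } else {
      new_frames <- read_pdb_frames(p, topology)
      frames <- c(frames, new_frames)
    }
  }
  keep <- seq(1L, length(frames), by = stride)
  frames <- frames[keep]
  new_trajectory_ensemble(topology, frames, replicate_id, frame_times)
}

new_trajectory_ensemble <- function(topology, frames, replicate_id = 1L,
                                    frame_times = NULL) {
  n_frames <- length(frames)
  if (n_frames < 1L)
    pf_error("empty_input_error", "trajectory has zero frames")
  n_atoms <- nrow(topology$atoms)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (k in seq_len(n_frames)) coords[k, , ] <- frames[[k]]
  if (!is.null(frame_times)) {
    if (length(frame_times) != n_frames || any(diff(frame_times) <= 0))
      pf_error("usage_error",
               "frame_times must be strictly increasing, one per frame")
  }
  structure(
    list(n_frames = n_frames, coords = coords, frame_times = frame_times,
         replicate_id = as.integer(replicate_id), topology = topology),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms (replicate %d)\n",
              x$n_frames, dim(x$coords)[2], x$replicate_id))
  invisible(x)
}

frame_coords <- function(traj, k) {
  matrix(traj$coords[k, , ], ncol = 3)
}

# round half away from zero, fixed number of decimals
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pdb_atom_name <- function(name, element) {
  # names shorter than 4 characters start in column 14 unless the element
  # symbol is two letters
  if (nchar(name) >= 4L || nchar(element) == 2L) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
}

#' Write a structure as PDB text with per-node values in the B-factor column
#'
#' Every atom belonging to a node carries that node's value; atoms outside all
#' nodes get 0.00.  Values are rounded half-away-from-zero to two decimals to
#' fit the fixed-width field.
#'
#' @param structure A `structure_model`.
#' @param node_map A `node_map` over the structure.
#' @param per_node_values Named numeric vector, one value per node label.
#' @param scaling `"none"` or `"minmax"` (linear map onto \[0, 99.99\] with the
#'   maximum mapped to 99.99 exactly).
#' @param path Optional output file; when given, lines are also written there.
#' @return Character vector of PDB lines, invisibly when `path` is given.
#' @export
write_bfactor_pdb <- function(structure, node_map, per_node_values,
                              scaling = c("none", "minmax"), path = NULL) {
  scaling <- match.arg(scaling)
  if (!all(is.finite(per_node_values)))
    pf_error("usage_error", "per-node values must be finite")
  vals <- per_node_values
  if (scaling == "minmax") {
    rng <- range(vals)
    vals <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1]) * 99.99
            else rep(0, length(vals))
    names(vals) <- names(per_node_values)
  }
  at <- structure$atoms
  b <- rep(0, nrow(at))
  for (lab in names(vals)) {
    idx <- node_map$members[[lab]]
    if (is.null(idx))
      pf_error("lookup_error", sprintf("unknown node label '%s'", lab))
    b[idx] <- vals[[lab]]
  }
  b <- round_half_away(b, 2)
  if (any(b > 999.99 | b < -99.99))
    pf_error("range_error",
             "value does not fit the B-factor field; use scaling = 'minmax'")
  rec <- ifelse(at$record == "HETATM", "HETATM", "ATOM")
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, at$atom_index,
                   vapply(seq_len(nrow(at)), function(i)
                     format_pdb_atom_name(at$atom_name[i], at$element[i]),
                     character(1)),
                   " ", at$residue_name, at$chain_id, at$residue_number,
                   at$x, at$y, at$z, 1.00, b, toupper(at$element))
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `trajectory_ensemble`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$topology$atoms
  rec <- ifelse(at$record == "HETATM", "HETATM", "ATOM")
  names4 <- vapply(seq_len(nrow(at)), function(i)
    format_pdb_atom_name(at$atom_name[i], at$element[i]), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, k)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, at$atom_index, names4, " ", at$residue_name,
                       at$chain_id, at$residue_number,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00,
                       toupper(at$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a per-node value table as CSV
#'
#' Columns: node_label, kind, chain, resnum, value.
#'
#' @param node_map A `node_map`.
#' @param values Named numeric vector keyed by node label.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_node_table <- function(node_map, values, path) {
  nd <- node_map$nodes
  df <- data.frame(node_label = nd$label, kind = nd$kind, chain = nd$chain,
                   resnum = nd$resnum,
                   value = as.numeric(values[nd$label]),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
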