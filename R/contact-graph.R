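# Time-averaged, smoothed heavy-atom contact graphs.
#
# The contact weight between two nodes in one frame is a Gaussian-smoothed
# step of the minimum heavy-atom distance d between their member atoms:
#
#     s(d) = 0.5 * erfc((d - c) / (sigma * sqrt(2)))
#
# i.e. the upper tail of a normal with mean c and SD sigma, so s(c) = 0.5
# exactly.  Defaults c = 4.5 A and sigma = 1.38 A.  The edge weight is the
# per-frame smoothed contact averaged over frames, then pruned.

#' Contact-map parameters
#'
#' @param c Cutoff length in Angstrom (midpoint of the smoothed step);
#'   a string with an `"nm"` suffix is converted.
#' @param sigma Smoothing SD in Angstrom (or string with unit suffix).
#' @param prune_below Edge weights below this value are stored as exact 0.
#' @return A `contact_params` list.
#' @export
contact_params <- function(c = 4.5, sigma = 1.38, prune_below = 1e-4) {
  c <- parse_length(c, "cutoff c")
  sigma <- parse_length(sigma, "sigma")
  if (c <= 0 || sigma <= 0)
    pf_error("config_error", "contact parameters c and sigma must be > 0")
  if (prune_below < 0 || prune_below >= 1)
    pf_error("config_error", "prune_below must lie in [0, 1)")
  structure(list(c = c, sigma = sigma, prune_below = prune_below),
            class = "contact_params")
}

#' Smoothed contact weight of a distance
#'
#' `s(d) = 0.5 * erfc((d - c)/(sigma*sqrt(2)))`: continuous, nonincreasing,
#' exactly 0.5 at `d = c`, and point-symmetric about `(c, 0.5)`.
#'
#' @param d Distance(s), Angstrom, `>= 0`.
#' @param params A [contact_params()] object.
#' @return Weight(s) in \[0, 1\].
#' @export
smoothed_contact_weight <- function(d, params = contact_params()) {
  if (any(d < 0)) pf_error("usage_error", "distances must be nonnegative")
  stats::pnorm(d, mean = params$c, sd = params$sigma, lower.tail = FALSE)
}

#' Minimum heavy-atom distance between two nodes in one frame
#'
#' @param coords `n_atoms x 3` coordinate matrix for the frame (full topology
#'   indexing).
#' @param node_map A `node_map`.
#' @param label_i,label_j Distinct node labels.
#' @return Minimum Euclidean distance (Angstrom) over all member-atom pairs.
#' @export
node_pair_distance <- function(coords, node_map, label_i, label_j) {
  if (identical(label_i, label_j))
    pf_error("usage_error", "node_pair_distance requires two distinct nodes")
  ai <- node_map$members[[label_i]]; aj <- node_map$members[[label_j]]
  if (is.null(ai) || is.null(aj))
    pf_error("lookup_error", "unknown node label")
  A <- coords[ai, , drop = FALSE]; B <- coords[aj, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

# All-pairs minimum inter-node distances for one frame; returns a symmetric
# n_nodes x n_nodes matrix with 0 on the diagonal.
node_min_distances <- function(coords, node_map) {
  labs <- node_map$nodes$label
  n <- length(labs)
  idx <- node_map$members[labs]
  atom_ids <- unlist(idx, use.names = FALSE)
  node_of <- rep.int(seq_len(n), lengths(idx))
  A <- coords[atom_ids, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(A^2), "+") - 2 * tcrossprod(A)
  d2[d2 < 0] <- 0
  # reduce atom-pair squared distances to node-pair minima: first rows by
  # node, then columns by node
  m <- matrix(Inf, n, n)
  row_groups <- split(seq_along(node_of), node_of)
  colmin <- matrix(NA_real_, n, ncol(d2))
  for (g in seq_len(n))
    colmin[g, ] <- if (length(row_groups[[g]]) == 1L) d2[row_groups[[g]], ]
                   else do.call(pmin, as.data.frame(t(d2[row_groups[[g]], ,
                                                         drop = FALSE])))
  for (g in seq_len(n))
    m[, g] <- if (length(row_groups[[g]]) == 1L) colmin[, row_groups[[g]]]
              else do.call(pmin,
                           as.data.frame(colmin[, row_groups[[g]],
                                                drop = FALSE]))
  m <- sqrt(m)
  diag(m) <- 0
  dimnames(m) <- list(labs, labs)
  m
}

new_contact_graph <- function(weights, labels, kinds, n_frames_used, params,
                              validate_range = TRUE) {
  w <- as.matrix(weights)
  dimnames(w) <- list(labels, labels)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    pf_error("integrity_error", "contact weights must be symmetric")
  if (any(diag(w) != 0))
    pf_error("integrity_error", "contact weights must have zero diagonal")
  if (any(w < 0))
    pf_error("integrity_error", "contact weights must be nonnegative")
  if (validate_range && any(w > 1))
    pf_error("integrity_error", "contact weights must lie in [0, 1]")
  structure(
    list(labels = labels, kinds = kinds, weights = w,
         n_frames_used = n_frames_used, params = params),
    class = "contact_graph"
  )
}

#' Build a time-averaged smoothed contact graph from a trajectory
#'
#' For every node pair the minimum heavy-atom distance is computed in each
#' frame, smoothed with [smoothed_contact_weight()], averaged over frames and
#' pruned below `params$prune_below`.
#'
#' @param traj A `trajectory_ensemble`.
#' @param node_map A `node_map` over the trajectory's topology.
#' @param params A [contact_params()] object.
#' @return A `contact_graph` with a symmetric weight matrix in \[0, 1\].
#' @export
build_contact_graph <- function(traj, node_map, params = contact_params()) {
  stopifnot(inherits(traj, "trajectory_ensemble"),
            inherits(node_map, "node_map"))
  if (traj$n_frames < 1L)
    pf_error("empty_input_error", "trajectory has no frames")
  n <- nrow(node_map$nodes)
  acc <- matrix(0, n, n)
  for (k in seq_len(traj$n_frames)) {
    d <- node_min_distances(frame_coords(traj, k), node_map)
    s <- smoothed_contact_weight(d, params)
    diag(s) <- 0
    acc <- acc + s
  }
  w <- acc / traj$n_frames
  w[w < params$prune_below] <- 0
  diag(w) <- 0
  new_contact_graph(w, node_map$nodes$label, node_map$nodes$kind,
                    traj$n_frames, params)
}

#' @export
print.contact_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("contact_graph: %d nodes, %d edges (from %d frames; c = %.3g A, sigma = %.3g A)\n",
              length(x$labels), ne, x$n_frames_used, x$params$c,
              x$params$sigma))
  invisible(x)
}

#' @export
plot.contact_graph <- function(x, ...) {
  graphics::image(x$weights, main = "contact weights", axes = FALSE, ...)
  invisible(x)
}

#' Serialize a contact graph as a weighted edge-list CSV
#'
#' Full-precision weights so the graph is loadable back bit-exactly with
#' [read_contact_graph()].
#'
#' @param graph A `contact_graph`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_contact_graph <- function(graph, path) {
  w <- graph$weights
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(node_i = graph$labels[ut[, 1]],
                   node_j = graph$labels[ut[, 2]],
                   weight = sprintf("%.17g", w[ut]),
                   stringsAsFactors = FALSE)
  header <- c(sprintf("# nodes=%s", paste(graph$labels, collapse = ";")),
              sprintf("# kinds=%s", paste(graph$kinds, collapse = ";")),
              sprintf("# n_frames=%d c=%.17g sigma=%.17g prune=%.17g",
                      graph$n_frames_used, graph$params$c,
                      graph$params$sigma, graph$params$prune_below))
  writeLines(c(header, "node_i,node_j,weight",
               sprintf("%s,%s,%s", df$node_i, df$node_j, df$weight)), path)
  invisible(path)
}

#' Load a contact graph written by [write_contact_graph()]
#'
#' @param path CSV path.
#' @return A `contact_graph`.
#' @export
read_contact_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  labels <- strsplit(sub("# nodes=", "", hdr[1]), ";", fixed = TRUE)[[1]]
  kinds <- strsplit(sub("# kinds=", "", hdr[2]), ";", fixed = TRUE)[[1]]
  meta_val <- function(key)
    as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", hdr[3]))
  meta <- c(meta_val("n_frames"), meta_val("c"), meta_val("sigma"),
            meta_val("prune"))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c("character", "character", "numeric"))
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(df) > 0) {
    i <- match(df$node_i, labels); j <- match(df$node_j, labels)
    w[cbind(i, j)] <- df$weight
    w[cbind(j, i)] <- df$weight
  }
  new_contact_graph(w, labels, kinds, as.integer(meta[1]),
                    contact_params(meta[2], meta[3], meta[4]),
                    validate_range = FALSE)
}
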