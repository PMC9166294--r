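# Current-flow ("information flow") analysis of a contact graph.
#
# The contact graph is treated as a resistor network with conductance g_ij
# equal to the contact weight w_ij.  A unit current is injected, split
# equally over the source nodes (+1/|S| each), and extracted equally over the
# sink nodes (-1/|T| each).  Potentials solve the weighted graph Laplacian
# system L v = b with the gauge fixed by grounding the lexicographically
# first sink.  Edge currents are i_ij = w_ij (v_i - v_j); the throughflow of
# an interior node is half the sum of absolute currents on its incident
# edges (the current-flow betweenness convention), and of a source/sink node
# the magnitude of its net injection.

#' Define a source/sink flow problem on a contact graph
#'
#' @param graph A `contact_graph`.
#' @param sources,sinks Nonempty, disjoint character vectors of node labels.
#' @return A `flow_network`.
#' @export
flow_network <- function(graph, sources, sinks) {
  stopifnot(inherits(graph, "contact_graph"))
  if (length(sources) == 0L || length(sinks) == 0L)
    pf_error("usage_error", "sources and sinks must be nonempty")
  if (length(intersect(sources, sinks)) > 0L)
    pf_error("usage_error", "sources and sinks must be disjoint")
  missing <- setdiff(c(sources, sinks), graph$labels)
  if (length(missing) > 0L)
    pf_error("lookup_error",
             sprintf("labels not in graph: %s", paste(missing, collapse = ", ")))
  structure(list(graph = graph, sources = sources, sinks = sinks),
            class = "flow_network")
}

# Connected components of the pruned graph; integer membership vector.
graph_components <- function(weights) {
  g <- igraph::graph_from_adjacency_matrix(weights > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Solve node potentials of the resistor network
#'
#' @param network A [flow_network()].
#' @return Named numeric vector of potentials (arbitrary gauge: the
#'   lexicographically first sink is grounded at 0).  Nodes outside the
#'   source/sink component get `NA`.
#' @export
solve_potentials <- function(network) {
  g <- network$graph
  labs <- g$labels
  W <- g$weights
  comp <- graph_components(W)
  names(comp) <- labs
  st_comp <- unique(comp[c(network$sources, network$sinks)])
  if (length(st_comp) != 1L) {
    tab <- split(c(network$sources, network$sinks),
                 comp[c(network$sources, network$sinks)])
    pf_error("connectivity_error",
             paste0("sources and sinks span disconnected components: ",
                    paste(vapply(tab, paste, character(1), collapse = "+"),
                          collapse = " | ")))
  }
  in_comp <- comp == st_comp
  idx <- which(in_comp)
  labs_c <- labs[idx]
  Wc <- W[idx, idx, drop = FALSE]
  n <- length(idx)
  b <- numeric(n); names(b) <- labs_c
  b[network$sources] <- b[network$sources] + 1 / length(network$sources)
  b[network$sinks] <- b[network$sinks] - 1 / length(network$sinks)
  L <- Matrix::Matrix(diag(rowSums(Wc)) - Wc, sparse = TRUE)
  ground <- match(sort(network$sinks)[1], labs_c)
  keep <- setdiff(seq_len(n), ground)
  v <- numeric(n)
  sol <- tryCatch(
    Matrix::solve(L[keep, keep, drop = FALSE], b[keep]),
    error = function(e) pf_error("numerical_error",
                                 paste("singular reduced Laplacian:",
                                       conditionMessage(e))))
  v[keep] <- as.numeric(sol)
  resid <- max(abs(as.numeric(L %*% v) - b))
  if (!is.finite(resid) || resid > 1e-9)
    pf_error("numerical_error",
             sprintf("Laplacian solve residual %.3g exceeds 1e-9", resid))
  out <- rep(NA_real_, length(labs)); names(out) <- labs
  out[idx] <- v
  out
}

#' Compute current-flow betweenness ("information flow") source to sink
#'
#' Injects one unit of current split equally over the sources and extracts it
#' equally over the sinks, solves the network potentials, and reports per-node
#' throughflow, edge currents and the effective resistance between the source
#' and sink sets.
#'
#' @param graph A `contact_graph` (or a `flow_network`, in which case
#'   `sources`/`sinks` are ignored).
#' @param sources,sinks Node label sets; see [flow_network()].
#' @return A `flow_result` with components `potentials`, `currents`
#'   (antisymmetric matrix over the connected component), `throughflow`
#'   (named, `>= 0`; interior nodes of a connected network are `<= 1`),
#'   `effective_resistance`, `sources`, `sinks`, `kinds` and
#'   `total_injected = 1`.
#' @export
information_flow <- function(graph, sources = NULL, sinks = NULL) {
  network <- if (inherits(graph, "flow_network")) graph
             else flow_network(graph, sources, sinks)
  g <- network$graph
  v <- solve_potentials(network)
  labs <- g$labels
  in_comp <- !is.na(v)
  W <- g$weights
  curr <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  vi <- v; vi[!in_comp] <- 0
  curr <- W * (outer(vi, rep(1, length(vi))) - outer(rep(1, length(vi)), vi))
  curr[!in_comp, ] <- 0; curr[, !in_comp] <- 0
  net_out <- rowSums(curr)
  thru <- 0.5 * rowSums(abs(curr))
  is_src <- labs %in% network$sources
  is_snk <- labs %in% network$sinks
  thru[is_src | is_snk] <- abs(net_out[is_src | is_snk])
  thru[!in_comp] <- 0
  eff_res <- mean(v[network$sources]) - mean(v[network$sinks])
  structure(
    list(potentials = v, currents = curr, throughflow = thru,
         effective_resistance = eff_res, total_injected = 1,
         sources = network$sources, sinks = network$sinks,
         labels = labs, kinds = g$kinds),
    class = "flow_result"
  )
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %d nodes; %d source(s) -> %d sink(s)\n",
              length(x$labels), length(x$sources), length(x$sinks)))
  cat(sprintf("  effective resistance: %.6g (unit injected current)\n",
              x$effective_resistance))
  interior <- setdiff(x$labels, c(x$sources, x$sinks))
  if (length(interior) > 0) {
    top <- sort(x$throughflow[interior], decreasing = TRUE)
    top <- top[seq_len(min(5, length(top)))]
    cat("  top interior throughflow:\n")
    for (nm in names(top)) cat(sprintf("    %-14s %.4f\n", nm, top[nm]))
  }
  invisible(x)
}

#' @export
summary.flow_result <- function(object, ...) {
  df <- as.data.frame(object)
  df <- df[order(-df$throughflow), ]
  rownames(df) <- NULL
  structure(list(table = df,
                 effective_resistance = object$effective_resistance,
                 sources = object$sources, sinks = object$sinks),
            class = "summary.flow_result")
}

#' @export
print.summary.flow_result <- function(x, ...) {
  cat(sprintf("Current-flow analysis: %s -> %s\n",
              paste(x$sources, collapse = ","),
              paste(x$sinks, collapse = ",")))
  cat(sprintf("Effective resistance: %.6g\n", x$effective_resistance))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' @export
coef.flow_result <- function(object, ...) {
  object$throughflow
}

#' @export
as.data.frame.flow_result <- function(x, ...) {
  role <- rep("interior", length(x$labels))
  role[x$labels %in% x$sources] <- "source"
  role[x$labels %in% x$sinks] <- "sink"
  data.frame(node_label = x$labels, kind = x$kinds, role = role,
             potential = as.numeric(x$potentials),
             throughflow = as.numeric(x$throughflow),
             stringsAsFactors = FALSE)
}

#' @export
plot.flow_result <- function(x, n = 20, ...) {
  interior <- setdiff(x$labels, c(x$sources, x$sinks))
  top <- sort(x$throughflow[interior], decreasing = TRUE)
  top <- top[seq_len(min(n, length(top)))]
  graphics::barplot(rev(top), horiz = TRUE, las = 1,
                    xlab = "throughflow (unit injected current)", ...)
  invisible(x)
}

#' Flow through one interactor node
#'
#' @param result A `flow_result`.
#' @param interactor_label Label of an interactor node present in the graph.
#' @return The node's throughflow (numeric scalar).
#' @export
interactor_flow <- function(result, interactor_label) {
  stopifnot(inherits(result, "flow_result"))
  i <- match(interactor_label, result$labels)
  if (is.na(i))
    pf_error("lookup_error", sprintf("unknown node label '%s'",
                                     interactor_label))
  if (result$kinds[i] != "interactor")
    pf_error("usage_error",
             sprintf("node '%s' is not an interactor node", interactor_label))
  unname(result$throughflow[i])
}

#' Compare per-node flow across conditions with replicate mean and SEM
#'
#' @param results Named list: condition name -> list of `flow_result`
#'   (one per replicate).
#' @param reference Reference condition for the delta column; defaults to
#'   `"apo"` or `"none"` when present, else the first condition
#'   alphabetically.
#' @return Data frame (condition, node_label, kind, mean, sem, delta).
#'   SEM is `sd/sqrt(n)` and `NA` for a single replicate; nodes absent from a
#'   condition (e.g. an interactor not bound there) are reported as `NA`,
#'   not 0.
#' @export
compare_states <- function(results, reference = NULL) {
  if (length(results) == 0L || is.null(names(results)))
    pf_error("usage_error", "results must be a nonempty named list")
  for (cond in names(results))
    if (length(results[[cond]]) == 0L)
      pf_error("usage_error", sprintf("condition '%s' has no replicates", cond))
  if (is.null(reference)) {
    reference <- intersect(c("apo", "none"), names(results))[1]
    if (is.na(reference)) reference <- sort(names(results))[1]
  } else if (!reference %in% names(results)) {
    pf_error("usage_error",
             sprintf("reference condition '%s' absent", reference))
  }
  all_nodes <- unique(unlist(lapply(results, function(reps)
    unlist(lapply(reps, function(r) r$labels)))))
  kind_of <- character(0)
  for (reps in results) for (r in reps)
    kind_of[r$labels] <- r$kinds
  per_cond <- lapply(results, function(reps) {
    mat <- sapply(reps, function(r) {
      v <- rep(NA_real_, length(all_nodes)); names(v) <- all_nodes
      v[r$labels] <- r$throughflow
      v
    })
    mat <- matrix(mat, nrow = length(all_nodes),
                  dimnames = list(all_nodes, NULL))
    n_obs <- rowSums(!is.na(mat))
    m <- rowMeans(mat, na.rm = TRUE); m[n_obs == 0] <- NA
    s <- apply(mat, 1, function(z) stats::sd(z[!is.na(z)]))
    sem <- ifelse(n_obs >= 2, s / sqrt(n_obs), NA_real_)
    list(mean = m, sem = sem)
  })
  ref_mean <- per_cond[[reference]]$mean
  out <- do.call(rbind, lapply(names(results), function(cond) {
    data.frame(condition = cond, node_label = all_nodes,
               kind = unname(kind_of[all_nodes]),
               mean = unname(per_cond[[cond]]$mean),
               sem = unname(per_cond[[cond]]$sem),
               delta = unname(per_cond[[cond]]$mean - ref_mean),
               stringsAsFactors = FALSE)
  }))
  attr(out, "reference") <- reference
  out
}

#' Write a flow result as CSV plus a JSON run manifest
#'
#' @param result A `flow_result`.
#' @param path CSV output path; the manifest is written alongside with a
#'   `.manifest.json` suffix.
#' @param graph Optional `contact_graph` used, for the graph hash.
#' @return The CSV path, invisibly.
#' @export
write_flow_result <- function(result, path, graph = NULL) {
  df <- as.data.frame(result)
  df$potential <- sprintf("%.6g", df$potential)
  df$throughflow <- sprintf("%.6g", df$throughflow)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    sources = result$sources, sinks = result$sinks,
    effective_resistance = result$effective_resistance,
    total_injected = result$total_injected,
    graph_hash = if (!is.null(graph)) contact_graph_hash(graph) else NULL
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# md5 of the canonical edge-list serialization
contact_graph_hash <- function(graph) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_contact_graph(graph, tmp)
  unname(tools::md5sum(tmp))
}
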