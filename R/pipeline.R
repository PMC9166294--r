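# Config-driven end-to-end runs: per condition and replicate, build the
# contact graph, compute flow and observables, aggregate replicates
# (mean +/- SEM), and write tables plus a JSON manifest.

.known_config_keys <- c("conditions", "source_residues", "sink_residues",
                        "interactors", "contact", "hbond", "hbond_pairs",
                        "distance_pairs", "numbering_offset", "stride",
                        "base_seed", "output_dir", "reference_condition",
                        "bin_width")

#' Load and validate a YAML run configuration
#'
#' Fills defaults (contact cutoff 4.5 A, smoothing SD 1.38 A, pruning 1e-4,
#' H-bond cutoff 3.0 A, stride 1, histogram bin width 0.5 A), normalizes
#' lengths given with `"nm"` suffixes to Angstrom, and checks that source and
#' sink residues resolve in each condition's topology.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    pf_error("config_error", sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    pf_error("config_error",
                             paste("cannot parse YAML:", conditionMessage(e))))
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown) > 0L)
    pf_error("config_error",
             sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")))
  if (is.null(raw$conditions) || length(raw$conditions) == 0L)
    pf_error("config_error", "config must define at least one condition")
  if (is.null(raw$source_residues) || is.null(raw$sink_residues) ||
      length(raw$source_residues) == 0L || length(raw$sink_residues) == 0L)
    pf_error("config_error", "source_residues and sink_residues are required")
  if (length(intersect(unlist(raw$source_residues),
                       unlist(raw$sink_residues))) > 0L)
    pf_error("config_error", "source and sink residue lists must be disjoint")
  ct <- raw$contact
  params <- contact_params(
    c = if (is.null(ct$c)) 4.5 else ct$c,
    sigma = if (is.null(ct$sigma)) 1.38 else ct$sigma,
    prune_below = if (is.null(ct$prune_below)) 1e-4
                  else as.numeric(ct$prune_below))
  hb <- raw$hbond
  hbond <- hbond_criteria(
    da_cutoff = if (is.null(hb$da_cutoff)) 3.0 else hb$da_cutoff,
    dha_angle_min = if (is.null(hb$dha_angle_min)) 150
                    else as.numeric(hb$dha_angle_min))
  conditions <- lapply(raw$conditions, function(reps) {
    if (!is.null(reps$topology)) reps <- list(reps)  # single replicate
    lapply(seq_along(reps), function(i) {
      r <- reps[[i]]
      if (is.null(r$topology))
        pf_error("config_error", "each replicate needs a topology path")
      list(topology = r$topology,
           trajectories = unlist(r$trajectories) %||% r$topology,
           replicate_id = r$replicate_id %||% i)
    })
  })
  cfg <- structure(list(
    conditions = conditions,
    source_residues = unlist(raw$source_residues),
    sink_residues = unlist(raw$sink_residues),
    interactors = raw$interactors %||% list(),
    contact = params,
    hbond = hbond,
    hbond_pairs = raw$hbond_pairs %||% list(),
    distance_pairs = raw$distance_pairs %||% list(),
    numbering_offset = raw$numbering_offset,
    stride = as.integer(raw$stride %||% 1L),
    bin_width = as.numeric(raw$bin_width %||% 0.5),
    base_seed = as.integer(raw$base_seed %||% 1L),
    output_dir = raw$output_dir %||% "pathflow_out",
    reference_condition = raw$reference_condition,
    config_path = path
  ), class = "run_config")
  # check source/sink resolvability against each condition's first topology
  for (cond in names(cfg$conditions)) {
    top_path <- cfg$conditions[[cond]][[1]]$topology
    if (file.exists(top_path)) {
      topo <- read_structure(top_path)
      nmap <- build_node_map(topo, normalize_selectors(cfg$interactors))
      resolve_residues(nmap, as.list(cfg$source_residues),
                       cfg$numbering_offset)
      resolve_residues(nmap, as.list(cfg$sink_residues),
                       cfg$numbering_offset)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_selectors <- function(sel) {
  lapply(sel, function(s) {
    if (is.character(s)) list(residue_name = s) else s
  })
}

resolve_atom <- function(structure, node_map, spec,
                         numbering_offset = NULL) {
  lab <- resolve_residues(node_map, list(spec$residue), numbering_offset)
  rows <- node_map$members[[lab[1]]]
  at <- structure$atoms
  hit <- rows[at$atom_name[rows] == (spec$atom %||% "CA")]
  if (length(hit) == 0L)
    pf_error("resolution_error",
             sprintf("atom '%s' not found in residue %s",
                     spec$atom %||% "CA", lab[1]))
  hit[1]
}

#' Aggregate per-node replicate tables into mean and SEM
#'
#' @param values List of numeric vectors (or single-value-column data frames)
#'   with identical node-label names.
#' @return Data frame (node_label, mean, sem); SEM is `sd/sqrt(n)` and `NA`
#'   when `n = 1`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L)
    pf_error("usage_error", "need at least one replicate table")
  vecs <- lapply(values, function(v) {
    if (is.data.frame(v)) {
      num_col <- names(v)[vapply(v, is.numeric, logical(1))][1]
      stats::setNames(v[[num_col]], v$node_label)
    } else v
  })
  ref_names <- names(vecs[[1]])
  for (i in seq_along(vecs)) {
    extra <- setdiff(names(vecs[[i]]), ref_names)
    miss <- setdiff(ref_names, names(vecs[[i]]))
    if (length(extra) + length(miss) > 0L)
      pf_error("usage_error",
               sprintf("inconsistent node sets across replicates: %s",
                       paste(c(extra, miss), collapse = ", ")))
  }
  mat <- sapply(vecs, function(v) v[ref_names])
  mat <- matrix(mat, nrow = length(ref_names))
  n <- ncol(mat)
  data.frame(node_label = ref_names,
             mean = rowMeans(mat),
             sem = if (n >= 2) apply(mat, 1, stats::sd) / sqrt(n)
                   else rep(NA_real_, nrow(mat)),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Per condition and replicate: contact graph, flow result, RMSF, distance
#' histograms, H-bond occupancies and ligand displacement; then a
#' cross-condition comparison table and a JSON manifest.  Reruns with the
#' same inputs reproduce identical tables.
#'
#' @param config A `run_config` from [load_run_config()], or a path to one.
#' @param keep_going Continue past per-replicate errors (reported at the
#'   end) instead of stopping on the first.
#' @return Invisibly, a list with the per-condition flow results, the
#'   comparison table and the manifest path.
#' @export
run_pipeline <- function(config, keep_going = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  selectors <- normalize_selectors(config$interactors)
  flow_by_cond <- list()
  rmsf_by_cond <- list()
  errors <- character(0)
  written <- character(0)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  emit <- function(path) { written <<- c(written, path); path }

  for (cond in names(config$conditions)) {
    flow_by_cond[[cond]] <- list()
    rmsf_by_cond[[cond]] <- list()
    for (rep_spec in config$conditions[[cond]]) {
      tag <- sprintf("%s_rep%d", cond, rep_spec$replicate_id)
      res <- tryCatch({
        log("start %s", tag)
        topo <- read_structure(rep_spec$topology)
        nmap <- build_node_map(topo, selectors)
        traj <- read_trajectory(topo, rep_spec$trajectories,
                                stride = config$stride,
                                replicate_id = rep_spec$replicate_id)
        graph <- build_contact_graph(traj, nmap, config$contact)
        emit(write_contact_graph(graph,
                                 file.path(out_dir,
                                           paste0(tag, "_graph.csv"))))
        src <- resolve_residues(nmap, as.list(config$source_residues),
                                config$numbering_offset)
        snk <- resolve_residues(nmap, as.list(config$sink_residues),
                                config$numbering_offset)
        fl <- information_flow(graph, src, snk)
        emit(write_flow_result(fl, file.path(out_dir,
                                             paste0(tag, "_flow.csv")),
                               graph = graph))
        flow_by_cond[[cond]][[length(flow_by_cond[[cond]]) + 1L]] <- fl
        if (traj$n_frames >= 2) {
          rmsf <- compute_rmsf(traj)
          utils::write.csv(rmsf,
                           emit(file.path(out_dir,
                                          paste0(tag, "_rmsf.csv"))),
                           row.names = FALSE, quote = FALSE)
          rmsf_by_cond[[cond]][[length(rmsf_by_cond[[cond]]) + 1L]] <- rmsf
        }
        for (dp in config$distance_pairs) {
          a <- resolve_atom(topo, nmap, list(residue = dp$a,
                                             atom = dp$atom_a %||% "CA"),
                            config$numbering_offset)
          b <- resolve_atom(topo, nmap, list(residue = dp$b,
                                             atom = dp$atom_b %||% "CA"),
                            config$numbering_offset)
          ds <- pair_distance_series(traj, a, b, config$bin_width)
          utils::write.csv(data.frame(frame = seq_along(ds$values),
                                      distance = sprintf("%.6g", ds$values)),
                           emit(file.path(out_dir,
                                          sprintf("%s_dist_%s_%s.csv", tag,
                                                  dp$a, dp$b))),
                           row.names = FALSE, quote = FALSE)
        }
        if (length(config$hbond_pairs) > 0L) {
          hb_rows <- do.call(rbind, lapply(config$hbond_pairs, function(hp) {
            don <- resolve_atom(topo, nmap,
                                list(residue = hp$donor_residue,
                                     atom = hp$donor_atom),
                                config$numbering_offset)
            acc <- resolve_atom(topo, nmap,
                                list(residue = hp$acceptor_residue,
                                     atom = hp$acceptor_atom),
                                config$numbering_offset)
            hbond_occupancy(traj, don, acc, config$hbond)
          }))
          utils::write.csv(hb_rows,
                           emit(file.path(out_dir,
                                          paste0(tag, "_hbonds.csv"))),
                           row.names = FALSE, quote = FALSE)
        }
        inter_labs <- nmap$nodes$label[nmap$nodes$kind == "interactor"]
        if (length(inter_labs) > 0L && traj$n_frames >= 2 &&
            length(default_ca_selection(topo)) >= 3) {
          for (il in inter_labs) {
            ld <- ligand_displacement(traj, nmap, il)
            ld$com_displacement <- sprintf("%.6g", ld$com_displacement)
            ld$rmsd <- sprintf("%.6g", ld$rmsd)
            utils::write.csv(ld,
                             emit(file.path(out_dir,
                                            sprintf("%s_ligand_%s.csv", tag,
                                                    gsub(":", "_", il)))),
                             row.names = FALSE, quote = FALSE)
          }
        }
        log("done %s", tag)
        TRUE
      }, pathflow_error = function(e) {
        msg <- sprintf("[%s] %s", tag, conditionMessage(e))
        if (!keep_going)
          pf_error(sub("pathflow_", "",
                       class(e)[startsWith(class(e), "pathflow_")][1]), msg)
        errors <<- c(errors, msg)
        FALSE
      })
    }
  }

  cmp <- compare_states(flow_by_cond, reference = config$reference_condition)
  cmp_out <- cmp
  cmp_out$mean <- sprintf("%.6g", cmp_out$mean)
  cmp_out$sem <- ifelse(is.na(cmp$sem), "", sprintf("%.6g", cmp$sem))
  cmp_out$delta <- ifelse(is.na(cmp$delta), "", sprintf("%.6g", cmp$delta))
  utils::write.csv(cmp_out, emit(file.path(out_dir, "compare_states.csv")),
                   row.names = FALSE, quote = FALSE)
  rmsf_agg <- lapply(rmsf_by_cond, function(lst) {
    if (length(lst) == 0L) return(NULL)
    aggregate_replicates(lst)
  })
  for (cond in names(rmsf_agg)) {
    if (is.null(rmsf_agg[[cond]])) next
    df <- rmsf_agg[[cond]]
    df$mean <- sprintf("%.6g", df$mean)
    df$sem <- ifelse(is.na(rmsf_agg[[cond]]$sem), "",
                     sprintf("%.6g", rmsf_agg[[cond]]$sem))
    utils::write.csv(df,
                     emit(file.path(out_dir,
                                    sprintf("rmsf_%s_mean_sem.csv", cond))),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("pathflow")),
    config_file = config$config_path,
    config_md5 = if (!is.null(config$config_path) &&
                     file.exists(config$config_path))
      unname(tools::md5sum(config$config_path)) else NULL,
    base_seed = config$base_seed,
    contact = unclass(config$contact),
    sources = config$source_residues,
    sinks = config$sink_residues,
    reference = attr(cmp, "reference"),
    outputs = as.list(stats::setNames(unname(tools::md5sum(written)),
                                      basename(written))),
    errors = if (length(errors) > 0) errors else NULL
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  if (length(errors) > 0)
    warning(sprintf("%d replicate(s) failed; see manifest", length(errors)))
  invisible(list(flow = flow_by_cond, comparison = cmp,
                 rmsf = rmsf_agg, manifest = manifest_path,
                 outputs = written))
}
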