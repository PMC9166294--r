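# Node assignment: one node per amino-acid residue (all of its heavy atoms)
# and one "interactor" node per selected ligand/lipid molecule (all of its
# heavy atoms).  Waters and monoatomic ions are never nodes.

node_label <- function(chain, resname, resnum) {
  sprintf("%s:%s%d", chain, resname, resnum)
}

#' Build the residue/interactor node partition of a structure
#'
#' Every amino-acid residue becomes one residue node holding all of its heavy
#' atoms.  Each hetero molecule matched by an interactor selector becomes one
#' interactor node (e.g. one node per bound cholesterol).  Waters (HOH) and
#' monoatomic ions are excluded; unmatched hetero molecules are not mapped.
#'
#' @param structure A `structure_model`.
#' @param interactor_selectors List of selectors, each a list with
#'   `residue_name` and optional `chain_id` and `residue_number`.
#' @return A `node_map`: list with a `nodes` data frame (label, kind, chain,
#'   resnum, resname, anchor_atom) and `members`, a named list of heavy-atom
#'   index vectors (disjoint across nodes).
#' @export
build_node_map <- function(structure, interactor_selectors = list()) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  res <- structure$residues
  is_aa <- res$residue_name %in% .standard_aa
  labels <- character(0); kinds <- character(0)
  chains <- character(0); resnums <- integer(0); resnames <- character(0)
  anchors <- integer(0); members <- list()

  add_node <- function(rows, kind, lab, chain, resnum, resname) {
    heavy <- rows[at$is_heavy[rows]]
    if (length(heavy) == 0L)
      pf_error("integrity_error",
               sprintf("residue %s has no heavy atoms", lab))
    anchor <- if (kind == "residue") {
      ca <- heavy[at$atom_name[heavy] == "CA"]
      if (length(ca) > 0L) ca[1] else heavy[1]
    } else heavy[1]
    labels <<- c(labels, lab); kinds <<- c(kinds, kind)
    chains <<- c(chains, chain); resnums <<- c(resnums, resnum)
    resnames <<- c(resnames, resname); anchors <<- c(anchors, anchor)
    members[[lab]] <<- heavy
  }

  for (i in seq_len(nrow(res))) {
    if (!is_aa[i]) next
    rows <- which(structure$residue_key == res$residue_key[i])
    add_node(rows, "residue",
             node_label(res$chain_id[i], res$residue_name[i],
                        res$residue_number[i]),
             res$chain_id[i], res$residue_number[i], res$residue_name[i])
  }

  for (sel in interactor_selectors) {
    if (is.null(sel$residue_name))
      pf_error("config_error", "interactor selector lacks residue_name")
    hit <- res$residue_name == sel$residue_name
    if (!is.null(sel$chain_id)) hit <- hit & res$chain_id == sel$chain_id
    if (!is.null(sel$residue_number))
      hit <- hit & res$residue_number == sel$residue_number
    if (any(hit & is_aa))
      pf_error("ambiguity_error",
               sprintf("interactor selector '%s' matches an amino-acid residue",
                       sel$residue_name))
    for (i in which(hit)) {
      rn <- res$residue_name[i]
      if (rn == "HOH" || rn %in% .ion_resnames) next
      rows <- which(structure$residue_key == res$residue_key[i])
      add_node(rows, "interactor",
               node_label(res$chain_id[i], rn, res$residue_number[i]),
               res$chain_id[i], res$residue_number[i], rn)
    }
  }

  if (anyDuplicated(labels))
    pf_error("integrity_error", "duplicate node labels in node map")
  map <- structure(
    list(nodes = data.frame(label = labels, kind = kinds, chain = chains,
                            resnum = resnums, resname = resnames,
                            anchor_atom = anchors, stringsAsFactors = FALSE),
         members = members),
    class = "node_map"
  )
  validate_node_map(map, structure)
  map
}

validate_node_map <- function(map, structure) {
  all_members <- unlist(map$members, use.names = FALSE)
  if (anyDuplicated(all_members))
    pf_error("integrity_error", "node member atom sets are not disjoint")
  if (any(!structure$atoms$is_heavy[all_members]))
    pf_error("integrity_error", "node member atoms must be heavy atoms")
  invisible(map)
}

#' @export
print.node_map <- function(x, ...) {
  cat(sprintf("node_map: %d nodes (%d residue, %d interactor)\n",
              nrow(x$nodes), sum(x$nodes$kind == "residue"),
              sum(x$nodes$kind == "interactor")))
  invisible(x)
}

# Resolve residue identifiers like "D99" or 99 against a node map, applying a
# per-chain numbering offset first.  Returns node labels.
resolve_residues <- function(node_map, specs, numbering_offset = NULL) {
  nd <- node_map$nodes[node_map$nodes$kind == "residue", ]
  out <- character(0)
  for (sp in specs) {
    chain <- NULL; letter <- NULL
    if (is.numeric(sp)) {
      num <- as.integer(sp)
    } else {
      s <- trimws(as.character(sp))
      if (grepl(":", s, fixed = TRUE)) {
        chain <- sub(":.*", "", s)
        s <- sub(".*:", "", s)
      }
      m <- regmatches(s, regexec("^([A-Za-z]?)([0-9]+)$", s))[[1]]
      if (length(m) == 0L)
        pf_error("resolution_error",
                 sprintf("cannot parse residue spec '%s'", sp))
      if (nzchar(m[2])) letter <- toupper(m[2])
      num <- as.integer(m[3])
    }
    cand <- nd
    if (!is.null(chain)) cand <- cand[cand$chain == chain, ]
    offs <- 0L
    if (!is.null(numbering_offset)) {
      if (length(numbering_offset) == 1L && is.null(names(numbering_offset))) {
        offs <- as.integer(numbering_offset)
      } else if (!is.null(chain) && chain %in% names(numbering_offset)) {
        offs <- as.integer(numbering_offset[[chain]])
      } else if (length(numbering_offset) >= 1L && is.null(chain)) {
        offs <- as.integer(numbering_offset[[1]])
      }
    }
    cand <- cand[cand$resnum == num + offs, ]
    if (nrow(cand) == 0L)
      pf_error("resolution_error",
               sprintf("residue '%s' (number %d after offset) not found%s",
                       sp, num + offs,
                       if (is.null(chain)) "" else paste0(" in chain ", chain)))
    if (!is.null(letter)) {
      one <- .aa_three_to_one[cand$resname]
      ok <- !is.na(one) & one == letter
      if (!any(ok))
        pf_error("resolution_error",
                 sprintf("residue number %d is %s, not '%s'",
                         num + offs, cand$resname[1], letter))
      cand <- cand[ok, , drop = FALSE]
    }
    out <- c(out, cand$label)
  }
  unique(out)
}
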