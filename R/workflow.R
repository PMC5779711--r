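# The project model: a DAG of operation nodes with parameter storage,
# execution dispatch, downstream recalculation, status tracking, group
# copy/paste and project summaries. Projects are plain values: every
# operation returns the updated project.

NODE_STATUSES <- c("not_started", "in_progress", "finished", "obsolete")

#' Create an empty project
#'
#' A project bundles the workflow graph with its registries: feature
#' library, restriction enzymes (+ aliases and buffer systems),
#' recombination sites, guide RNAs, and the primer list with its
#' ordered flags.
#'
#' @param name project name.
#' @param load_defaults load the bundled enzyme/site/gRNA tables?
#' @return an object of class `clone_project`.
#' @export
new_project <- function(name = "project", load_defaults = TRUE) {
  structure(
    list(name = name,
         nodes = list(),
         counter = 0L,
         features = feature_library(),
         enzymes = if (load_defaults) read_enzyme_table() else list(),
         aliases = if (load_defaults) read_alias_table() else NULL,
         sites = if (load_defaults) read_site_table() else list(),
         grnas = if (load_defaults) read_grna_table() else list(),
         primers = data.frame(name = character(0), sequence = character(0),
                              ordered = logical(0), stringsAsFactors = FALSE),
         metadata = list()),
    class = "clone_project")
}

new_node_id <- function(project) sprintf("n%04d", project$counter + 1L)

#' Add a workflow node
#'
#' @param project a [new_project()].
#' @param op_kind operation kind (see [execute_node()] for the dispatch
#'   table).
#' @param params operation-specific parameter list.
#' @param sources character vector of source node ids (ordered).
#' @param name display name.
#' @param node_id explicit id (auto-generated when `NULL`).
#' @return the updated project; the new node's id is in
#'   `attr(, "node_id")`.
#' @export
add_node <- function(project, op_kind, params = list(),
                     sources = character(0), name = op_kind, node_id = NULL) {
  stopifnot(inherits(project, "clone_project"))
  missing <- setdiff(sources, names(project$nodes))
  if (length(missing) > 0) {
    stop("dangling source node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(node_id)) node_id <- new_node_id(project)
  if (node_id %in% names(project$nodes)) {
    stop("duplicate node id: ", node_id, call. = FALSE)
  }
  project$counter <- project$counter + 1L
  project$nodes[[node_id]] <- list(
    node_id = node_id, name = name, op_kind = op_kind, params = params,
    sources = sources, status = "not_started", notes = "",
    results = NULL, stale = TRUE, cache_key = "")
  attr(project, "node_id") <- node_id
  project
}

#' Connect two existing nodes
#'
#' Appends `from` to the sources of `to`; refuses edges that would create a
#' cycle.
#'
#' @param project a project.
#' @param from,to node ids.
#' @return the updated project.
#' @export
connect <- function(project, from, to) {
  stopifnot(from %in% names(project$nodes), to %in% names(project$nodes))
  if (from %in% .descendants(project, to) || from == to) {
    stop("edge ", from, " -> ", to, " would create a cycle", call. = FALSE)
  }
  project$nodes[[to]]$sources <- c(project$nodes[[to]]$sources, from)
  project$nodes[[to]]$stale <- TRUE
  project
}

.descendants <- function(project, node_id) {
  out <- character(0)
  frontier <- node_id
  while (length(frontier) > 0) {
    kids <- names(Filter(function(nd) any(frontier %in% nd$sources),
                         project$nodes))
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Topological order of a node set (Kahn's algorithm)
#' @param project a project.
#' @param ids node ids to order (whole graph when `NULL`).
#' @return ids ordered so every node follows all its in-set sources.
#' @export
topo_order <- function(project, ids = NULL) {
  if (is.null(ids)) ids <- names(project$nodes)
  indeg <- vapply(ids, function(id) {
    length(intersect(project$nodes[[id]]$sources, ids))
  }, integer(1))
  names(indeg) <- ids
  out <- character(0)
  ready <- ids[indeg == 0L]
  while (length(ready) > 0) {
    nd <- ready[1]
    ready <- ready[-1]
    out <- c(out, nd)
    kids <- ids[vapply(ids, function(k) nd %in% project$nodes[[k]]$sources,
                       logical(1))]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(out) != length(ids)) stop("graph has a cycle", call. = FALSE)
  out
}

#' Cached results of a node
#' @param project a project.
#' @param node_id node id.
#' @return the node's result list (molecules and/or host cells).
#' @export
node_results <- function(project, node_id) {
  project$nodes[[node_id]]$results
}

# stable digest of (op_kind, params, source hashes) for no-op recalculation
.node_cache_key <- function(node, src_hashes) {
  cli::hash_sha256(paste(
    node$op_kind,
    paste(deparse(node$params), collapse = ""),
    paste(src_hashes, collapse = ","),
    sep = "\x1f"))
}

.result_hash <- function(x) {
  if (inherits(x, "dna_molecule")) return(canonical_hash(x))
  cli::hash_sha256(paste(deparse(x), collapse = ""))
}

#' Execute one workflow node
#'
#' Dispatches on `op_kind` with the node's parameters and its sources'
#' cached results, caches the results and clears the stale flag. All
#' molecule-producing operations annotate their products against the
#' project feature library. Supported kinds: `sequence_input`,
#' `sequence_designer`, `host_input`, `digest`, `crispr`, `modification`,
#' `ligation`, `recombination`, `gibson`, `pcr`, `gel`, `feature_screen`,
#' `pcr_screen`, `hash_select`, `enzyme_analysis`, `merge`, `sequencing`,
#' `compare`, `orf_detect`, `transformation`, `incubation`, `extraction`.
#'
#' @param project a project.
#' @param node_id the node to run.
#' @return the updated project (results cached on the node).
#' @export
execute_node <- function(project, node_id) {
  node <- project$nodes[[node_id]]
  if (is.null(node)) stop("unknown node: ", node_id, call. = FALSE)
  src_results <- list()
  for (s in node$sources) {
    src <- project$nodes[[s]]
    if (src$stale || is.null(src$results)) {
      stop("source node ", s, " of ", node_id, " has no up-to-date results",
           call. = FALSE)
    }
    src_results <- c(src_results, src$results)
  }
  src_hashes <- vapply(src_results, .result_hash, character(1))
  key <- .node_cache_key(node, src_hashes)
  if (identical(key, node$cache_key) && !is.null(node$results) && !node$stale) {
    return(project)   # content-addressed no-op
  }
  results <- .dispatch_op(node, src_results, project)
  results <- lapply(results, function(x) {
    if (inherits(x, "dna_molecule")) annotate_features(x, project$features)
    else x
  })
  node$results <- results
  node$stale <- FALSE
  node$cache_key <- key
  lens <- vapply(results, function(x) {
    if (inherits(x, "dna_molecule")) nchar(x$seq) else NA_integer_
  }, integer(1))
  node$notes <- sprintf("%d result(s)%s", length(results),
                        if (all(is.na(lens))) "" else
                          paste0("; lengths ", paste(stats::na.omit(lens),
                                                     collapse = ",")))
  project$nodes[[node_id]] <- node
  project
}

.only_molecules <- function(xs) Filter(function(x) inherits(x, "dna_molecule"), xs)
.only_cells <- function(xs) Filter(function(x) inherits(x, "host_cell"), xs)

.resolve_primers <- function(project, spec) {
  if (is.null(spec)) stop("primers required", call. = FALSE)
  if (is.character(spec)) {
    idx <- match(spec, project$primers$name)
    if (anyNA(idx)) {
      stop("unknown primer(s): ", paste(spec[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    return(lapply(idx, function(i) {
      pcr_primer(project$primers$name[i], project$primers$sequence[i])
    }))
  }
  as_primer_list(spec)
}

.dispatch_op <- function(node, inputs, project) {
  p <- node$params
  mols <- .only_molecules(inputs)
  switch(node$op_kind,
    sequence_input = {
      if (!is.null(p$molecule)) list(p$molecule)
      else if (!is.null(p$path)) read_sequences(p$path, format = p$format)
      else stop("sequence_input needs a molecule or a path", call. = FALSE)
    },
    sequence_designer = {
      seqd <- expand_designer_text(p$text, enzymes = project$enzymes,
                                   sites = project$sites,
                                   features = project$features)
      list(dna_molecule(seqd, "linear", note = "designed sequence"))
    },
    host_input = list(p$host),
    digest = digest(mols, p$enzymes, registry = project$enzymes)$fragments,
    crispr = {
      guides <- if (is.character(p$guides)) project$grnas[p$guides] else p$guides
      crispr_digest(mols, guides)
    },
    modification = modify_ends(mols, p$treatment),
    ligation = ligate(mols, mode = p$mode %||% join_mode("normal")),
    recombination = recombine(mols, p$spec, mode = p$mode,
                              site_registry = project$sites),
    gibson = {
      stopifnot(length(mols) == length(p$sources_meta))
      srcs <- lapply(seq_along(mols), function(i) {
        meta <- p$sources_meta[[i]]
        gibson_source(mols[[i]], is_pcr = isTRUE(meta$is_pcr),
                      fwd = meta$fwd, rev = meta$rev)
      })
      res <- design_gibson(srcs, tm_threshold = p$tm_threshold %||% 48,
                           min_overlap = p$min_overlap %||% 15L)
      list(res$product)
    },
    pcr = {
      res <- simulate_pcr(mols, .resolve_primers(project, p$primers),
                          min_anneal_3p = p$min_anneal_3p %||% 15L)
      res$products
    },
    gel = gel_select(mols, p$min_len %||% 1L, p$max_len %||% Inf),
    feature_screen = feature_screen(mols, p$condition),
    pcr_screen = pcr_screen(mols, .resolve_primers(project, p$primers),
                            p$len_range),
    hash_select = Filter(function(m) canonical_hash(m) %in% p$hashes, mols),
    enzyme_analysis = as.list(enzyme_analysis(mols, p$conditions,
                                              registry = project$enzymes)),
    merge = lapply(merge_sequences(mols, p$min_overlap %||% 15L),
                   function(s) dna_molecule(s, "linear", note = "merged")),
    sequencing = {
      stopifnot(length(mols) == 1L)
      read <- simulate_sequencing(mols[[1]],
                                  .resolve_primers(project, p$primer)[[1]],
                                  p$read_length %||% 800L)
      list(dna_molecule(read, "linear", note = "simulated read"))
    },
    compare = {
      stopifnot(length(mols) >= 2L)
      list(compare_sequences(mols[[1]], mols[-1]))
    },
    orf_detect = {
      stopifnot(length(mols) == 1L)
      m <- mols[[1]]
      m$features <- c(m$features,
                      detect_orfs(m, p$start_codons %||% "ATG",
                                  p$min_len %||% 90L,
                                  p$both_strands %||% TRUE))
      list(m)
    },
    transformation = {
      cells <- .only_cells(inputs)
      stopifnot(length(cells) == 1L)
      transform_dna(cells[[1]], mols, method = p$method %||% "chemical",
                    mode = p$mode %||% "all_in_one")
    },
    incubation = incubate(.only_cells(inputs), p$antibiotics %||% character(0),
                          overnight = p$overnight %||% TRUE),
    extraction = {
      cells <- .only_cells(inputs)
      unlist(lapply(cells, extract_plasmids), recursive = FALSE)
    },
    stop("unknown op_kind: ", node$op_kind, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recalculate a node and all its descendants
#'
#' Re-executes the node and every downstream node in a topological order
#' (each node after all its sources). A node whose execution fails is
#' marked stale together with its descendants, and its siblings continue.
#'
#' @param project a project.
#' @param node_id the edited node.
#' @return list with `project` (updated) and `recalculated` (ordered ids
#'   actually re-run).
#' @export
recalculate_children <- function(project, node_id) {
  if (!node_id %in% names(project$nodes)) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  set <- c(node_id, .descendants(project, node_id))
  order <- topo_order(project, set)
  # force re-execution of the edited node itself
  project$nodes[[node_id]]$cache_key <- ""
  project$nodes[[node_id]]$stale <- TRUE
  ran <- character(0)
  for (id in order) {
    srcs <- project$nodes[[id]]$sources
    bad <- srcs[vapply(srcs, function(s) isTRUE(project$nodes[[s]]$stale) ||
                         is.null(project$nodes[[s]]$results), logical(1))]
    if (length(bad) > 0) {
      project$nodes[[id]]$stale <- TRUE
      next
    }
    ok <- tryCatch({
      project <- execute_node(project, id)
      TRUE
    }, error = function(e) {
      project$nodes[[id]]$stale <<- TRUE
      project$nodes[[id]]$notes <<- conditionMessage(e)
      FALSE
    })
    if (ok) ran <- c(ran, id)
  }
  list(project = project, recalculated = ran)
}

#' Set a node's status
#'
#' One of `"not_started"`, `"in_progress"`, `"finished"`, `"obsolete"`
#' (`"completed"` is accepted as an alias for `"finished"`). Status has no
#' effect on results or staleness, but obsolete nodes are excluded from
#' [project_summary()].
#'
#' @param project a project.
#' @param node_id node id.
#' @param status status token.
#' @return the updated project.
#' @export
set_status <- function(project, node_id, status) {
  if (identical(status, "completed")) status <- "finished"
  if (!status %in% NODE_STATUSES) {
    stop("unknown status: ", status, call. = FALSE)
  }
  if (!node_id %in% names(project$nodes)) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  project$nodes[[node_id]]$status <- status
  project
}

#' Register primers in the project
#'
#' @param project a project.
#' @param names,sequences primer names and sequences.
#' @param ordered has each primer already been ordered?
#' @return the updated project.
#' @export
register_primers <- function(project, names, sequences, ordered = FALSE) {
  add <- data.frame(name = names, sequence = toupper(sequences),
                    ordered = rep_len(ordered, length(names)),
                    stringsAsFactors = FALSE)
  keep <- !project$primers$name %in% add$name
  project$primers <- rbind(project$primers[keep, , drop = FALSE], add)
  project
}

#' Group copy / group paste
#'
#' `group_copy` captures the selected nodes with the edges among them and
#' the registry entries they reference. `group_paste` inserts them into a
#' (possibly different) project with fresh ids: internal edges are
#' preserved, edges to non-copied sources are dropped (pasted nodes become
#' inputs-required), and referenced features/primers are merged into the
#' target registries without duplication.
#'
#' @param project source project.
#' @param node_ids nodes to copy.
#' @return `group_copy`: a clipboard object.
#' @export
group_copy <- function(project, node_ids) {
  stopifnot(all(node_ids %in% names(project$nodes)))
  nodes <- project$nodes[node_ids]
  # referenced feature-library entries: conservative, ship the whole library
  structure(list(nodes = nodes, features = project$features,
                 primers = project$primers),
            class = "node_clipboard")
}

#' @rdname group_copy
#' @param target target project.
#' @param clipboard a `group_copy()` result.
#' @return `group_paste`: list with `project` and `new_ids` (named by the
#'   original ids).
#' @export
group_paste <- function(target, clipboard) {
  stopifnot(inherits(clipboard, "node_clipboard"))
  old_ids <- names(clipboard$nodes)
  new_ids <- stats::setNames(character(length(old_ids)), old_ids)
  for (oid in old_ids) {
    nd <- clipboard$nodes[[oid]]
    nid <- new_node_id(target)
    target$counter <- target$counter + 1L
    new_ids[oid] <- nid
    nd$node_id <- nid
    nd$sources <- unname(new_ids[nd$sources[nd$sources %in% old_ids]])
    nd$sources <- nd$sources[!is.na(nd$sources) & nzchar(nd$sources)]
    nd$results <- NULL
    nd$stale <- TRUE
    nd$cache_key <- ""
    target$nodes[[nid]] <- nd
  }
  # merge registries without duplication
  for (nm in names(clipboard$features$entries)) {
    if (is.null(library_lookup(target$features, nm))) {
      target$features$entries[[nm]] <- clipboard$features$entries[[nm]]
    }
  }
  newp <- clipboard$primers[!clipboard$primers$name %in% target$primers$name, ,
                            drop = FALSE]
  target$primers <- rbind(target$primers, newp)
  list(project = target, new_ids = new_ids)
}

#' Project summary
#'
#' Aggregates across non-obsolete nodes: all primers used (partitioned into
#' already-ordered and new by the registry's ordered flag), sequences
#' flagged for synthesis, restriction enzymes and end-modification
#' treatments used.
#'
#' @param project a project.
#' @return list with `primers_ordered`, `primers_new`, `synthesis`,
#'   `enzymes`, `treatments`.
#' @export
project_summary <- function(project) {
  primer_names <- character(0)
  enzymes <- character(0)
  treatments <- character(0)
  synthesis <- character(0)
  for (nd in project$nodes) {
    if (nd$status == "obsolete") next
    p <- nd$params
    if (nd$op_kind %in% c("pcr", "pcr_screen") && is.character(p$primers)) {
      primer_names <- c(primer_names, p$primers)
    }
    if (nd$op_kind == "sequencing" && is.character(p$primer)) {
      primer_names <- c(primer_names, p$primer)
    }
    if (nd$op_kind == "digest") enzymes <- c(enzymes, p$enzymes)
    if (nd$op_kind == "modification") treatments <- c(treatments, p$treatment)
    if (nd$op_kind == "sequence_designer" && isTRUE(p$synthesize)) {
      synthesis <- c(synthesis, p$text)
    }
  }
  primer_names <- unique(primer_names)
  reg <- project$primers
  idx <- match(primer_names, reg$name)
  known <- primer_names[!is.na(idx)]
  ordered_flag <- reg$ordered[match(known, reg$name)]
  list(
    primers_ordered = data.frame(
      name = known[ordered_flag],
      sequence = reg$sequence[match(known[ordered_flag], reg$name)],
      stringsAsFactors = FALSE),
    primers_new = data.frame(
      name = c(known[!ordered_flag], primer_names[is.na(idx)]),
      sequence = c(reg$sequence[match(known[!ordered_flag], reg$name)],
                   rep(NA_character_, sum(is.na(idx)))),
      stringsAsFactors = FALSE),
    synthesis = synthesis,
    enzymes = sort(unique(enzymes)),
    treatments = sort(unique(treatments)))
}

#' New-primer clipboard view
#'
#' @param project a project.
#' @return character vector of `name<TAB>sequence` lines for primers not yet
#'   ordered.
#' @export
copy_new_primers <- function(project) {
  s <- project_summary(project)
  nw <- s$primers_new
  sprintf("%s\t%s", nw$name, ifelse(is.na(nw$sequence), "", nw$sequence))
}
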