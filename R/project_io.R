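# Project persistence: a documented structured-text (JSON) schema with a
# canonical field order, so save -> load -> save is byte-identical.

.enc <- function(x) {
  if (inherits(x, "dna_molecule")) {
    list(`_type` = "dna_molecule", id = x$id, seq = x$seq,
         topology = x$topology,
         left_end = if (is.null(x$left_end)) NULL else format_end_code(x$left_end),
         right_end = if (is.null(x$right_end)) NULL else format_end_code(x$right_end),
         features = lapply(x$features, .enc), note = x$note)
  } else if (inherits(x, "dna_feature")) {
    list(`_type` = "dna_feature", name = x$name, kind = x$kind,
         start = x$start, end = x$end, strand = x$strand,
         qualifiers = x$qualifiers)
  } else if (inherits(x, "dna_end")) {
    list(`_type` = "dna_end", code = format_end_code(x))
  } else if (inherits(x, "feature_library")) {
    list(`_type` = "feature_library", entries = x$entries)
  } else if (inherits(x, "host_cell")) {
    list(`_type` = "host_cell", name = x$name,
         genome_fragments = lapply(x$genome_fragments, .enc),
         primase_commands = as.list(x$primase_commands),
         intrinsic_resistances = as.list(x$intrinsic_resistances),
         hosted = lapply(x$hosted, .enc),
         transfer_competence = as.list(x$transfer_competence))
  } else if (inherits(x, "pcr_primer")) {
    list(`_type` = "pcr_primer", name = x$name, sequence = x$sequence,
         fixed = x$fixed, phosphorylated = x$phosphorylated)
  } else if (inherits(x, "screen_condition")) {
    list(`_type` = "screen_condition", require_circular = x$require_circular,
         feature_counts = x$feature_counts)
  } else if (inherits(x, "join_mode")) {
    list(`_type` = "join_mode", mode = x$mode, rounds = x$rounds,
         copies = as.list(x$copies))
  } else if (inherits(x, "homology_params")) {
    list(`_type` = "homology_params", family = x$family,
         min_homology_len = x$min_homology_len,
         terminal_window = if (is.finite(x$terminal_window))
           x$terminal_window else "Inf",
         min_arm_len = x$min_arm_len)
  } else if (inherits(x, "guide_rna")) {
    list(`_type` = "guide_rna", name = x$name, spacer = x$spacer,
         pam = x$pam, cut_offset = x$cut_offset,
         cut_offset_bottom = x$cut_offset_bottom)
  } else if (inherits(x, "recombination_site")) {
    list(`_type` = "recombination_site", name = x$name, sequence = x$sequence,
         core_start = x$core_start, core_end = x$core_end,
         reversible = x$reversible, partners = as.list(x$partners),
         marker_left = x$marker_left, marker_right = x$marker_right)
  } else if (inherits(x, "restriction_enzyme")) {
    list(`_type` = "restriction_enzyme", name = x$name,
         recognition = x$recognition, cut_top = x$cut_top,
         cut_bottom = x$cut_bottom, notes = x$notes)
  } else if (is.data.frame(x)) {
    list(`_type` = "data.frame", columns = lapply(as.list(x), as.vector))
  } else if (is.list(x)) {
    lapply(x, .enc)
  } else if (is.atomic(x) && length(x) > 1L && is.null(names(x))) {
    as.list(x)   # canonical form: multi-element vectors save as arrays of
                 # scalars, matching what a load produces
  } else {
    x
  }
}

.dec <- function(x) {
  if (!is.list(x)) return(x)
  ty <- x[["_type"]]
  if (is.null(ty)) {
    out <- lapply(x, .dec)
    # unnamed arrays of same-type scalars come back as vectors
    if (length(out) > 1L && is.null(names(out)) &&
        all(vapply(out, function(e) is.atomic(e) && length(e) == 1L,
                   logical(1))) &&
        length(unique(vapply(out, function(e) class(e)[1], character(1)))) == 1L) {
      return(unlist(out))
    }
    return(out)
  }
  switch(ty,
    dna_molecule = dna_molecule(
      x$seq, x$topology,
      left_end = if (is.null(x$left_end)) dna_end() else parse_end_code(x$left_end),
      right_end = if (is.null(x$right_end)) dna_end() else parse_end_code(x$right_end),
      features = lapply(x$features, .dec), id = x$id, note = x$note %||% ""),
    dna_feature = feature(x$name, x$kind, x$start, x$end, x$strand,
                          qualifiers = x$qualifiers %||% list()),
    dna_end = parse_end_code(x$code),
    feature_library = feature_library(x$entries),
    host_cell = host_cell(x$name, lapply(x$genome_fragments, .dec),
                          unlist(x$primase_commands) %||% character(0),
                          unlist(x$intrinsic_resistances) %||% character(0),
                          lapply(x$hosted, .dec),
                          unlist(x$transfer_competence)),
    pcr_primer = pcr_primer(x$name, x$sequence, x$fixed, x$phosphorylated),
    screen_condition = screen_condition(x$require_circular,
                                        lapply(x$feature_counts, .dec)),
    join_mode = join_mode(x$mode, x$rounds, unlist(x$copies)),
    homology_params = homology_params(
      x$family, min_homology_len = x$min_homology_len,
      terminal_window = if (identical(x$terminal_window, "Inf")) Inf else
        x$terminal_window,
      min_arm_len = x$min_arm_len),
    guide_rna = guide_rna(x$name, x$spacer, x$pam, x$cut_offset,
                          x$cut_offset_bottom),
    recombination_site = recombination_site(
      x$name, x$sequence, x$core_start, x$core_end, x$reversible,
      unlist(x$partners), x$marker_left %||% "", x$marker_right %||% ""),
    restriction_enzyme = restriction_enzyme(x$name, x$recognition,
                                            x$cut_top, x$cut_bottom,
                                            x$notes %||% ""),
    data.frame = as.data.frame(lapply(x$columns, function(cl) {
      if (length(cl) == 0L) character(0) else unlist(cl)
    }), stringsAsFactors = FALSE),
    stop("unknown serialized type: ", ty, call. = FALSE)
  )
}

#' Save / load a project
#'
#' Projects serialize to a canonical JSON schema (fixed field order, two-
#' space indentation), so saving, loading and saving again produces a
#' byte-identical file.
#'
#' @param project a [new_project()].
#' @param path file path.
#' @return `save_project`: the path, invisibly. `load_project`: the project.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "clone_project"))
  body <- list(
    schema = "clonesim-project-v1",
    name = project$name,
    counter = project$counter,
    nodes = lapply(project$nodes, function(nd) {
      list(node_id = nd$node_id, name = nd$name, op_kind = nd$op_kind,
           params = .enc(nd$params), sources = as.list(nd$sources),
           status = nd$status, notes = nd$notes,
           results = if (is.null(nd$results)) NULL else lapply(nd$results, .enc),
           stale = nd$stale, cache_key = nd$cache_key)
    }),
    features = .enc(project$features),
    primers = .enc(project$primers),
    metadata = project$metadata)
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$schema, "clonesim-project-v1")) {
    stop("not a clonesim project file", call. = FALSE)
  }
  project <- new_project(raw$name)
  project$counter <- raw$counter
  project$features <- .dec(raw$features)
  pr <- .dec(raw$primers)
  project$primers <- data.frame(name = as.character(pr$name),
                                sequence = as.character(pr$sequence),
                                ordered = as.logical(pr$ordered),
                                stringsAsFactors = FALSE)
  project$metadata <- raw$metadata %||% list()
  project$nodes <- lapply(raw$nodes, function(nd) {
    list(node_id = nd$node_id, name = nd$name, op_kind = nd$op_kind,
         params = .dec(nd$params), sources = unlist(nd$sources) %||% character(0),
         status = nd$status, notes = nd$notes %||% "",
         results = if (is.null(nd$results)) NULL else lapply(nd$results, .dec),
         stale = isTRUE(nd$stale), cache_key = nd$cache_key %||% "")
  })
  names(project$nodes) <- vapply(raw$nodes, `[[`, character(1), "node_id")
  project
}
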