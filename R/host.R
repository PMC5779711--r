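# Simulated bacterial hosts: transformation, incubation (replication-origin
# and antibiotic selection), plasmid extraction.

#' Define a host cell
#'
#' @param name strain name.
#' @param genome_fragments list of molecules with topology
#'   `"genomic_fragment"`.
#' @param primase_commands replication-origin names this host supports (an
#'   ori feature persists iff its origin name matches one of these).
#' @param intrinsic_resistances antibiotic names the strain resists without
#'   a plasmid.
#' @param hosted plasmids (circular molecules) currently carried.
#' @param transfer_competence subset of `c("chemical", "electro",
#'   "conjugation")`.
#' @return an object of class `host_cell`.
#' @export
host_cell <- function(name, genome_fragments = list(),
                      primase_commands = character(0),
                      intrinsic_resistances = character(0),
                      hosted = list(),
                      transfer_competence = c("chemical", "electro")) {
  genome_fragments <- as_molecule_list(genome_fragments)
  hosted <- as_molecule_list(hosted)
  for (g in genome_fragments) {
    if (g$topology != "genomic_fragment") {
      stop("genome fragments must have topology genomic_fragment", call. = FALSE)
    }
  }
  for (p in hosted) {
    if (p$topology != "circular") {
      stop("hosted molecules must be circular plasmids", call. = FALSE)
    }
  }
  stopifnot(all(transfer_competence %in% c("chemical", "electro", "conjugation")))
  structure(list(name = name, genome_fragments = genome_fragments,
                 primase_commands = primase_commands,
                 intrinsic_resistances = intrinsic_resistances,
                 hosted = hosted, transfer_competence = transfer_competence),
            class = "host_cell")
}

#' @export
print.host_cell <- function(x, ...) {
  cat(sprintf("<host_cell %s> %d genome fragment(s), %d hosted plasmid(s)\n",
              x$name, length(x$genome_fragments), length(x$hosted)))
  invisible(x)
}

#' Transformation
#'
#' Introduces DNA into host cells. `all_in_one`: one cell hosting all the
#' DNAs. `one_per_cell`: one cell per DNA (library construction).
#' `combinational`: one cell per non-empty subset of the DNAs.
#'
#' @param host the recipient [host_cell()] (cloned per resulting cell).
#' @param dnas list of circular molecules.
#' @param method one of the host's `transfer_competence` methods.
#' @param mode `"all_in_one"`, `"one_per_cell"` or `"combinational"`.
#' @return list of [host_cell()] objects.
#' @export
transform_dna <- function(host, dnas, method = "chemical",
                          mode = c("all_in_one", "one_per_cell",
                                   "combinational")) {
  stopifnot(inherits(host, "host_cell"))
  mode <- match.arg(mode)
  dnas <- as_molecule_list(dnas)
  if (!method %in% host$transfer_competence) {
    stop("host ", host$name, " is not competent for ", method,
         " transformation", call. = FALSE)
  }
  with_plasmids <- function(ps, tag) {
    cell <- host
    cell$name <- paste0(host$name, tag)
    cell$hosted <- c(host$hosted, ps)
    cell
  }
  switch(mode,
    all_in_one = list(with_plasmids(dnas, "")),
    one_per_cell = lapply(seq_along(dnas), function(i) {
      with_plasmids(dnas[i], paste0("#", i))
    }),
    combinational = {
      nsub <- 2L^length(dnas) - 1L
      lapply(seq_len(nsub), function(mask) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(dnas) - 1L)) != 0L)
        with_plasmids(dnas[sel], paste0("#", mask))
      })
    })
}

# does a molecule carry an ori feature matching one of the host's primase
# commands? The origin name is the feature's `origin` qualifier, falling
# back to the feature name.
.ori_supported <- function(mol, primase_commands) {
  for (f in mol$features) {
    if (f$kind != "ori") next
    origin <- f$qualifiers$origin
    if (is.null(origin)) origin <- f$name
    if (origin %in% primase_commands) return(TRUE)
  }
  FALSE
}

.has_resistance <- function(mol, antibiotic) {
  for (f in mol$features) {
    if (f$kind != "resistance") next
    ab <- f$qualifiers$antibiotic
    if (is.null(ab)) ab <- f$name
    if (ab == antibiotic) return(TRUE)
  }
  FALSE
}

#' Incubation
#'
#' First, replication: a hosted plasmid persists iff it carries an ori
#' feature whose origin name matches one of the host's primase commands;
#' other plasmids are lost. Then, selection (overnight incubation): a cell
#' survives iff for every antibiotic in the culture it has a matching
#' resistance feature on a persisting plasmid or an integrated genome copy,
#' or resists intrinsically. Without `overnight`, no cell is killed, but
#' unsupported plasmids are still lost.
#'
#' @param cells a [host_cell()] or list of them.
#' @param antibiotics character vector of antibiotic names in the culture.
#' @param overnight apply antibiotic selection?
#' @return list of surviving cells (with their plasmid complements updated).
#' @export
incubate <- function(cells, antibiotics = character(0), overnight = TRUE) {
  if (inherits(cells, "host_cell")) cells <- list(cells)
  out <- list()
  for (cell in cells) {
    cell$hosted <- Filter(function(p) .ori_supported(p, cell$primase_commands),
                          cell$hosted)
    if (overnight && length(antibiotics) > 0) {
      resists <- vapply(antibiotics, function(ab) {
        ab %in% cell$intrinsic_resistances ||
          any(vapply(cell$hosted, .has_resistance, logical(1), ab)) ||
          any(vapply(cell$genome_fragments, .has_resistance, logical(1), ab))
      }, logical(1))
      if (!all(resists)) next
    }
    out <- c(out, list(cell))
  }
  out
}

#' Plasmid extraction
#'
#' Returns all DNA hosted in a cell as a mixture, excluding the host genomic
#' DNA. The cell is not modified.
#'
#' @param cell a [host_cell()].
#' @return list of plasmid molecules.
#' @export
extract_plasmids <- function(cell) {
  stopifnot(inherits(cell, "host_cell"))
  cell$hosted
}
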