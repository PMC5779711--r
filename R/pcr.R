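# PCR simulation by single-strand enumeration and 3'-anchored annealing.
#
# Stage 1 generates every single-strand extension product: a primer whose
# 3'-terminal `min_anneal_3p` bases match a template strand exactly is
# extended to the template's 5' end (its 5' tail, if any, is retained
# verbatim). New strands re-enter the pool as templates, so overlap-extension
# products emerge at the fixed point. Stage 2 anneals pairs of single strands
# with mutually complementary 3' regions and fills both in to duplexes.
# Duplexes flanked by a primer on each strand are exponential products; the
# rest are by-products.

#' Construct a PCR primer
#'
#' @param name primer name.
#' @param sequence 5'->3' sequence (>= 6 nt, concrete ACGT).
#' @param fixed may the Gibson assembly designer not modify it?
#' @param phosphorylated does it carry a 5' phosphate?
#' @return an object of class `pcr_primer`.
#' @export
pcr_primer <- function(name, sequence, fixed = FALSE, phosphorylated = FALSE) {
  sequence <- normalize_dna(sequence, "primer sequence")
  if (nchar(sequence) < 6L) stop("primers must be >= 6 nt", call. = FALSE)
  .check_concrete(sequence)
  structure(list(name = name, sequence = sequence, fixed = isTRUE(fixed),
                 phosphorylated = isTRUE(phosphorylated)),
            class = "pcr_primer")
}

as_primer_list <- function(primers) {
  if (inherits(primers, "pcr_primer")) return(list(primers))
  if (is.character(primers)) {
    nm <- names(primers)
    if (is.null(nm)) nm <- paste0("primer", seq_along(primers))
    return(lapply(seq_along(primers), function(i) pcr_primer(nm[i], primers[i])))
  }
  stopifnot(is.list(primers), all(vapply(primers, inherits, logical(1), "pcr_primer")))
  primers
}

# 0-based start positions of `needle` (exact) in `hay`; circular scans the
# doubled sequence and reports starts < n
.exact_starts <- function(hay, needle, circular = FALSE) {
  n <- nchar(hay)
  subject <- if (circular && nchar(needle) > 1L) {
    paste0(hay, substr(hay, 1L, nchar(needle) - 1L))
  } else {
    hay
  }
  starts <- iupac_match_starts(subject, needle)
  starts[starts < n]
}

# annealing sites of a primer on one template strand: data.frame(pos) where
# pos is the 0-based start of the 3'-tail match on the strand (5'->3')
.anneal_sites <- function(strand_seq, primer_seq, k, circular) {
  k <- min(k, nchar(primer_seq))
  tail3 <- substr(primer_seq, nchar(primer_seq) - k + 1L, nchar(primer_seq))
  .exact_starts(strand_seq, revcomp(tail3), circular)
}

# template-directed extension downstream of a primer annealed at 0-based
# `pos` (start of the k-base 3'-tail match) on a strand: the polymerase
# reads the template 3'->5' from position pos-1; on circular templates it
# wraps and stops after one full turn (n - k copied bases)
.extension_seq <- function(strand_seq, pos, k, circular, n) {
  if (circular) {
    segment <- substr(rotate_seq(strand_seq, (pos + k) %% n), 1L, n - k)
    revcomp(segment)
  } else {
    revcomp(substr(strand_seq, 1L, pos))
  }
}

# full single-strand product: primer (5' tail retained verbatim) + extension
.extend_on <- function(strand_seq, primer_seq, pos, k, circular, n) {
  paste0(primer_seq, .extension_seq(strand_seq, pos, k, circular, n))
}

# largest-first list of mutual 3'-overlap lengths between strands u and v:
# suffix_L(u) == revcomp(suffix_L(v)), L >= k
.mutual_overlaps <- function(u, v, k) {
  w <- revcomp(v)
  nu <- nchar(u); nw <- nchar(w)
  out <- integer(0)
  for (L in seq.int(min(nu, nw), k)) {
    if (substr(u, nu - L + 1L, nu) == substr(w, 1L, L)) out <- c(out, L)
  }
  out
}

#' PCR simulation
#'
#' See the module comments for the two-stage algorithm. Reactions with one
#' primer, or more than two, are legal. Circular templates support amplicons
#' spanning the origin. Product ends are blunt and unphosphorylated unless
#' the corresponding primer is phosphorylated.
#'
#' @param templates a [dna_molecule()] or list of them.
#' @param primers primers ([pcr_primer()] list or character vector).
#' @param min_anneal_3p exact 3'-terminal match length required for
#'   annealing (default 15 nt).
#' @param max_rounds cap on the strand-generation fixed-point iteration.
#' @return list with `products` (exponential, primer-flanked duplexes) and
#'   `byproducts` (other duplexes), both lists of molecules.
#' @export
simulate_pcr <- function(templates, primers, min_anneal_3p = 15L,
                         max_rounds = 10L) {
  templates <- as_molecule_list(templates)
  primers <- as_primer_list(primers)
  if (length(primers) < 1L) stop("at least one primer required", call. = FALSE)
  k <- as.integer(min_anneal_3p)

  # strand pool: sequence + whether it starts with a primer (and which)
  pool <- character(0)
  pool_primer <- character(0)   # name of the primer at the 5' end ("" if none)
  pool_circ <- logical(0)
  pool_len <- integer(0)        # template length for circular strands
  add_strand <- function(s, primer_name = "", circ = FALSE, tlen = 0L) {
    if (s %in% pool) return(invisible())
    pool <<- c(pool, s)
    pool_primer <<- c(pool_primer, primer_name)
    pool_circ <<- c(pool_circ, circ)
    pool_len <<- c(pool_len, tlen)
    invisible()
  }
  for (tmpl in templates) {
    circ <- tmpl$topology == "circular"
    add_strand(tmpl$seq, circ = circ, tlen = nchar(tmpl$seq))
    add_strand(revcomp(tmpl$seq), circ = circ, tlen = nchar(tmpl$seq))
  }
  template_hashes <- vapply(templates, canonical_hash, character(1))

  for (round in seq_len(max_rounds)) {
    added <- FALSE
    np <- length(pool)
    for (si in seq_len(np)) {
      s <- pool[si]
      for (p in primers) {
        sites <- .anneal_sites(s, p$sequence, k, pool_circ[si])
        for (pos in sites) {
          kk <- min(k, nchar(p$sequence))
          ext <- .extend_on(s, p$sequence, pos, kk, pool_circ[si], pool_len[si])
          before <- length(pool)
          add_strand(ext, primer_name = p$name)
          if (length(pool) > before) added <- TRUE
        }
      }
      if (length(pool) > 200L) break
    }
    if (!added || length(pool) > 200L) break
  }

  # which primer (if any) forms the 5' terminus of a strand — structural
  # check, so a primer sitting exactly at a template end still counts
  primer_at_start <- function(s) {
    for (p in primers) {
      if (startsWith(s, p$sequence)) return(p)
    }
    NULL
  }
  products <- list()
  byproducts <- list()
  seen <- character(0)
  linear_idx <- which(!pool_circ)
  for (ui in linear_idx) {
    for (vi in linear_idx) {
      if (vi < ui) next
      u <- pool[ui]; v <- pool[vi]
      for (L in .mutual_overlaps(u, v, k)) {
        pu <- primer_at_start(u)
        pv <- primer_at_start(v)
        top <- paste0(u, revcomp(substr(v, 1L, nchar(v) - L)))
        mol <- dna_molecule(
          top, "linear",
          left_end = dna_end("blunt",
                             phos = !is.null(pu) && pu$phosphorylated),
          right_end = dna_end("blunt",
                              phos = !is.null(pv) && pv$phosphorylated),
          note = "PCR product")
        h <- canonical_hash(mol)
        if (h %in% seen || h %in% template_hashes) next
        seen <- c(seen, h)
        if (!is.null(pu) && !is.null(pv)) {
          products <- c(products, list(mol))
        } else {
          byproducts <- c(byproducts, list(mol))
        }
      }
    }
  }
  list(products = products, byproducts = byproducts)
}

#' Single-primer sequencing simulation
#'
#' Returns the theoretical read of a one-primer sequencing reaction: the
#' template-directed extension downstream of the primer's 3' end, truncated
#' at `read_length` or at the template end (circular templates wrap, capped
#' at `read_length`). The primer must anneal exactly once (3'-exact match
#' over `min_anneal` bases); zero or multiple sites are an error, not a
#' guess.
#'
#' @param mol template molecule.
#' @param primer a [pcr_primer()] or sequence string.
#' @param read_length maximum read length in nt.
#' @param min_anneal exact 3' match length required.
#' @return the read as a DNA string (primer not included).
#' @export
simulate_sequencing <- function(mol, primer, read_length, min_anneal = 15L) {
  stopifnot(inherits(mol, "dna_molecule"))
  pseq <- if (inherits(primer, "pcr_primer")) primer$sequence else
    normalize_dna(primer, "primer")
  k <- min(as.integer(min_anneal), nchar(pseq))
  circ <- mol$topology == "circular"
  n <- nchar(mol$seq)
  strands <- c(mol$seq, revcomp(mol$seq))
  hits <- list()
  for (s in strands) {
    for (pos in .anneal_sites(s, pseq, k, circ)) {
      hits <- c(hits, list(list(strand = s, pos = pos)))
    }
  }
  if (length(hits) == 0L) stop("primer does not anneal to the template", call. = FALSE)
  if (length(hits) > 1L) stop("primer anneals at multiple sites", call. = FALSE)
  h <- hits[[1]]
  read <- .extension_seq(h$strand, h$pos, k, circ, n)
  substr(read, 1L, read_length)
}
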