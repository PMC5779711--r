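# The DNA-molecule data model.
#
# A molecule is the top strand written 5'->3' plus a topology and, for
# non-circular molecules, two typed ends.  All coordinates are 0-based
# half-open on the top strand; GenBank I/O converts to/from 1-based
# inclusive.  Single-stranded protrusions are described on the end objects:
# an overhang sequence is always given 5'->3' on the protruding strand, a
# convention that is invariant under strand flips.
#
# Representation invariants tying ends to the sequence field:
#   * a left  5' overhang protrudes on the top strand: its bases are the
#     prefix of `seq`;
#   * a right 3' overhang protrudes on the top strand: its bases are the
#     suffix of `seq`;
#   * a left 3' / right 5' overhang protrudes on the bottom strand: its
#     bases are NOT part of `seq`.
# Under this convention two compatible ends join by plain concatenation of
# the top strands, and the total top-strand length of digestion fragments
# equals that of the substrate (mass conservation).

END_OVERHANGS <- c("blunt", "5ov", "3ov", "virtual")
TOPOLOGIES <- c("linear", "circular", "genomic_fragment")

#' Construct a DNA end
#'
#' @param overhang one of `"blunt"`, `"5ov"`, `"3ov"`, `"virtual"`.
#' @param seq overhang sequence, 5'->3' on the protruding strand; must be
#'   empty for blunt ends.
#' @param phos is a 5' phosphate present?
#' @param hairpin is the end a closed hairpin (cannot ligate)?
#' @param marker virtual-overhang marker; non-empty only on recombination
#'   intermediates, which are never final products.
#' @return an object of class `dna_end`.
#' @export
dna_end <- function(overhang = "blunt", seq = "", phos = FALSE,
                    hairpin = FALSE, marker = NULL) {
  overhang <- match.arg(overhang, END_OVERHANGS)
  if (overhang == "blunt" && nzchar(seq)) {
    stop("blunt ends carry no overhang sequence", call. = FALSE)
  }
  if (overhang %in% c("5ov", "3ov")) {
    if (!nzchar(seq)) stop("overhang ends need a non-empty sequence", call. = FALSE)
    seq <- normalize_dna(seq, "overhang sequence")
  }
  if (overhang == "virtual" && (is.null(marker) || !nzchar(marker))) {
    stop("virtual ends need a marker", call. = FALSE)
  }
  structure(
    list(overhang = overhang, seq = seq, phos = isTRUE(phos),
         hairpin = isTRUE(hairpin),
         marker = if (is.null(marker)) "" else marker),
    class = "dna_end"
  )
}

is_virtual_end <- function(end) {
  !is.null(end) && end$overhang == "virtual"
}

#' Construct a sequence feature
#'
#' @param name feature name (library key, gene name, ...).
#' @param kind feature kind (`"CDS"`, `"promoter"`, `"ori"`,
#'   `"alignment_match"`, ...). The registry is extensible: any string is
#'   accepted.
#' @param start,end 0-based half-open interval on the top strand. On circular
#'   molecules `end` may exceed the length to express an origin-wrapping
#'   feature (`end - start` is the feature length).
#' @param strand `"+"` or `"-"`.
#' @param qualifiers named list of free-form qualifiers.
#' @return an object of class `dna_feature`.
#' @export
feature <- function(name, kind, start, end, strand = "+", qualifiers = list()) {
  stopifnot(start >= 0, end > start, strand %in% c("+", "-"))
  structure(
    list(name = as.character(name), kind = as.character(kind),
         start = as.integer(start), end = as.integer(end),
         strand = strand, qualifiers = qualifiers),
    class = "dna_feature"
  )
}

.next_mol_id <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("mol%06d", counter)
  }
})

#' Construct a DNA molecule
#'
#' @param seq top strand, 5'->3', IUPAC DNA alphabet.
#' @param topology `"linear"`, `"circular"` or `"genomic_fragment"`.
#' @param left_end,right_end [dna_end()] objects (ignored for circular
#'   molecules; default blunt, unphosphorylated).
#' @param features list of [feature()] objects.
#' @param id opaque identifier (auto-generated when `NULL`).
#' @param note free-text provenance note.
#' @return an object of class `dna_molecule`.
#' @export
dna_molecule <- function(seq, topology = "linear",
                         left_end = dna_end(), right_end = dna_end(),
                         features = list(), id = NULL, note = "") {
  topology <- match.arg(topology, TOPOLOGIES)
  seq <- normalize_dna(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  n <- nchar(seq)
  if (topology == "circular") {
    left_end <- NULL
    right_end <- NULL
  } else {
    stopifnot(inherits(left_end, "dna_end"), inherits(right_end, "dna_end"))
  }
  for (f in features) {
    stopifnot(inherits(f, "dna_feature"))
    if (topology == "circular") {
      if (f$start < 0 || f$start >= n || (f$end - f$start) > n) {
        stop("feature ", f$name, " outside circular coordinates", call. = FALSE)
      }
    } else if (f$start < 0 || f$end > n) {
      stop("feature ", f$name, " outside [0, length)", call. = FALSE)
    }
  }
  structure(
    list(id = if (is.null(id)) .next_mol_id() else id,
         seq = seq, topology = topology,
         left_end = left_end, right_end = right_end,
         features = features, note = note),
    class = "dna_molecule"
  )
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule %s> %s, %d bp", x$id, x$topology, nchar(x$seq)))
  if (x$topology != "circular") {
    cat(sprintf(", ends %s | %s", format_end_code(x$left_end),
                format_end_code(x$right_end)))
  }
  cat(sprintf(", %d feature(s)\n", length(x$features)))
  invisible(x)
}

#' Length of a molecule in base pairs (top-strand length)
#' @param mol a [dna_molecule()].
#' @return integer length.
#' @export
mol_length <- function(mol) nchar(mol$seq)

#' Reverse complement of a molecule
#'
#' The sequence is reverse-complemented, the two ends are swapped (overhang
#' sequences are physical, 5'->3' on the protruding strand, so they are
#' unchanged), and feature coordinates and strands are remapped. Applying the
#' operation twice returns an equivalent molecule.
#'
#' @param mol a [dna_molecule()].
#' @return the flipped molecule (same id).
#' @export
reverse_complement <- function(mol) {
  stopifnot(inherits(mol, "dna_molecule"))
  n <- nchar(mol$seq)
  feats <- lapply(mol$features, function(f) {
    len <- f$end - f$start
    if (mol$topology == "circular") {
      new_start <- ((n - f$end) %% n + n) %% n
    } else {
      new_start <- n - f$end
    }
    feature(f$name, f$kind, new_start, new_start + len,
            strand = if (f$strand == "+") "-" else "+",
            qualifiers = f$qualifiers)
  })
  out <- mol
  out$seq <- revcomp(mol$seq)
  out$features <- feats
  if (mol$topology != "circular") {
    out$left_end <- mol$right_end
    out$right_end <- mol$left_end
  }
  out
}

#' Find all occurrences of an IUPAC pattern in a molecule
#'
#' Degenerate pattern symbols match their IUPAC base sets; overlapping matches
#' are all reported; on circular molecules matches may wrap the origin
#' (the scan runs over `seq` followed by its first `patlen - 1` bases and
#' reports starts `< length`).
#'
#' @param mol a [dna_molecule()].
#' @param pattern non-empty IUPAC string.
#' @param both_strands also search the minus strand? Minus-strand hits are
#'   reported at the 0-based top-strand start of the reverse-complement
#'   occurrence.
#' @return data.frame with columns `pos` (0-based top-strand start) and
#'   `strand` (`"+"`/`"-"`).
#' @export
find_pattern <- function(mol, pattern, both_strands = TRUE) {
  stopifnot(inherits(mol, "dna_molecule"))
  pattern <- normalize_dna(pattern, "pattern")
  if (!nzchar(pattern)) stop("pattern must be non-empty", call. = FALSE)
  n <- nchar(mol$seq)
  m <- nchar(pattern)
  subject <- mol$seq
  if (mol$topology == "circular" && m > 1L && n > 1L) {
    subject <- paste0(mol$seq, substr(mol$seq, 1L, min(m - 1L, n)))
  }
  hit_one <- function(pat) {
    starts <- iupac_match_starts(subject, pat)
    starts[starts < n]
  }
  plus <- hit_one(pattern)
  out <- data.frame(pos = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    minus <- hit_one(revcomp(pattern))
    out <- rbind(out, data.frame(pos = minus, strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Format / parse DNA end codes
#'
#' One token per end: `[P-](blunt | 5ov:<SEQ> | 3ov:<SEQ>) | hairpin`, where
#' the optional `P-` prefix marks a 5' phosphate and `<SEQ>` is the
#' protruding strand 5'->3'.  Virtual recombination intermediates format as
#' `virt:<marker>` (they are internal and never appear on final products).
#'
#' @param end a [dna_end()].
#' @return `format_end_code`: the code string.
#' @export
format_end_code <- function(end) {
  stopifnot(inherits(end, "dna_end"))
  if (end$hairpin) return("hairpin")
  body <- switch(end$overhang,
    blunt = "blunt",
    "5ov" = paste0("5ov:", end$seq),
    "3ov" = paste0("3ov:", end$seq),
    virtual = paste0("virt:", end$marker)
  )
  if (end$phos && end$overhang != "virtual") paste0("P-", body) else body
}

#' @rdname format_end_code
#' @param code an end-code string.
#' @return `parse_end_code`: the [dna_end()].
#' @export
parse_end_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code0 <- code
  if (code == "hairpin") return(dna_end(hairpin = TRUE))
  phos <- startsWith(code, "P-")
  if (phos) code <- substr(code, 3L, nchar(code))
  if (code == "blunt") return(dna_end("blunt", phos = phos))
  if (grepl("^5ov:.+$", code)) return(dna_end("5ov", sub("^5ov:", "", code), phos = phos))
  if (grepl("^3ov:.+$", code)) return(dna_end("3ov", sub("^3ov:", "", code), phos = phos))
  if (grepl("^virt:.+$", code)) {
    return(dna_end("virtual", marker = sub("^virt:", "", code), phos = phos))
  }
  stop("malformed end code: ", code0, call. = FALSE)
}

# serialized end pair for hashing (left|right); circular molecules have none
.end_codes_string <- function(mol) {
  if (mol$topology == "circular") return("")
  paste(format_end_code(mol$left_end), format_end_code(mol$right_end), sep = "|")
}

#' Canonical identity hash of a molecule
#'
#' SHA-256 digest of (topology, canonical sequence representative, end
#' codes).  The representative is invariant under strand flip for
#' non-circular molecules and under both rotation and strand flip for
#' circular molecules, so physically identical molecules hash equal while a
#' linear and a circular molecule of the same sequence differ.
#'
#' @param mol a [dna_molecule()].
#' @return hex digest string.
#' @export
canonical_hash <- function(mol) {
  stopifnot(inherits(mol, "dna_molecule"))
  if (mol$topology == "circular") {
    f <- rotate_seq(mol$seq, least_rotation_index(mol$seq))
    r <- revcomp(mol$seq)
    r <- rotate_seq(r, least_rotation_index(r))
    rep <- if (f <= r) f else r
    key <- paste("circular", rep, sep = "\x1f")
  } else {
    fwd <- mol$seq
    rev_ <- revcomp(mol$seq)
    fc <- paste(fwd, .end_codes_string(mol), sep = "\x1f")
    rc_mol <- reverse_complement(mol)
    rcch <- paste(rev_, .end_codes_string(rc_mol), sep = "\x1f")
    rep <- if (fc <= rcch) fc else rcch
    key <- paste(mol$topology, rep, sep = "\x1f")
  }
  cli::hash_sha256(key)
}

#' Create a feature library
#'
#' @param entries named list: name -> list(seq =, kind =, qualifiers =). A
#'   plain character vector of sequences is accepted (kind defaults to
#'   `"misc"`). Names are unique; lookup is case-insensitive.
#' @return an object of class `feature_library`.
#' @export
feature_library <- function(entries = list()) {
  if (is.character(entries)) {
    entries <- lapply(entries, function(s) list(seq = s, kind = "misc",
                                                qualifiers = list()))
  }
  nm <- names(entries)
  if (length(entries) > 0 && (is.null(nm) || any(!nzchar(nm)))) {
    stop("library entries must be named", call. = FALSE)
  }
  if (anyDuplicated(tolower(nm))) {
    stop("library names must be unique (case-insensitive)", call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    list(seq = normalize_dna(e$seq, "library sequence"),
         kind = if (is.null(e$kind)) "misc" else e$kind,
         qualifiers = if (is.null(e$qualifiers)) list() else e$qualifiers)
  })
  structure(list(entries = entries), class = "feature_library")
}

#' Look up a library entry by name (case-insensitive)
#' @param lib a [feature_library()].
#' @param name entry name.
#' @return the entry or `NULL`.
#' @export
library_lookup <- function(lib, name) {
  idx <- match(tolower(name), tolower(names(lib$entries)))
  if (is.na(idx)) NULL else lib$entries[[idx]]
}

#' Annotate a molecule against a feature library
#'
#' Every library entry whose sequence occurs in the molecule (either strand,
#' wrapping allowed on circles) is added as a feature; existing features are
#' preserved and exact duplicates (same name, span and strand) suppressed.
#'
#' @param mol a [dna_molecule()].
#' @param lib a [feature_library()].
#' @return the annotated molecule.
#' @export
annotate_features <- function(mol, lib) {
  stopifnot(inherits(mol, "dna_molecule"), inherits(lib, "feature_library"))
  feats <- mol$features
  keyset <- vapply(feats, function(f) paste(f$name, f$start, f$end, f$strand),
                   character(1))
  for (nm in names(lib$entries)) {
    e <- lib$entries[[nm]]
    hits <- find_pattern(mol, e$seq, both_strands = TRUE)
    L <- nchar(e$seq)
    for (i in seq_len(nrow(hits))) {
      f <- feature(nm, e$kind, hits$pos[i], hits$pos[i] + L,
                   strand = hits$strand[i], qualifiers = e$qualifiers)
      key <- paste(f$name, f$start, f$end, f$strand)
      if (!key %in% keyset) {
        feats <- c(feats, list(f))
        keyset <- c(keyset, key)
      }
    }
  }
  mol$features <- feats
  mol
}

# shift all features by `delta` (used when concatenating molecules)
shift_features <- function(features, delta) {
  lapply(features, function(f) {
    feature(f$name, f$kind, f$start + delta, f$end + delta,
            strand = f$strand, qualifiers = f$qualifiers)
  })
}

# keep features lying fully inside [lo, hi); truncate those crossing a cut
# point, marking them with a `truncated` qualifier; rebase to lo.
clip_features <- function(features, lo, hi) {
  out <- list()
  for (f in features) {
    if (f$end <= lo || f$start >= hi) next
    s <- max(f$start, lo)
    e <- min(f$end, hi)
    quals <- f$qualifiers
    if (s != f$start || e != f$end) quals$truncated <- "true"
    out <- c(out, list(feature(f$name, f$kind, s - lo, e - lo,
                               strand = f$strand, qualifiers = quals)))
  }
  out
}
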